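# Shared vocabulary and small helpers.

# The 12 point-mutation directions, in the order used for reporting
# (transitions first, then N->S transversions, then N->W).
DIRECTIONS <- c(
  "C>T", "G>A", "T>C", "A>G",
  "C>G", "G>C", "T>G", "A>C",
  "T>A", "A>T", "C>A", "G>T"
)

BASES <- c("A", "C", "G", "T")

#' Point-mutation direction vocabulary
#'
#' `mutation_directions()` returns the 12 ordered point-mutation directions
#' ("from>to"); `strand_complement_direction()` maps a direction to its
#' strand-symmetric counterpart (both bases complemented), e.g. C>T to G>A.
#'
#' @param direction Character vector of directions such as `"C>T"`.
#' @return A character vector.
#' @export
#' @examples
#' mutation_directions()
#' strand_complement_direction(c("C>T", "T>C"))
mutation_directions <- function() DIRECTIONS

#' @rdname mutation_directions
#' @export
strand_complement_direction <- function(direction) {
  stopifnot(is.character(direction))
  bad <- !direction %in% DIRECTIONS & !is.na(direction)
  if (any(bad)) {
    abort(paste0("unknown mutation direction: ", direction[bad][1]))
  }
  chartr("ACGT", "TGCA", direction)
}

direction_from <- function(direction) substr(direction, 1L, 1L)
direction_to <- function(direction) substr(direction, 3L, 3L)

make_direction <- function(from, to) {
  ifelse(is.na(from) | is.na(to), NA_character_, paste0(from, ">", to))
}

# Reverse complement for plain character k-mers (vectorised).
revcomp_chr <- function(x) {
  out <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(out, NULL), function(ch) paste(rev(ch), collapse = ""), "",
         USE.NAMES = FALSE)
}

# All k-mers over ACGT in lexicographic order (matches Biostrings'
# oligonucleotideFrequency column order).
all_kmers <- function(k) {
  stopifnot(k >= 1)
  grids <- rep(list(BASES), k)
  do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
}

central_base <- function(kmer) {
  k <- nchar(kmer)
  substr(kmer, (k + 1L) %/% 2L, (k + 1L) %/% 2L)
}

# Deterministic 32-bit sub-seed derivation so that independent random
# streams (per chain, per cell) flow from one user seed.
derive_seed <- function(seed, index) {
  s <- (as.numeric(seed) %% 2147483647) + 1
  (s * 48271 + as.numeric(index) * 9973) %% 2147483629 + 1
}

check_odd_k <- function(k) {
  if (length(k) != 1 || k < 1 || k %% 2 == 0) {
    abort("`k` must be a single odd integer >= 1")
  }
  as.integer(k)
}

# Population variance (divide by n, not n - 1): the variance statistics here
# are moments of the observed series / weight distribution, not estimators
# of a superpopulation variance.
pop_var <- function(x) mean((x - mean(x))^2)
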