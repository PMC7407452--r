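# Exact context counting and cell tallies: the proportion p_c of counted
# sites matching each k-mer is treated as known (contexts can be counted
# exactly); each (k-mer, direction) cell is a binomial with the k-mer count
# as trials and the qualified variants of that direction as successes.

#' Count k-mer contexts over a region mask
#'
#' Counts every k-mer centred on a maskable site, exactly. Only windows
#' lying wholly inside a mask interval are counted (sites within (k-1)/2 of
#' an interval edge are skipped, as are windows containing N). Minus-strand
#' intervals are counted on the reverse complement, so contexts are read off
#' the annotated strand.
#'
#' @param genome A `DNAStringSet`.
#' @param mask A `region_mask` (restrict to one class first if classes
#'   should be analysed separately).
#' @param k Odd context size.
#' @return A tibble of class `"context_weights"` with columns `kmer`,
#'   `central`, `n_sites` and `pc` (`n_sites / sum(n_sites)`), one row per
#'   possible k-mer, with attribute `k`.
#' @export
count_contexts <- function(genome, mask, k) {
  k <- check_odd_k(k)
  kmers <- all_kmers(k)
  counts <- setNames(numeric(length(kmers)), kmers)
  m <- tibble::as_tibble(mask)
  for (i in seq_len(nrow(m))) {
    ch <- m$chrom[i]
    if (!ch %in% names(genome)) next
    len <- m$end[i] - m$start[i]
    if (len < k) next
    sq <- Biostrings::subseq(genome[[ch]], m$start[i] + 1, m$end[i])
    if (identical(m$strand[i], "-")) sq <- Biostrings::reverseComplement(sq)
    of <- Biostrings::oligonucleotideFrequency(sq, width = k)
    counts <- counts + of[kmers]
  }
  total <- sum(counts)
  structure(
    tibble::tibble(kmer = kmers, central = central_base(kmers),
                   n_sites = unname(counts),
                   pc = if (total > 0) unname(counts) / total else 0),
    k = k,
    class = c("context_weights", class(tibble::tibble()))
  )
}

#' Tally per-(context, direction) trials and successes
#'
#' Builds the context table behind the variance-due-to-context statistic:
#' for every k-mer and point-mutation direction from its central base, the
#' number of trials (k-mer occurrences over the mask, from
#' [count_contexts()]) and successes (qualified variants of that direction
#' whose strand-oriented context is that k-mer). Variants whose context
#' window crosses an interval edge are skipped, keeping trials and
#' successes on the same site set. A variant whose oriented ancestral base
#' differs from the genome base at its position is counted as a mismatch
#' and excluded; more than `mismatch_max` mismatches is an error.
#'
#' @param variants Output of [qualify_context_variants()] run with the same
#'   mask.
#' @param genome A `DNAStringSet`.
#' @param mask The same `region_mask` used for qualification.
#' @param k Odd context size.
#' @param empty_warn Warn when more than this fraction of populated-trial
#'   cells have zero variants (default 0.01): such cells keep a uniform
#'   Beta(1,1) posterior and inflate the variance.
#' @param mismatch_max Maximum tolerated fraction of ancestral/genome
#'   mismatches (default 0.01).
#' @return A tibble of class `"context_table"` with columns `kmer`,
#'   `central`, `direction`, `n_contexts`, `n_variants`; attributes `k`,
#'   `weights` (the [count_contexts()] tibble), `empty_cell_fraction` and
#'   `mismatches`.
#' @export
tally_cells <- function(variants, genome, mask, k,
                        empty_warn = 0.01, mismatch_max = 0.01) {
  k <- check_odd_k(k)
  h <- (k - 1L) %/% 2L
  need <- c("strand", "int_start", "int_end", "oriented")
  if (!all(need %in% names(variants))) {
    abort("variants must come from qualify_context_variants() (same mask)")
  }
  weights <- count_contexts(genome, mask, k)

  v <- tibble::as_tibble(variants)
  v <- v[v$pos - h >= v$int_start & v$pos + h <= v$int_end - 1, , drop = FALSE]

  kmer <- character(nrow(v))
  mism <- 0L
  if (nrow(v)) {
    for (ch in unique(v$chrom)) {
      rows <- which(v$chrom == ch)
      s <- as.character(genome[[ch]])
      kmer[rows] <- substring(s, v$pos[rows] + 1 - h, v$pos[rows] + 1 + h)
    }
    valid <- !grepl("[^ACGT]", kmer)
    v <- v[valid, , drop = FALSE]; kmer <- kmer[valid]
    minus <- v$strand == "-"
    kmer[minus] <- revcomp_chr(kmer[minus])
    mismatch <- substr(kmer, h + 1L, h + 1L) != direction_from(v$direction)
    mism <- sum(mismatch)
    if (nrow(v) && mism / nrow(v) > mismatch_max) {
      abort(sprintf(
        "%d of %d variants (%.1f%%) disagree with the genome ancestral base",
        mism, nrow(v), 100 * mism / nrow(v)))
    }
    v <- v[!mismatch, , drop = FALSE]; kmer <- kmer[!mismatch]
  }

  cells <- tidyr::expand_grid(kmer = weights$kmer, to = BASES)
  cells$central <- central_base(cells$kmer)
  cells <- cells[cells$to != cells$central, ]
  cells$direction <- make_direction(cells$central, cells$to)
  cells$n_contexts <- weights$n_sites[match(cells$kmer, weights$kmer)]

  if (nrow(v)) {
    key <- paste(kmer, v$direction)
    tab <- table(key)
    cells$n_variants <- as.numeric(tab[paste(cells$kmer, cells$direction)])
    cells$n_variants[is.na(cells$n_variants)] <- 0
  } else {
    cells$n_variants <- 0
  }
  if (any(cells$n_variants > cells$n_contexts)) {
    abort("more variants than context occurrences in a cell")
  }

  populated <- cells$n_contexts > 0
  ecf <- if (any(populated)) mean(cells$n_variants[populated] == 0) else NA_real_
  if (is.finite(ecf) && ecf > empty_warn && nrow(v) > 0) {
    warn(sprintf(
      "%.1f%% of populated cells have zero variants; their Beta(1,1) posteriors will inflate the variance",
      100 * ecf))
  }

  out <- cells[, c("kmer", "central", "direction", "n_contexts", "n_variants")]
  structure(tibble::as_tibble(out), k = k, weights = weights,
            empty_cell_fraction = ecf, mismatches = mism,
            class = c("context_table", class(tibble::tibble())))
}

#' Build a context table directly from counts
#'
#' Constructor for toy tables in tests and examples: supply per-cell trials
#' and successes and (optionally) site weights.
#'
#' @param cells Data frame with columns `kmer`, `direction`, `n_contexts`,
#'   `n_variants`; missing (kmer, direction) combinations get zero counts.
#' @param k Odd context size (inferred from the k-mers if omitted).
#' @return A `"context_table"` as from [tally_cells()].
#' @export
context_table <- function(cells, k = NULL) {
  cells <- tibble::as_tibble(cells)
  k <- check_odd_k(k %||% nchar(cells$kmer[1]))
  stopifnot(all(nchar(cells$kmer) == k))
  kmers <- all_kmers(k)
  full <- tidyr::expand_grid(kmer = kmers, to = BASES)
  full$central <- central_base(full$kmer)
  full <- full[full$to != full$central, ]
  full$direction <- make_direction(full$central, full$to)
  key <- paste(cells$kmer, cells$direction)
  idx <- match(paste(full$kmer, full$direction), key)
  full$n_variants <- ifelse(is.na(idx), 0, cells$n_variants[idx])
  trial_tbl <- tapply(cells$n_contexts, cells$kmer, max)
  full$n_contexts <- as.numeric(trial_tbl[full$kmer])
  full$n_contexts[is.na(full$n_contexts)] <- 0
  weights <- tibble::tibble(
    kmer = kmers, central = central_base(kmers),
    n_sites = full$n_contexts[match(kmers, full$kmer)]
  )
  weights$pc <- if (sum(weights$n_sites) > 0)
    weights$n_sites / sum(weights$n_sites) else 0
  populated <- full$n_contexts > 0
  out <- full[, c("kmer", "central", "direction", "n_contexts", "n_variants")]
  structure(tibble::as_tibble(out), k = k,
            weights = structure(weights, k = k,
                                class = c("context_weights",
                                          class(tibble::tibble()))),
            empty_cell_fraction = if (any(populated))
              mean(out$n_variants[populated] == 0) else NA_real_,
            mismatches = 0L,
            class = c("context_table", class(tibble::tibble())))
}
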