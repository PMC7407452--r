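# Genome simulator: sequences whose per-site polymorphism probability
# depends on a configurable k-mer context table, emitting biallelic,
# multiallelic and clustered variants to exercise every downstream filter.
# Rates are applied to the plus-strand (physical) sequence; strand
# orientation happens only in analysis, so asymmetric tables produce
# genuinely strand-asymmetric data.

#' Build a k-mer x direction polymorphism-rate table
#'
#' Constructs the ground-truth table mapping each k-mer context and point
#' mutation direction from its central base to a per-site polymorphism
#' probability. The default structure is: a base transversion rate, a
#' transition multiplier, a CpG multiplier on C>T at central C with 3' G
#' (and, strand-symmetrically, G>A at central G with 5' C), optional flank
#' neighbour effects and optional per-direction strand-asymmetry
#' multipliers.
#'
#' @param k Odd context size (1, 3, 5, ...).
#' @param base_rate Per-site polymorphism probability of one transversion
#'   direction.
#' @param transition_mult Multiplier for the transition direction of each
#'   base (A>G, G>A, C>T, T>C).
#' @param cpg_mult Multiplier for C>T in CpG context and G>A in its
#'   strand-symmetric counterpart (requires `k >= 3`; ignored at `k = 1`).
#' @param neighbor_effects Optional data frame with columns `offset`
#'   (position relative to the central base, e.g. -1 for the 5' neighbour),
#'   `base`, and `mult`: all direction rates of a k-mer are multiplied by
#'   `mult` when the flank at `offset` equals `base`.
#' @param asymmetry Optional named numeric vector of per-direction
#'   multipliers (e.g. `c("T>C" = 3)`) breaking strand symmetry.
#' @return A tibble of class `"context_rate_table"` with columns `kmer`,
#'   `central`, `direction`, `prob`, and attribute `k`.
#' @export
context_rate_table <- function(k = 3,
                               base_rate = 0.003,
                               transition_mult = 3,
                               cpg_mult = 10,
                               neighbor_effects = NULL,
                               asymmetry = NULL) {
  k <- check_odd_k(k)
  kmers <- all_kmers(k)
  central <- central_base(kmers)
  h <- (k - 1L) %/% 2L

  tbl <- tidyr::expand_grid(kmer = kmers, to = BASES)
  tbl$central <- central_base(tbl$kmer)
  tbl <- tbl[tbl$to != tbl$central, ]
  tbl$direction <- make_direction(tbl$central, tbl$to)
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  is_ts <- unname(tbl$to == transition_of[tbl$central])
  tbl$prob <- base_rate * ifelse(is_ts, transition_mult, 1)

  if (k >= 3 && cpg_mult != 1) {
    three_prime <- substr(tbl$kmer, h + 2L, h + 2L)
    five_prime <- substr(tbl$kmer, h, h)
    cpg_ct <- tbl$central == "C" & three_prime == "G" & tbl$direction == "C>T"
    cpg_ga <- tbl$central == "G" & five_prime == "C" & tbl$direction == "G>A"
    tbl$prob[cpg_ct | cpg_ga] <- tbl$prob[cpg_ct | cpg_ga] * cpg_mult
  }

  if (!is.null(neighbor_effects)) {
    ne <- tibble::as_tibble(neighbor_effects)
    stopifnot(all(c("offset", "base", "mult") %in% names(ne)))
    if (any(abs(ne$offset) > h) || any(ne$offset == 0)) {
      abort("neighbor_effects offsets must be nonzero and within (k-1)/2")
    }
    for (i in seq_len(nrow(ne))) {
      at <- substr(tbl$kmer, h + 1L + ne$offset[i], h + 1L + ne$offset[i])
      hit <- at == ne$base[i]
      tbl$prob[hit] <- tbl$prob[hit] * ne$mult[i]
    }
  }

  if (!is.null(asymmetry)) {
    stopifnot(all(names(asymmetry) %in% DIRECTIONS))
    for (d in names(asymmetry)) {
      tbl$prob[tbl$direction == d] <- tbl$prob[tbl$direction == d] * asymmetry[[d]]
    }
  }

  if (any(tbl$prob < 0 | tbl$prob > 1)) abort("rates must lie in [0, 1]")
  tot <- tapply(tbl$prob, tbl$kmer, sum)
  if (any(tot > 1)) abort("total polymorphism probability exceeds 1 for some k-mer")

  out <- tibble::as_tibble(tbl[, c("kmer", "central", "direction", "prob")])
  structure(out, k = k,
            class = c("context_rate_table", class(tibble::tibble())))
}

#' Genome simulation parameters
#'
#' @param length Genome length in bp.
#' @param base_freq Named frequencies of A, C, G, T (normalised internally).
#' @param rate_table A [context_rate_table()] giving ground-truth per-site
#'   polymorphism probabilities by k-mer and direction.
#' @param fraction_multiallelic Fraction of variants upgraded to
#'   multiallelic (a second derived allele added), in `[0, 1)`.
#' @param cluster_rate Expected clustered-variant pairs per kb: partners are
#'   placed within 4 bp of existing variants to exercise the neighbourhood
#'   filter.
#' @param regions Optional tibble (`start`, `end`, `class`, `strand`,
#'   0-based half-open) annotating the simulated chromosome; default is one
#'   plus-strand intronic interval covering the whole sequence.
#' @param seed Integer seed.
#' @return A list of class `"genome_sim_params"`.
#' @export
genome_sim_params <- function(length = 1e6,
                              base_freq = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                              rate_table = context_rate_table(),
                              fraction_multiallelic = 0,
                              cluster_rate = 0,
                              regions = NULL,
                              seed = 1L) {
  stopifnot(inherits(rate_table, "context_rate_table"))
  base_freq <- base_freq[BASES]
  if (anyNA(base_freq) || any(base_freq < 0)) {
    abort("base_freq must be named non-negative frequencies of A, C, G, T")
  }
  base_freq <- base_freq / sum(base_freq)
  if (fraction_multiallelic < 0 || fraction_multiallelic >= 1) {
    abort("fraction_multiallelic must lie in [0, 1)")
  }
  if (is.null(regions)) {
    regions <- tibble::tibble(start = 0, end = as.numeric(length),
                              class = "intronic", strand = "+")
  }
  structure(
    list(length = as.numeric(length), base_freq = base_freq,
         rate_table = rate_table,
         fraction_multiallelic = fraction_multiallelic,
         cluster_rate = cluster_rate, regions = tibble::as_tibble(regions),
         seed = as.integer(seed)),
    class = "genome_sim_params"
  )
}

#' Simulate a genome with context-dependent polymorphism
#'
#' Generates a random sequence from the base frequencies, then draws, for
#' every site with a full k-mer context, an independent Bernoulli
#' polymorphism indicator with probability looked up in the rate table for
#' the site's realized context; polymorphic sites get a derived allele
#' chosen among the three directions in proportion to their rates.
#' Requested fractions of multiallelic variants and clustered variant pairs
#' are injected afterwards. The truth record is the rate table actually
#' used.
#'
#' @param params A [genome_sim_params()] object.
#' @return A list with `genome` (a `DNAStringSet` with one sequence
#'   `"sim1"`), `regions` (a `region_mask`), `variants` (a `variant_tbl`,
#'   sorted by position) and `truth` (the `context_rate_table`).
#' @export
simulate_genome <- function(params = genome_sim_params()) {
  stopifnot(inherits(params, "genome_sim_params"))
  p <- params
  k <- attr(p$rate_table, "k")
  h <- (k - 1L) %/% 2L
  n <- p$length
  set.seed(derive_seed(p$seed, 11))

  code <- sample.int(4L, n, replace = TRUE, prob = p$base_freq) - 1L

  # k-mer index per eligible site (vectorised positional encoding).
  centers <- seq.int(h + 1L, n - h)
  idx <- integer(length(centers))
  for (j in seq_len(k)) {
    idx <- idx * 4L + code[centers + (j - h - 1L)]
  }

  # Lookup tables in lexicographic k-mer order.
  kmers <- all_kmers(k)
  cells <- p$rate_table
  prob_dir <- matrix(0, nrow = length(kmers), ncol = 4,
                     dimnames = list(kmers, BASES))
  prob_dir[cbind(match(cells$kmer, kmers), match(direction_to(cells$direction),
                                                 BASES))] <- cells$prob
  prob_tot <- rowSums(prob_dir)

  u <- runif(length(centers))
  site_tot <- prob_tot[idx + 1L]
  poly <- which(u < site_tot)

  # Direction choice among the three rates of the realized k-mer.
  cum1 <- prob_dir[, 1]
  cum2 <- cum1 + prob_dir[, 2]
  cum3 <- cum2 + prob_dir[, 3]
  up <- u[poly]  # uniform on [0, site_tot): reuse for the categorical draw
  ip <- idx[poly] + 1L
  to_code <- 1L + (up >= cum1[ip]) + (up >= cum2[ip]) + (up >= cum3[ip])

  pos <- centers[poly] - 1L  # 0-based
  anc <- BASES[code[centers[poly]] + 1L]
  der <- BASES[to_code]

  vt <- tibble::tibble(
    chrom = "sim1", pos = as.numeric(pos), ref = anc, ancestral = anc,
    alleles = paste(anc, der, sep = ","), biallelic = TRUE, derived = der,
    direction = make_direction(anc, der)
  )

  if (p$fraction_multiallelic > 0 && nrow(vt)) {
    m <- which(runif(nrow(vt)) < p$fraction_multiallelic)
    if (length(m)) {
      extra <- vapply(m, function(i) {
        sample(setdiff(BASES, c(vt$ancestral[i], vt$derived[i])), 1)
      }, "")
      vt$alleles[m] <- paste(vt$alleles[m], extra, sep = ",")
      vt$biallelic[m] <- FALSE
      vt$derived[m] <- NA_character_
      vt$direction[m] <- NA_character_
    }
  }

  if (p$cluster_rate > 0 && nrow(vt)) {
    n_pairs <- rpois(1, p$cluster_rate * n / 1000)
    n_pairs <- min(n_pairs, nrow(vt))
    if (n_pairs > 0) {
      anchors <- sample.int(nrow(vt), n_pairs)
      offs <- sample(c(-4:-1, 1:4), n_pairs, replace = TRUE)
      newpos <- vt$pos[anchors] + offs
      ok <- newpos >= h & newpos < n - h & !(newpos %in% vt$pos)
      ok <- ok & !duplicated(newpos)
      newpos <- newpos[ok]
      if (length(newpos)) {
        anc2 <- BASES[code[newpos + 1L] + 1L]
        transition_of <- c(A = "G", G = "A", C = "T", T = "C")
        der2 <- unname(transition_of[anc2])
        vt <- dplyr::bind_rows(vt, tibble::tibble(
          chrom = "sim1", pos = as.numeric(newpos), ref = anc2,
          ancestral = anc2, alleles = paste(anc2, der2, sep = ","),
          biallelic = TRUE, derived = der2,
          direction = make_direction(anc2, der2)
        ))
      }
    }
  }

  vt <- dplyr::arrange(vt, .data$pos)
  class(vt) <- c("variant_tbl", class(tibble::tibble()))

  seq <- Biostrings::DNAStringSet(paste(BASES[code + 1L], collapse = ""))
  names(seq) <- "sim1"

  regions <- new_region_mask(tibble::tibble(
    chrom = "sim1", start = as.numeric(p$regions$start),
    end = as.numeric(p$regions$end),
    class = p$regions$class, strand = p$regions$strand
  ))

  list(genome = seq, regions = regions, variants = vt, truth = p$rate_table)
}
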