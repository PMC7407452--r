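# Data-qualification rules: the context-analysis variant filters
# (biallelic, ancestral among alleles, isolated by > `neighborhood` bp,
# inside the mask, strand-oriented), and assembly of the LOCF-adjusted
# block series for the recombination regression.

#' Qualify variants for context analysis
#'
#' Applies the context-model assumptions: a variant is retained only if it
#' is biallelic with the ancestral allele among its alleles, lies inside a
#' mask interval, and has no other variant (qualified or not) within
#' `neighborhood` bp on either side. Every input variant acts as a
#' disqualifier, including variants that themselves fail the other rules.
#' For minus-strand intervals the mutation direction is reverse-complemented
#' so that directions (and, downstream, contexts) are read off the annotated
#' strand of the gene.
#'
#' The operation is idempotent: qualified output carries an `oriented` flag
#' so re-application neither re-complements directions nor removes further
#' variants.
#'
#' @param variants A `variant_tbl`, sorted by (chrom, pos).
#' @param mask A `region_mask`.
#' @param genome Optional `DNAStringSet`; when supplied, variant positions
#'   are checked against sequence bounds.
#' @param neighborhood Disqualification distance in bp (default 4): a
#'   variant is removed iff another variant lies at distance `<=
#'   neighborhood`. Use `neighborhood = 3` for the strict-inequality reading
#'   of a minimum separation of 4.
#' @return The qualified subset of `variants`, with columns `strand`,
#'   `class`, `int_start`, `int_end` describing the containing interval,
#'   direction oriented to the interval strand, and an `oriented` flag.
#' @export
qualify_context_variants <- function(variants, mask, genome = NULL,
                                     neighborhood = 4L) {
  v <- tibble::as_tibble(variants)
  if (nrow(v) > 1) {
    o <- order(v$chrom, v$pos)
    if (!identical(o, seq_len(nrow(v)))) {
      abort("variants must be sorted by (chrom, pos)")
    }
  }
  if (anyDuplicated(v[c("chrom", "pos")])) {
    abort("duplicate variant positions")
  }
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    bad <- is.na(lens[v$chrom]) | v$pos < 0 | v$pos >= lens[v$chrom]
    if (any(bad)) abort("variant outside genome bounds")
  }

  already_oriented <- isTRUE(attr(variants, "oriented")) ||
    ("oriented" %in% names(v) && all(v$oriented))

  # Neighbourhood rule against ALL variants on the same chromosome.
  keep_iso <- unsplit(lapply(split(v$pos, v$chrom), function(pos) {
    n <- length(pos)
    if (n == 1) return(TRUE)
    d_prev <- c(Inf, diff(pos))
    d_next <- c(diff(pos), Inf)
    pmin(d_prev, d_next) > neighborhood
  }), v$chrom)

  v <- v[keep_iso & v$biallelic & !is.na(v$direction), , drop = FALSE]

  # Mask membership: first containing interval wins (mask intervals are
  # merged per class/strand, and a mask is normally restricted to one class
  # before this call).
  m <- tibble::as_tibble(mask)
  if (!nrow(m) || !nrow(v)) {
    out <- v[0, , drop = FALSE]
    out$strand <- character(0); out$class <- character(0)
    out$int_start <- numeric(0); out$int_end <- numeric(0)
    out$oriented <- logical(0)
    return(structure(out, oriented = TRUE,
                     class = c("variant_tbl", class(tibble::tibble()))))
  }
  hit_strand <- rep(NA_character_, nrow(v))
  hit_class <- rep(NA_character_, nrow(v))
  hit_start <- rep(NA_real_, nrow(v))
  hit_end <- rep(NA_real_, nrow(v))
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    mi <- which(m$chrom == ch)
    if (!length(mi)) next
    q <- IRanges::IRanges(start = v$pos[vi] + 1, width = 1)
    s <- IRanges::IRanges(start = m$start[mi] + 1, end = m$end[mi])
    ov <- IRanges::findOverlaps(q, s, select = "first")
    got <- !is.na(ov)
    hit_strand[vi[got]] <- m$strand[mi][ov[got]]
    hit_class[vi[got]] <- m$class[mi][ov[got]]
    hit_start[vi[got]] <- m$start[mi][ov[got]]
    hit_end[vi[got]] <- m$end[mi][ov[got]]
  }
  inside <- !is.na(hit_strand)
  v$strand <- hit_strand
  v$class <- hit_class
  v$int_start <- hit_start
  v$int_end <- hit_end
  v <- v[inside, , drop = FALSE]

  if (!already_oriented && nrow(v)) {
    minus <- v$strand == "-"
    v$direction[minus] <- strand_complement_direction(v$direction[minus])
    v$ancestral[minus] <- chartr("ACGT", "TGCA", v$ancestral[minus])
    v$derived[minus] <- chartr("ACGT", "TGCA", v$derived[minus])
  }
  v$oriented <- TRUE
  structure(v, oriented = TRUE,
            class = c("variant_tbl", class(tibble::tibble())))
}

#' Assemble the analysis-ready block series
#'
#' Counts SNVs per recombination-map block, converts to densities, applies
#' the three exclusion rules (no SNVs reported; block flagged missing by the
#' map; block adjacent to a missing block), and repairs excluded blocks by
#' Last Observation Carried Forward from the nearest non-excluded 5'
#' neighbour so that lags between blocks are preserved. Leading excluded
#' blocks with no 5' neighbour are dropped from the head. A warning (not an
#' error) is raised when the excluded fraction of a chromosome exceeds
#' `warn_fraction`. When a genome is supplied, per-direction densities are
#' added with the count of ancestral-base sites in the block as denominator
#' (per-direction SNV density conditioned on the ancestral allele).
#'
#' @param variants A `variant_tbl` (direction need not be oriented; total
#'   density uses all variants, per-direction densities those with a defined
#'   direction).
#' @param rmap A `recomb_map`.
#' @param genome Optional `DNAStringSet` for per-direction denominators.
#' @param warn_fraction Excluded-fraction warning threshold (default 0.05).
#' @return A tibble of class `"block_series"`: `chrom`, `start`, `rate`,
#'   `density`, per-direction density columns named by direction, flags
#'   `excluded`, `excl_reason`, `locf_applied`, and shadow columns
#'   `rate_obs` / `density_obs` holding pre-LOCF values (NA where never
#'   observed). Attribute `block_size` is carried from the map.
#' @export
build_block_series <- function(variants, rmap, genome = NULL,
                               warn_fraction = 0.05) {
  stopifnot(inherits(rmap, "recomb_map") || all(c("chrom", "start", "rate",
                                                 "missing") %in% names(rmap)))
  bs <- attr(rmap, "block_size") %||% 10000L
  v <- tibble::as_tibble(variants)

  out <- purrr::map_dfr(split(tibble::as_tibble(rmap),
                              tibble::as_tibble(rmap)$chrom), function(mp) {
    mp <- dplyr::arrange(mp, .data$start)
    n <- nrow(mp)
    vi <- v[v$chrom == mp$chrom[1], , drop = FALSE]
    bin <- findInterval(vi$pos, mp$start)
    inblock <- bin >= 1 & vi$pos < mp$start[pmax(bin, 1)] + bs
    counts <- tabulate(bin[inblock], nbins = n)
    density <- counts / bs

    excluded <- rep(FALSE, n)
    reason <- rep(NA_character_, n)
    no_snv <- counts == 0
    miss <- mp$missing
    adj <- (c(FALSE, miss[-n]) | c(miss[-1], FALSE)) & !miss
    excluded[no_snv] <- TRUE; reason[no_snv] <- "no-SNV"
    excluded[adj] <- TRUE; reason[adj] <- "adjacent"
    excluded[miss] <- TRUE; reason[miss] <- "decode-missing"

    frac <- mean(excluded)
    if (frac > warn_fraction) {
      warn(sprintf("%.1f%% of blocks excluded on %s (threshold %.0f%%)",
                   100 * frac, mp$chrom[1], 100 * warn_fraction))
    }

    rate_obs <- ifelse(miss, NA_real_, mp$rate)
    density_obs <- ifelse(miss, NA_real_, density)
    density_obs[excluded & !miss] <- density[excluded & !miss]

    res <- tibble::tibble(
      chrom = mp$chrom, start = mp$start,
      rate = ifelse(excluded, NA_real_, mp$rate),
      density = ifelse(excluded, NA_real_, density),
      excluded = excluded, excl_reason = reason,
      locf_applied = FALSE,
      rate_obs = rate_obs, density_obs = density_obs
    )

    if (!is.null(genome)) {
      seqch <- genome[[mp$chrom[1]]]
      vdir <- vi[inblock & !is.na(vi$direction), , drop = FALSE]
      bdir <- findInterval(vdir$pos, mp$start)
      views <- Biostrings::Views(seqch,
                                 start = pmin(mp$start + 1, length(seqch)),
                                 end = pmin(mp$start + bs, length(seqch)))
      base_counts <- Biostrings::letterFrequency(views, letters = BASES)
      for (d in DIRECTIONS) {
        from <- direction_from(d)
        cnt <- tabulate(bdir[vdir$direction == d], nbins = n)
        denom <- unname(base_counts[, from])
        res[[d]] <- ifelse(denom > 0 & !excluded, cnt / denom, NA_real_)
        res[[d]][excluded] <- NA_real_
      }
    }
    res
  })

  out <- locf_blocks(out)
  structure(tibble::as_tibble(out), block_size = bs,
            class = c("block_series", class(tibble::tibble())))
}

#' Repair a block series by Last Observation Carried Forward
#'
#' Excluded (or simulator-flagged missing) blocks inherit the rate,
#' density and per-direction densities of their nearest non-excluded 5'
#' neighbour, preserving the lag structure of the series; leading blocks
#' with no 5' neighbour are dropped with a message. Called by
#' [build_block_series()], and directly useful for simulator output with
#' injected missingness.
#'
#' @param blocks A `block_series` with an `excluded` or `missing` flag.
#' @return The repaired series with `locf_applied` flags set.
#' @export
locf_blocks <- function(blocks) {
  value_cols <- intersect(c("rate", "density", DIRECTIONS), names(blocks))
  purrr::map_dfr(split(blocks, blocks$chrom), function(b) {
    b <- dplyr::arrange(b, .data$start)
    excl <- if ("excluded" %in% names(b)) b$excluded else b$missing
    first_ok <- which(!excl)[1]
    if (is.na(first_ok)) abort("all blocks excluded on a chromosome")
    if (first_ok > 1) {
      inform(sprintf("dropping %d leading excluded block(s) on %s (no 5' neighbour)",
                     first_ok - 1, b$chrom[1]))
      b <- b[-seq_len(first_ok - 1), , drop = FALSE]
      excl <- excl[-seq_len(first_ok - 1)]
    }
    if (any(excl)) {
      src <- cummax(ifelse(!excl, seq_len(nrow(b)), 0L))
      for (cl in value_cols) b[[cl]][excl] <- b[[cl]][src[excl]]
      b$locf_applied <- excl
    }
    b
  })
}

#' Variance of mean-normalized recombination rates
#'
#' For each chromosome in the map, computes the population variance of the
#' block rates divided by the genome-wide (all-chromosome) mean rate - the
#' per-chromosome heterogeneity measure of the recombination landscape.
#'
#' @param rmap A `recomb_map` (possibly spanning several chromosomes).
#' @param genome_mean Optional mean rate to normalise by; defaults to the
#'   mean over all non-missing blocks in `rmap`.
#' @return A tibble with columns `chrom`, `n_blocks` (non-missing), and
#'   `var_norm_rate`.
#' @export
chromosome_rate_variance <- function(rmap, genome_mean = NULL) {
  rates <- rmap$rate[!rmap$missing]
  if (!length(rates)) abort("all blocks missing")
  gm <- genome_mean %||% mean(rates)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(rmap), .data$chrom),
    n_blocks = sum(!.data$missing),
    var_norm_rate = {
      r <- .data$rate[!.data$missing]
      if (length(r) < 2) abort("need at least 2 non-missing blocks per chromosome")
      pop_var(r / gm)
    },
    .groups = "drop"
  )
}
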