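# The weighted variance in SNV density due to k-mer context, estimated by
# conjugate beta posterior sampling: each cell with s successes of n trials
# contributes Beta(1 + s, 1 + n - s) rate draws, and the weighted variance
# sigma2_k = sum_c p_c (m_c - m_bar)^2 is evaluated per draw. Draws are
# generated from a counter-based per-cell seed stream so adding cells does
# not perturb other cells' draws, and every statistic that combines cells
# regenerates identical per-cell draws.

# Canonical cell index: k-mers in lexicographic order, three directions per
# k-mer ordered by derived base.
cell_index <- function(kmer_idx, dir_rank) (kmer_idx - 1L) * 3L + dir_rank

cell_rbeta <- function(s, n, n_draws, seed, idx) {
  set.seed(derive_seed(seed, idx))
  rbeta(n_draws, 1 + s, 1 + n - s)
}

# Per-kmer cell layout of a context table in canonical order: a list with
# trials, and a draws(kmer_idx) closure returning the 3 x n_draws direction
# draws for that kmer.
table_layout <- function(table) {
  k <- attr(table, "k")
  kmers <- all_kmers(k)
  tbl <- tibble::as_tibble(table)
  tbl$to <- direction_to(tbl$direction)
  ord <- order(match(tbl$kmer, kmers), tbl$to)
  tbl <- tbl[ord, ]
  list(k = k, kmers = kmers,
       weights = attr(table, "weights"),
       s = matrix(tbl$n_variants, nrow = 3),
       n = matrix(tbl$n_contexts, nrow = 3),
       dirs = matrix(tbl$direction, nrow = 3))
}

check_weights <- function(pc, tol = 1e-9) {
  if (abs(sum(pc) - 1) > tol) {
    abort("context weights do not sum to 1 (empty or unpopulated table?)")
  }
}

new_variance_posterior <- function(draws, kind, k, direction = NA_character_,
                                   seed = NA_integer_, extra = list()) {
  structure(
    c(list(draws = pmax(draws, 0), kind = kind, k = k,
           direction = direction, n_draws = length(draws), seed = seed),
      extra),
    class = "variance_posterior"
  )
}

#' Sample per-cell beta posteriors
#'
#' Returns the raw posterior rate draws for every populated cell of a
#' context table: a cell with `s` successes of `n` trials yields
#' `Beta(1 + s, 1 + n - s)` draws (uniform for empty cells - the inflation
#' hazard when many cells have no variants). Draws are independent across
#' cells and reproducible per cell under a fixed seed.
#'
#' @param table A `context_table`.
#' @param n_draws Number of draws per cell.
#' @param seed Integer seed.
#' @param populated_only Drop cells with zero trials (default `TRUE`).
#' @return A matrix with one row per cell (rownames `"kmer|direction"`) and
#'   `n_draws` columns.
#' @export
sample_posteriors <- function(table, n_draws = 10000L, seed = 1L,
                              populated_only = TRUE) {
  stopifnot(n_draws >= 1)
  lay <- table_layout(table)
  nk <- length(lay$kmers)
  keep_kmer <- rep(TRUE, nk)
  if (populated_only) keep_kmer <- lay$n[1, ] > 0
  rows <- list()
  for (i in which(keep_kmer)) {
    for (r in 1:3) {
      rows[[paste0(lay$kmers[i], "|", lay$dirs[r, i])]] <-
        cell_rbeta(lay$s[r, i], lay$n[r, i], n_draws, seed,
                   cell_index(i, r))
    }
  }
  do.call(rbind, rows)
}

#' Total variance in SNV density due to k-mer context
#'
#' Per posterior draw, the per-k-mer SNV rate is the sum of its three
#' direction-cell draws, and the statistic is the weighted variance of
#' these rates over contexts, `sigma2_k = sum_c p_c (m_c - m_bar)^2` with
#' `m_bar = sum_c p_c m_c`.
#'
#' @param table A `context_table`.
#' @param n_draws Number of posterior draws of the statistic.
#' @param seed Integer seed.
#' @return An object of class `"variance_posterior"` (kind `"total"`).
#' @export
variance_total <- function(table, n_draws = 10000L, seed = 1L) {
  lay <- table_layout(table)
  pc <- lay$weights$pc
  check_weights(pc)
  s1 <- numeric(n_draws); s2 <- numeric(n_draws)
  for (i in which(pc > 0)) {
    m <- cell_rbeta(lay$s[1, i], lay$n[1, i], n_draws, seed, cell_index(i, 1L)) +
      cell_rbeta(lay$s[2, i], lay$n[2, i], n_draws, seed, cell_index(i, 2L)) +
      cell_rbeta(lay$s[3, i], lay$n[3, i], n_draws, seed, cell_index(i, 3L))
    s1 <- s1 + pc[i] * m
    s2 <- s2 + pc[i] * m^2
  }
  new_variance_posterior(s2 - s1^2, "total", lay$k, seed = seed,
                         extra = list(m_bar_draws = s1))
}

#' Variance due to context for one mutation direction
#'
#' The direction-partitioned component of the context variance:
#' `sigma2_k(a->b) = sum_(c in C(a)) p_c(a) (m_(c,a->b) - centre)^2`, with
#' weights restricted and renormalised to contexts with central base `a`.
#' Under the default `"direction"` convention the centre is the
#' direction-specific mean `sum p_c(a) m_(c,a->b)` (each component is then a
#' genuine variance); `"literal"` centres at `m_bar_a`, the all-direction
#' SNV rate of central base `a`.
#'
#' @param table A `context_table`.
#' @param direction Direction string such as `"C>T"`.
#' @param convention `"direction"` (default) or `"literal"`.
#' @inheritParams variance_total
#' @return A `"variance_posterior"` (kind `"direction"`).
#' @export
variance_by_direction <- function(table, direction,
                                  convention = c("direction", "literal"),
                                  n_draws = 10000L, seed = 1L) {
  convention <- match.arg(convention)
  if (!direction %in% DIRECTIONS) abort("unknown mutation direction")
  a <- direction_from(direction)
  lay <- table_layout(table)
  sel <- central_base(lay$kmers) == a
  pc_a <- lay$weights$pc[sel]
  if (sum(pc_a) <= 0) abort("no counted contexts with the required central base")
  pc_a <- pc_a / sum(pc_a)
  idxs <- which(sel)
  s1d <- numeric(n_draws); s2d <- numeric(n_draws); s1all <- numeric(n_draws)
  for (j in seq_along(idxs)) {
    i <- idxs[j]
    if (pc_a[j] == 0) next
    dr <- lapply(1:3, function(r) {
      cell_rbeta(lay$s[r, i], lay$n[r, i], n_draws, seed, cell_index(i, r))
    })
    r_tgt <- which(lay$dirs[, i] == direction)
    m_d <- dr[[r_tgt]]
    s1d <- s1d + pc_a[j] * m_d
    s2d <- s2d + pc_a[j] * m_d^2
    if (convention == "literal") {
      s1all <- s1all + pc_a[j] * (dr[[1]] + dr[[2]] + dr[[3]])
    }
  }
  v <- if (convention == "direction") s2d - s1d^2
       else s2d - 2 * s1all * s1d + s1all^2
  new_variance_posterior(v, "direction", lay$k, direction = direction,
                         seed = seed,
                         extra = list(convention = convention,
                                      m_bar_draws = s1d))
}

#' Variance due to flanking context, marginalised over the central base
#'
#' Measures the influence of the flanking nucleotides alone: k-mers sharing
#' the same flanking (k-1)-mer (central base removed) are pooled - trials
#' and variant counts summed over the four central bases and all directions
#' - and the weighted variance of the pooled-bin SNV rates is sampled via
#' the same beta-posterior scheme.
#'
#' @inheritParams variance_total
#' @return A `"variance_posterior"` (kind `"marginalised"`).
#' @export
variance_marginalised <- function(table, n_draws = 10000L, seed = 1L) {
  lay <- table_layout(table)
  if (lay$k < 3) abort("marginalisation requires k >= 3 (no flanks at k = 1)")
  h <- (lay$k - 1L) %/% 2L
  flank <- paste0(substr(lay$kmers, 1, h),
                  substr(lay$kmers, h + 2L, lay$k))
  bins <- sort(unique(flank))
  trials <- tapply(lay$weights$n_sites, flank, sum)[bins]
  succ <- tapply(colSums(lay$s), flank, sum)[bins]
  pb <- tapply(lay$weights$pc, flank, sum)[bins]
  check_weights(pb)
  offset <- 3L * length(lay$kmers)  # own seed namespace
  s1 <- numeric(n_draws); s2 <- numeric(n_draws)
  for (j in seq_along(bins)) {
    if (pb[j] == 0) next
    m <- cell_rbeta(succ[j], trials[j], n_draws, seed, offset + j)
    s1 <- s1 + pb[j] * m
    s2 <- s2 + pb[j] * m^2
  }
  new_variance_posterior(s2 - s1^2, "marginalised", lay$k, seed = seed,
                         extra = list(m_bar_draws = s1))
}

#' CpG contribution to the context variance
#'
#' Splits the total context variance `sigma2_k` into the contribution of
#' CpG-defined contexts and the rest: the subset sum
#' `sum_(c in CpG) p_c (m_c - m_bar)^2` with `m_bar` the global weighted
#' mean, and its share of `sigma2_k`. Under the default `"cpg"` orientation
#' the subset is central C with 3' G plus central G with 5' C;
#' `"gpc-literal"` uses the transposed reading (central C with 5' G,
#' central G with 3' C).
#'
#' @inheritParams variance_total
#' @param orientation `"cpg"` (default) or `"gpc-literal"`.
#' @return A `"variance_posterior"` (kind `"cpg"`) whose draws are the
#'   subset contribution, with extra elements `share_draws`
#'   (contribution / total per draw), `total_draws` and `weight_mass` (the
#'   p_c mass of the subset).
#' @export
variance_cpg <- function(table, n_draws = 10000L, seed = 1L,
                         orientation = c("cpg", "gpc-literal")) {
  orientation <- match.arg(orientation)
  lay <- table_layout(table)
  if (lay$k < 3) abort("CpG conditioning requires k >= 3")
  h <- (lay$k - 1L) %/% 2L
  centr <- central_base(lay$kmers)
  five <- substr(lay$kmers, h, h)
  three <- substr(lay$kmers, h + 2L, h + 2L)
  subset <- if (orientation == "cpg") {
    (centr == "C" & three == "G") | (centr == "G" & five == "C")
  } else {
    (centr == "C" & five == "G") | (centr == "G" & three == "C")
  }
  pc <- lay$weights$pc
  check_weights(pc)
  s1 <- numeric(n_draws); s2 <- numeric(n_draws)
  s1s <- numeric(n_draws); s2s <- numeric(n_draws)
  for (i in which(pc > 0)) {
    m <- cell_rbeta(lay$s[1, i], lay$n[1, i], n_draws, seed, cell_index(i, 1L)) +
      cell_rbeta(lay$s[2, i], lay$n[2, i], n_draws, seed, cell_index(i, 2L)) +
      cell_rbeta(lay$s[3, i], lay$n[3, i], n_draws, seed, cell_index(i, 3L))
    s1 <- s1 + pc[i] * m
    s2 <- s2 + pc[i] * m^2
    if (subset[i]) {
      s1s <- s1s + pc[i] * m
      s2s <- s2s + pc[i] * m^2
    }
  }
  p_sub <- sum(pc[subset])
  total <- pmax(s2 - s1^2, 0)
  contrib <- pmax(s2s - 2 * s1 * s1s + s1^2 * p_sub, 0)
  new_variance_posterior(contrib, "cpg", lay$k, seed = seed,
                         extra = list(share_draws = contrib / total,
                                      total_draws = total,
                                      weight_mass = p_sub,
                                      orientation = orientation))
}

#' Strand-asymmetry criterion for a pair of direction posteriors
#'
#' Rejects strand symmetry when the 97.5 percentile of one of a pair of
#' strand-complementary mutation directions lies below the 2.5 percentile
#' of the other.
#'
#' @param post_a,post_b `"variance_posterior"` objects of the same kind and
#'   k, for strand-complementary directions.
#' @return A list of class `"strand_asymmetry"` with the verdict and the
#'   four percentiles.
#' @export
strand_asymmetry <- function(post_a, post_b) {
  stopifnot(inherits(post_a, "variance_posterior"),
            inherits(post_b, "variance_posterior"))
  if (post_a$k != post_b$k) abort("posteriors computed at different k")
  if (!identical(post_a$kind, post_b$kind)) {
    abort("posteriors of different statistic kinds")
  }
  if (!is.na(post_a$direction) && !is.na(post_b$direction) &&
      strand_complement_direction(post_a$direction) != post_b$direction) {
    abort("directions are not strand complements")
  }
  qa <- quantile(post_a$draws, c(0.025, 0.975), names = FALSE)
  qb <- quantile(post_b$draws, c(0.025, 0.975), names = FALSE)
  asym <- qa[2] < qb[1] || qb[2] < qa[1]
  structure(
    list(asymmetric = asym,
         direction_a = post_a$direction, direction_b = post_b$direction,
         k = post_a$k,
         q2.5_a = qa[1], q97.5_a = qa[2], q2.5_b = qb[1], q97.5_b = qb[2]),
    class = "strand_asymmetry"
  )
}

#' @export
print.strand_asymmetry <- function(x, ...) {
  cat(sprintf(
    "Strand asymmetry (%s vs %s, k = %d): %s\n  [2.5, 97.5]%%: %s = [%.3g, %.3g]; %s = [%.3g, %.3g]\n",
    x$direction_a, x$direction_b, x$k,
    if (x$asymmetric) "ASYMMETRIC" else "symmetric",
    x$direction_a, x$q2.5_a, x$q97.5_a, x$direction_b, x$q2.5_b, x$q97.5_b))
  invisible(x)
}

#' @export
print.variance_posterior <- function(x, ...) {
  lbl <- if (is.na(x$direction)) x$kind else paste0(x$kind, " ", x$direction)
  q <- quantile(x$draws, c(0.025, 0.975), names = FALSE)
  cat(sprintf("Context-variance posterior (%s, k = %d): mean %.4g, 95%% CI [%.4g, %.4g], %d draws\n",
              lbl, x$k, mean(x$draws), q[1], q[2], x$n_draws))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.variance_posterior <- function(x, ...) {
  q <- quantile(x$draws, c(0.025, 0.975), names = FALSE)
  tibble::tibble(kind = x$kind, k = x$k, direction = x$direction,
                 mean = mean(x$draws), lower95 = q[1], upper95 = q[2],
                 n_draws = x$n_draws)
}

#' Percentile accessor for a variance posterior
#'
#' @param x A `"variance_posterior"`.
#' @param q Percentile(s) in `[0, 100]`.
#' @return Numeric percentile values.
#' @export
percentile <- function(x, q) {
  stopifnot(inherits(x, "variance_posterior"))
  quantile(x$draws, q / 100, names = FALSE)
}

#' Closed-form context variance of a ground-truth rate table
#'
#' The infinite-data limit of the context-variance statistics: the weighted
#' variance computed directly from known per-cell polymorphism
#' probabilities rather than sampled rates. Used for truth comparisons in
#' parameter-recovery studies.
#'
#' @param rate_table A [context_rate_table()].
#' @param weights Optional `context_weights` (defaults to uniform weights
#'   over all k-mers).
#' @param kind `"total"`, `"direction"`, `"marginalised"` or `"cpg"` (for
#'   `"cpg"` the value returned is the subset contribution; the share is in
#'   the `"share"` attribute).
#' @param direction Direction for `kind = "direction"`.
#' @param convention Centre convention for `kind = "direction"`.
#' @param orientation Subset orientation for `kind = "cpg"`.
#' @return The variance (a scalar).
#' @export
true_context_variance <- function(rate_table, weights = NULL,
                                  kind = c("total", "direction",
                                           "marginalised", "cpg"),
                                  direction = NULL,
                                  convention = c("direction", "literal"),
                                  orientation = c("cpg", "gpc-literal")) {
  kind <- match.arg(kind)
  convention <- match.arg(convention)
  orientation <- match.arg(orientation)
  k <- attr(rate_table, "k")
  kmers <- all_kmers(k)
  pc <- if (is.null(weights)) {
    setNames(rep(1 / length(kmers), length(kmers)), kmers)
  } else {
    setNames(weights$pc, weights$kmer)[kmers]
  }
  per_dir <- matrix(0, length(kmers), 4, dimnames = list(kmers, BASES))
  per_dir[cbind(match(rate_table$kmer, kmers),
                match(direction_to(rate_table$direction), BASES))] <-
    rate_table$prob
  m_tot <- rowSums(per_dir)

  if (kind == "total") {
    mb <- sum(pc * m_tot)
    return(sum(pc * (m_tot - mb)^2))
  }
  if (kind == "direction") {
    a <- direction_from(direction)
    sel <- central_base(kmers) == a
    pa <- pc[sel] / sum(pc[sel])
    md <- per_dir[sel, direction_to(direction)]
    centre <- if (convention == "direction") sum(pa * md)
              else sum(pa * m_tot[sel])
    return(sum(pa * (md - centre)^2))
  }
  if (kind == "marginalised") {
    h <- (k - 1L) %/% 2L
    flank <- paste0(substr(kmers, 1, h), substr(kmers, h + 2L, k))
    pb <- tapply(pc, flank, sum)
    mb_bin <- tapply(pc * m_tot, flank, sum) / pb
    mb_bin[pb == 0] <- 0
    mbar <- sum(pb * mb_bin)
    return(sum(pb * (mb_bin - mbar)^2))
  }
  # cpg
  h <- (k - 1L) %/% 2L
  centr <- central_base(kmers)
  five <- substr(kmers, h, h); three <- substr(kmers, h + 2L, h + 2L)
  subset <- if (orientation == "cpg") {
    (centr == "C" & three == "G") | (centr == "G" & five == "C")
  } else {
    (centr == "C" & five == "G") | (centr == "G" & three == "C")
  }
  mb <- sum(pc * m_tot)
  contrib <- sum(pc[subset] * (m_tot[subset] - mb)^2)
  total <- sum(pc * (m_tot - mb)^2)
  structure(contrib, share = contrib / total)
}
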