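# Context counting, cell tallies, beta-posterior sampling and the weighted
# variance statistics (total, per-direction, marginalised, CpG, strand
# asymmetry).

test_that("context counting enumerates interior windows, per strand", {
  g <- toy_genome("ACGT")
  cw <- count_contexts(g, toy_mask("chr1", 0, 4), k = 3)
  expect_equal(sum(cw$n_sites), 2)
  expect_equal(cw$pc[cw$kmer %in% c("ACG", "CGT")], c(0.5, 0.5))

  # minus strand counts the reverse complement
  cw <- count_contexts(g, toy_mask("chr1", 0, 4, strand = "-"), k = 3)
  expect_equal(cw$pc[cw$kmer %in% c("ACG", "CGT")], c(0.5, 0.5))
  g2 <- toy_genome("AAAC")
  cw <- count_contexts(g2, toy_mask("chr1", 0, 4, strand = "-"), k = 3)
  expect_equal(cw$n_sites[cw$kmer == "GTT"], 1)
  expect_equal(cw$n_sites[cw$kmer == "TTT"], 1)

  # windows containing N are skipped
  gn <- toy_genome("ACNGT")
  cw <- count_contexts(gn, toy_mask("chr1", 0, 5), k = 3)
  expect_equal(sum(cw$n_sites), 0)

  expect_error(count_contexts(g, toy_mask("chr1", 0, 4), k = 2), "odd")
})

test_that("k-mer frequencies on a uniform random genome are uniform", {
  g <- random_genome(4e6, seed = 13)
  cw <- count_contexts(g, toy_mask("chr1", 0, 4e6), k = 3)
  p_hat <- cw$pc
  sd_bin <- sqrt((1 / 64) * (63 / 64) / sum(cw$n_sites))
  expect_true(all(abs(p_hat - 1 / 64) < 3.5 * sd_bin))
})

test_that("cell tallies perform exact bookkeeping", {
  g <- toy_genome("TTACGTT")
  mask <- toy_mask("chr1", 0, 7)
  v <- toy_variants(3, "C", "T")   # C of ACG, 0-based position 3
  q <- qualify_context_variants(v, mask, genome = g)
  tab <- tally_cells(q, g, mask, k = 3)
  expect_equal(tab$n_variants[tab$kmer == "ACG" & tab$direction == "C>T"], 1)
  expect_equal(sum(tab$n_variants), 1)
  expect_equal(tab$n_contexts[tab$kmer == "ACG"][1], 1)

  # empty mask: zero trials everywhere, downstream variance errors
  empty <- toy_mask(character(0), numeric(0), numeric(0))
  tab0 <- tally_cells(q[0, ], g, empty, k = 3)
  expect_equal(sum(tab0$n_contexts), 0)
  expect_error(variance_total(tab0), "weights")
})

test_that("an ancestral/genome mismatch above threshold errors", {
  g <- toy_genome("TTACGTTTTTTTTTT")
  mask <- toy_mask("chr1", 0, 15)
  v <- toy_variants(3, "T", "C")   # claims T, genome has C
  q <- qualify_context_variants(v, mask, genome = g)
  expect_error(tally_cells(q, g, mask, k = 3), "disagree")
})

test_that("cell rates converge to truth on a simulated genome", {
  rt <- context_rate_table(k = 3, base_rate = 5e-4, transition_mult = 3,
                           cpg_mult = 6)
  sim <- simulate_genome(genome_sim_params(length = 3e6, rate_table = rt,
                                           seed = 14))
  q <- qualify_context_variants(sim$variants, sim$regions,
                                genome = sim$genome)
  tab <- suppressWarnings(tally_cells(q, sim$genome, sim$regions, k = 3))
  joined <- dplyr::inner_join(tibble::as_tibble(tab),
                              tibble::as_tibble(rt),
                              by = c("kmer", "direction"))
  big <- joined[joined$n_contexts >= 1000, ]
  dev <- abs(big$n_variants / big$n_contexts - big$prob)
  sd_bin <- sqrt(big$prob * (1 - big$prob) / big$n_contexts)
  expect_lt(max(dev / sd_bin), 5)
})

test_that("beta conjugacy closed forms hold for sampled posteriors", {
  tab <- context_table(tibble::tibble(
    kmer = c("ACA", "ACA", "AGA"),
    direction = c("C>T", "C>G", "G>A"),
    n_contexts = c(2, 2, 1e6),
    n_variants = c(1, 0, 1e3)
  ))
  dr <- sample_posteriors(tab, n_draws = 1e5, seed = 3)
  # (n=2, s=1) -> Beta(2, 2), mean 1/2
  expect_equal(mean(dr["ACA|C>T", ]), 0.5, tolerance = 0.01)
  # (n=1e6, s=1e3) concentrates at 1e-3
  expect_lt(abs(mean(dr["AGA|G>A", ]) - 1e-3), 1e-4)
  # empty cell -> Beta(1,1) uniform: the inflation hazard
  tab0 <- context_table(tibble::tibble(
    kmer = "ACA", direction = "C>T", n_contexts = 0, n_variants = 0
  ))
  dr0 <- sample_posteriors(tab0, n_draws = 1e5, seed = 4,
                           populated_only = FALSE)
  expect_equal(mean(dr0["ACA|C>T", ]), 0.5, tolerance = 0.01)
  expect_equal(var(dr0["ACA|C>T", ]), 1 / 12, tolerance = 0.01)
})

test_that("hand-computed weighted variances are reproduced", {
  # two contexts pc = 0.5/0.5 with fixed rates 0.1/0.3: sigma2 = 0.01.
  # Enormous trial counts pin the beta posteriors to the rates.
  tab <- context_table(tibble::tibble(
    kmer = c("ACA", "ACA", "ACA", "GCG", "GCG", "GCG"),
    direction = rep(c("C>T", "C>G", "C>A"), 2),
    n_contexts = 1e8,
    n_variants = c(0.1e8, 0, 0, 0.3e8, 0, 0)
  ))
  vt <- variance_total(tab, n_draws = 400, seed = 5)
  expect_equal(mean(vt$draws), 0.01, tolerance = 2e-4)
  expect_equal(mean(vt$m_bar_draws), 0.2, tolerance = 2e-3)

  # all contexts sharing one rate: sigma2 ~ 0 every draw
  tab_eq <- context_table(tibble::tibble(
    kmer = c("ACA", "GCG"), direction = "C>T",
    n_contexts = 1e8, n_variants = 0.2e8
  ))
  vt0 <- variance_total(tab_eq, n_draws = 400, seed = 6)
  expect_lt(max(vt0$draws), 1e-6)
})

test_that("per-direction variance honours both centring conventions", {
  # two C-centred contexts, pc(C) = 0.5/0.5, C>T rates 0.02/0.04
  tab <- context_table(tibble::tibble(
    kmer = c("ACA", "ACA", "ACA", "GCG", "GCG", "GCG"),
    direction = rep(c("C>T", "C>G", "C>A"), 2),
    n_contexts = 1e8,
    n_variants = c(0.02e8, 0.015e8, 0.015e8, 0.04e8, 0.005e8, 0.005e8)
  ))
  vd <- variance_by_direction(tab, "C>T", n_draws = 400, seed = 7)
  expect_lt(abs(mean(vd$draws) - 1e-4), 5e-6)

  # literal convention centres at m_bar_C = 0.05 here:
  # 0.5 (0.02 - 0.05)^2 + 0.5 (0.04 - 0.05)^2 = 5e-4
  vl <- variance_by_direction(tab, "C>T", convention = "literal",
                              n_draws = 400, seed = 7)
  expect_lt(abs(mean(vl$draws) - 5e-4), 2e-5)

  # k = 1: a single context per direction, direction convention -> 0
  tab1 <- context_table(tibble::tibble(
    kmer = "C", direction = "C>T", n_contexts = 1e8, n_variants = 0.02e8
  ), k = 1)
  v1 <- variance_by_direction(tab1, "C>T", n_draws = 200, seed = 8)
  expect_lt(mean(v1$draws), 1e-8)

  expect_error(variance_by_direction(tab, "C>C"), "direction")
})

test_that("posterior mean of sigma2_k matches a brute-force Monte Carlo", {
  # <= 16-cell toy table; independent beta sampling straight from
  # definitions, different RNG stream
  set.seed(99)
  counts <- tibble::tibble(
    kmer = rep(c("ACA", "CCT", "GCG", "TCT"), each = 3),
    direction = rep(c("C>T", "C>G", "C>A"), 4),
    n_contexts = rep(c(4000, 1000, 2500, 600), each = 3),
    n_variants = c(40, 3, 1, 11, 2, 0, 90, 12, 4, 5, 0, 1)
  )
  tab <- context_table(counts)
  vt <- variance_total(tab, n_draws = 20000, seed = 9)

  B <- 20000
  km <- unique(counts$kmer)
  n_k <- counts$n_contexts[match(km, counts$kmer)]
  pc <- n_k / sum(n_k)
  m <- matrix(0, B, length(km))
  for (j in seq_along(km)) {
    rows <- counts[counts$kmer == km[j], ]
    for (r in seq_len(nrow(rows))) {
      m[, j] <- m[, j] + rbeta(B, 1 + rows$n_variants[r],
                               1 + rows$n_contexts[r] - rows$n_variants[r])
    }
  }
  mbar <- as.numeric(m %*% pc)
  sig2 <- as.numeric((m^2) %*% pc) - mbar^2
  mc_se <- sd(sig2) / sqrt(B)
  expect_lt(abs(mean(vt$draws) - mean(sig2)), 3 * mc_se)
})

test_that("sampled variance agrees with the truth table on a simulated genome", {
  # small rates keep filter thinning negligible
  rt <- context_rate_table(k = 3, base_rate = 3e-4, cpg_mult = 10)
  sim <- simulate_genome(genome_sim_params(length = 4e6, rate_table = rt,
                                           seed = 15))
  q <- qualify_context_variants(sim$variants, sim$regions,
                                genome = sim$genome)
  tab <- suppressWarnings(tally_cells(q, sim$genome, sim$regions, k = 3))
  vt <- variance_total(tab, n_draws = 4000, seed = 16)
  truth <- true_context_variance(rt, attr(tab, "weights"))
  expect_lt(abs(mean(vt$draws) - truth), 3 * sd(vt$draws))
})

test_that("marginalised variance isolates flank effects", {
  # rates depending only on the central base (C/G totals elevated over
  # A/T): flank signal is zero but total variance is not
  rt0 <- context_rate_table(k = 3, base_rate = 0.002, transition_mult = 3,
                            cpg_mult = 1,
                            asymmetry = c("C>T" = 3, "G>A" = 3))
  expect_equal(true_context_variance(rt0, kind = "marginalised"), 0,
               tolerance = 1e-18)
  expect_gt(true_context_variance(rt0, kind = "total"), 1e-6)
  sim <- simulate_genome(genome_sim_params(length = 1e6, rate_table = rt0,
                                           seed = 17))
  q <- qualify_context_variants(sim$variants, sim$regions,
                                genome = sim$genome)
  tab <- tally_cells(q, sim$genome, sim$regions, k = 3)
  vm <- variance_marginalised(tab, n_draws = 2000, seed = 18)
  vt <- variance_total(tab, n_draws = 2000, seed = 18)
  expect_lt(mean(vm$draws), mean(vt$draws) / 5)

  # rates depending only on the 5' neighbour, two equal-frequency classes
  # at rates r and r * mult: marginalised sigma2 = delta^2 (small rates
  # keep the neighbourhood-filter thinning negligible)
  b <- 5e-4; mult <- 3
  rt1 <- context_rate_table(k = 3, base_rate = b, transition_mult = 1,
                            cpg_mult = 1,
                            neighbor_effects = data.frame(
                              offset = -1, base = "A", mult = mult))
  freq <- c(A = 0.5, C = 1 / 6, G = 1 / 6, T = 1 / 6)
  sim <- simulate_genome(genome_sim_params(length = 4e6, base_freq = freq,
                                           rate_table = rt1, seed = 19))
  q <- qualify_context_variants(sim$variants, sim$regions,
                                genome = sim$genome)
  tab <- tally_cells(q, sim$genome, sim$regions, k = 3)
  vm <- variance_marginalised(tab, n_draws = 2000, seed = 20)
  delta <- 3 * b * (mult - 1) / 2
  expect_equal(mean(vm$draws), delta^2, tolerance = 0.15)

  expect_error(variance_marginalised(context_table(tibble::tibble(
    kmer = "C", direction = "C>T", n_contexts = 10, n_variants = 1
  ), k = 1)), "k >= 3")
})

test_that("marginalised variance never exceeds total variance", {
  for (seed in c(21, 22, 23)) {
    rt <- context_rate_table(k = 3, base_rate = 0.001,
                             cpg_mult = c(4, 10, 1)[seed - 20],
                             neighbor_effects = if (seed == 23)
                               data.frame(offset = 1, base = "T", mult = 2)
                             else NULL)
    sim <- simulate_genome(genome_sim_params(length = 1e6, rate_table = rt,
                                             seed = seed))
    q <- qualify_context_variants(sim$variants, sim$regions,
                                  genome = sim$genome)
    tab <- suppressWarnings(tally_cells(q, sim$genome, sim$regions, k = 3))
    vm <- variance_marginalised(tab, n_draws = 1500, seed = seed)
    vt <- variance_total(tab, n_draws = 1500, seed = seed)
    expect_lt(mean(vm$draws), mean(vt$draws))
  }
})

test_that("CpG conditioning isolates the CpG share of the variance", {
  # null: multiplier 1 -> the CpG share reflects only its weight mass
  rt0 <- context_rate_table(k = 3, base_rate = 0.002, transition_mult = 1,
                            cpg_mult = 1)
  sim <- simulate_genome(genome_sim_params(length = 1e6, rate_table = rt0,
                                           seed = 24))
  q <- qualify_context_variants(sim$variants, sim$regions,
                                genome = sim$genome)
  tab <- tally_cells(q, sim$genome, sim$regions, k = 3)
  v0 <- variance_cpg(tab, n_draws = 2000, seed = 25)
  expect_lt(mean(v0$share_draws), 3 * v0$weight_mass)

  # dominant effect: multiplier 25 -> CpG cells carry most of sigma2_3
  rt1 <- context_rate_table(k = 3, base_rate = 0.002, cpg_mult = 25)
  sim <- simulate_genome(genome_sim_params(length = 1e6, rate_table = rt1,
                                           seed = 26))
  q <- qualify_context_variants(sim$variants, sim$regions,
                                genome = sim$genome)
  tab <- tally_cells(q, sim$genome, sim$regions, k = 3)
  v1 <- variance_cpg(tab, n_draws = 2000, seed = 27)
  expect_gt(mean(v1$share_draws), 0.5)

  # subset + complement weights partition the whole mass
  w <- attr(tab, "weights")
  centr <- substr(w$kmer, 2, 2)
  cpg <- (centr == "C" & substr(w$kmer, 3, 3) == "G") |
    (centr == "G" & substr(w$kmer, 1, 1) == "C")
  expect_equal(sum(w$pc[cpg]) + sum(w$pc[!cpg]), 1, tolerance = 1e-12)
  expect_equal(v1$weight_mass, sum(w$pc[cpg]), tolerance = 1e-12)

  # the literal (GpC) orientation selects the transposed subset
  v_lit <- variance_cpg(tab, n_draws = 200, seed = 28,
                        orientation = "gpc-literal")
  gpc <- (centr == "C" & substr(w$kmer, 1, 1) == "G") |
    (centr == "G" & substr(w$kmer, 3, 3) == "C")
  expect_equal(v_lit$weight_mass, sum(w$pc[gpc]), tolerance = 1e-12)
})

test_that("strand-asymmetry verdicts follow the percentile criterion", {
  mk <- function(draws, dir) {
    structure(list(draws = draws, kind = "direction", k = 3,
                   direction = dir, n_draws = length(draws), seed = 1),
              class = "variance_posterior")
  }
  a <- mk(rep(1e-4, 100) + seq(0, 1e-6, length.out = 100), "T>C")
  expect_false(strand_asymmetry(a, mk(a$draws, "A>G"))$asymmetric)
  b <- mk(rep(4e-4, 100) + seq(0, 1e-6, length.out = 100), "A>G")
  expect_true(strand_asymmetry(a, b)$asymmetric)
  expect_error(strand_asymmetry(a, mk(b$draws, "G>A")), "complement")
  b5 <- mk(b$draws, "A>G"); b5$k <- 5
  expect_error(strand_asymmetry(a, b5), "different k")
})

test_that("mean decomposition and variance monotonicity hold on truth tables", {
  rt <- context_rate_table(k = 5, base_rate = 0.002, transition_mult = 3,
                           cpg_mult = 8,
                           neighbor_effects = data.frame(
                             offset = c(-1, 2), base = c("T", "A"),
                             mult = c(1.6, 1.3)))
  freq <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)
  pc <- kmer_weights_from_freq(5, freq)

  kmers <- names(pc)
  m_tot <- vapply(kmers, function(km) sum(rt$prob[rt$kmer == km]),
                  numeric(1))
  # law of total probability: the weighted mean is scale-invariant
  m5 <- sum(pc * m_tot)
  for (to_k in c(3, 1)) {
    trim <- (5 - to_k) / 2
    grp <- substr(kmers, trim + 1, 5 - trim)
    mg <- tapply(pc * m_tot, grp, sum) / tapply(pc, grp, sum)
    expect_equal(sum(tapply(pc, grp, sum) * mg), m5, tolerance = 1e-12)
  }

  # coarser partitions cannot have larger between-group variance
  s5 <- brute_force_weighted_variance(m_tot, pc)
  s3 <- collapse_truth_variance(rt, pc, 3)
  s1 <- collapse_truth_variance(rt, pc, 1)
  expect_lte(s1, s3 + 1e-15)
  expect_lte(s3, s5 + 1e-15)
  expect_gt(s3, s1)   # the constructed table has genuine neighbour signal
})

test_that("identical seeds give identical draws and percentile reports", {
  tab <- context_table(tibble::tibble(
    kmer = c("ACA", "GCG"), direction = "C>T",
    n_contexts = c(5000, 3000), n_variants = c(50, 90)
  ))
  v1 <- variance_total(tab, n_draws = 1000, seed = 11)
  v2 <- variance_total(tab, n_draws = 1000, seed = 11)
  expect_identical(v1$draws, v2$draws)
  expect_identical(percentile(v1, c(2.5, 97.5)), percentile(v2, c(2.5, 97.5)))
  v3 <- variance_total(tab, n_draws = 1000, seed = 12)
  expect_false(identical(v1$draws, v3$draws))
})
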