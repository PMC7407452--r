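# mutvar

Quantifying influences on the intragenomic mutation rate from population
variation data.

Two forces dominate the fine-scale heterogeneity of the human germline
mutation rate: meiotic recombination, and the local sequence context of the
mutating base (most famously the CpG effect). `mutvar` implements a
consistent statistical framework for measuring both from single nucleotide
variant (SNV) densities, for population geneticists working with per-block
recombination maps (deCODE-style), variant tables with ancestral-allele
annotation (VCF `AA` key), genome FASTA and region masks (BED6).

## The two estimators

**Recombination.** Per 10-kb block *i*, SNV density is modelled as

    density_i = alpha + beta * rate_i + eps_i,    eps ~ ARMA(p, q)

where `rate_i` is the standardized recombination rate of the block.
Because mutation and recombination rates are spatially autocorrelated
along the genome, the residuals are modelled as an autoregressive
moving-average process; the order (p, q) is chosen by AIC over a grid
(after an augmented Dickey–Fuller stationarity check), and alpha, beta and
the p+q ARMA coefficients are estimated *jointly* by Bayesian MCMC
(adaptive random-walk Metropolis). Missing blocks are repaired by
last-observation-carried-forward (LOCF) so the lag structure survives.
From the posterior the package derives, per draw:

* `sigma2_rec` — variance in SNV density due to recombination,
  `Var(density) − mean(residual²)` (negative when the fit is worse than a
  flat line), and `R² = sigma2_rec / Var(density)`;
* `rho_hat = (m̄ − alpha) / m̄` — the proportion of SNVs attributable to
  recombination, with `m̄` the mean SNV density;
* `mutations_per_crossover = rho_hat · mu / xover`, converting that
  proportion into the expected number of mutations caused by one
  recombination event (defaults `mu = 1.19e-8`, `xover = 1.16e-8` per bp
  per generation);
* the posterior probability that the slope is ≤ 0, the evidence criterion
  for a per-direction effect of recombination.

**Sequence context.** For odd k, every site's k-mer context `c` has a
known weight `p_c` (contexts are counted exactly over the mask) and an
unknown polymorphism probability `m_c`. Each (k-mer, mutation-direction)
cell is a binomial — trials = k-mer occurrences, successes = qualified
variants — with a conjugate Beta(1, 1) prior, so the posterior is
Beta(1+s, 1+n−s). Sampling every cell and applying

    sigma2_k = sum_c p_c (m_c − m̄)²,   m̄ = sum_c p_c m_c

per draw yields the posterior of the variance in SNV density due to
context, in total, per mutation direction, marginalised over the central
base (flank-only signal), conditioned on CpG status, and with a
percentile-overlap criterion for strand asymmetry. Variants qualify only
if biallelic, ancestral-consistent, and ≥ 5 bp from any other variant;
minus-strand genic intervals are read on the annotated strand.

A synthetic-data module generates block series and genomes with known
ground truth (rate→density slope, ARMA residuals, k-mer rate tables with
CpG/neighbour/asymmetry effects, multiallelic and clustered variants), and
writes them through the same on-disk formats the readers consume, so every
estimator has a parameter-recovery test.

## Worked example

```r
library(mutvar)

# --- recombination: simulate 5,000 blocks with known truth and fit
sim    <- simulate_blocks(block_sim_params(n_blocks = 5000, seed = 1))
blocks <- locf_blocks(sim$blocks)
ana    <- analyze_recombination(blocks, p_max = 2, q_max = 2, seed = 1)
ana
#> ADF test: tau = -14.857, p ~ 0.010 (17 lags, n = 5000) -> stationary
#> ARMA order selection: chosen (p, q) = (2, 0) at AIC rank 1; 6/6 grid fits converged
#> Recombination summary (density; ARMA(2,0) errors; m_bar = 0.033039, observed)
#> P(slope <= 0) = 0.0000
#> # A tibble: 8 x 4
#>   quantity                          mean     lower95     upper95
#>   <chr>                            <dbl>       <dbl>       <dbl>
#> 1 alpha                      0.0260      0.0258      0.0263
#> 2 beta                       0.00700     0.00695     0.00705
#> 3 sigma2_rec                 0.000146    0.000146    0.000146
#> 4 R2                         0.878       0.878       0.878
#> 5 rho_hat                    0.212       0.205       0.219
#> 6 mutations_per_crossover    0.217       0.210       0.225
#> 7 slope_per_cM               0.603       0.599       0.607
#> 8 slope_mutation_rate_per_cM 0.000000217 0.000000216 0.000000219
```

The generator's truth was `alpha = 0.026` and `beta = 0.007`; both
posterior means land on the truth and the 95% credibility intervals cover
it. `rho_hat = 0.212` says that, in this synthetic genome where
recombination genuinely drives density, 21% of SNVs are attributable to
recombination; `R² = 0.878` is the share of block-to-block density
variance the regression explains.

```r
# --- context: simulate a 2 Mb genome with a 10x CpG effect at k = 3
rt  <- context_rate_table(k = 3, base_rate = 5e-4, cpg_mult = 10)
g   <- simulate_genome(genome_sim_params(length = 2e6, rate_table = rt, seed = 2))
q   <- qualify_context_variants(g$variants, g$regions, genome = g$genome)
tab <- tally_cells(q, g$genome, g$regions, k = 3)

variance_total(tab, n_draws = 5000, seed = 3)
#> Context-variance posterior (total, k = 3): mean 1.159e-05,
#>   95% CI [1.053e-05, 1.273e-05], 5000 draws

vc <- variance_cpg(tab, n_draws = 5000, seed = 3)
mean(vc$share_draws)
#> 0.91   # ~91% of sigma2_3 is carried by CpG-defined contexts
```

With a 10-fold CpG multiplier as the only context effect, essentially all
of the 3-mer variance is the CpG effect, as it should be. Result objects
have `tidy()`, `glance()` and `autoplot()` methods; `run_pipeline()`
drives simulate → write → read-back → filter → fit → report from a single
config (R list or YAML) with a provenance sidecar per output.

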