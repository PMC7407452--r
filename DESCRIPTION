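Package: mutvar
Title: Variance in SNV Density Due to Recombination and Sequence Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies influences on the intragenomic mutation rate from
    population variation data. Fits a Bayesian linear regression of per-block
    single nucleotide variant (SNV) density on standardized recombination rate
    with ARMA-modelled residuals (joint MCMC over slope, intercept and ARMA
    coefficients), and derives the variance in SNV density due to
    recombination, the proportion of SNVs attributable to recombination, and
    the expected number of mutations per crossover. Separately, estimates the
    variance in SNV density due to k-mer sequence context by conjugate
    beta-binomial posterior sampling over per-context mutation counts, in
    total, per mutation direction, marginalised over the central base,
    conditioned on CpG status, and with a strand-asymmetry criterion. Includes
    readers for recombination maps, VCF variants, FASTA genomes and BED
    region masks, and a synthetic-data generator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
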