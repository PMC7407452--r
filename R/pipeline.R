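# Pipeline orchestration: one config (R list or YAML file) drives
# simulate -> write -> read-back -> filter -> fit / variance -> report,
# with a provenance sidecar for every output and deterministic behaviour
# under a fixed seed. Simulated inputs are round-tripped through the
# on-disk formats so the real I/O path is exercised, not bypassed.

#' Run an end-to-end analysis pipeline
#'
#' Executes the stage graph described by `config`:
#'
#' * `blocks`: simulate a block series ([simulate_blocks()]), write it as a
#'   recombination map, re-read it, and run the regression pipeline
#'   ([analyze_recombination()]); writes a summary TSV and a posterior
#'   draw dump.
#' * `genome`: simulate a genome ([simulate_genome()]), write
#'   FASTA/VCF/BED, re-read them, qualify variants, tally contexts for each
#'   requested `k` and write total-variance posteriors plus a summary TSV;
#'   optionally a per-direction strand-asymmetry report.
#'
#' Alternatively, `inputs` may point at existing files (`rmap`, `fasta`,
#' `vcf`, `bed`) instead of simulation blocks. Every output file gets a
#' `.prov.json` sidecar recording the config, seed, package version and
#' input checksums. On any stage failure, partial outputs are removed and
#' the error is re-thrown.
#'
#' @param config A named list, or path to a YAML file. Top-level fields:
#'   `out_dir` (required), `seed` (default 1), and stage blocks `blocks`,
#'   `genome`, `regression`, `context`, `inputs`.
#' @return Invisibly, a list with the produced result objects and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$out_dir)) abort("config must name an out_dir")
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  written <- character(0)
  results <- list()
  emit <- function(path) written <<- c(written, path)

  # Validate referenced inputs before doing any work.
  for (f in unlist(config$inputs)) {
    if (!file.exists(f)) abort(sprintf("input file does not exist: %s", f))
  }

  sidecar <- function(path, stage, inputs = character(0)) {
    meta <- list(
      tool = "mutvar",
      version = as.character(utils::packageVersion("mutvar")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      stage = stage, seed = seed, config = config,
      input_checksums = as.list(tools::md5sum(inputs))
    )
    pj <- paste0(path, ".prov.json")
    jsonlite::write_json(meta, pj, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    emit(pj)
  }

  run <- function() {
    # --- recombination stage -------------------------------------------
    if (!is.null(config$blocks) || !is.null(config$inputs$rmap)) {
      rg <- config$regression %||% list()
      if (!is.null(config$blocks)) {
        bp <- do.call(block_sim_params,
                      c(config$blocks, list(seed = derive_seed(seed, 1))))
        sim <- simulate_blocks(bp)
        rmap_path <- file.path(out_dir, "blocks.rmap")
        write_recomb_map(blocks_to_recomb_map(sim$blocks), rmap_path)
        emit(rmap_path); sidecar(rmap_path, "simulate-blocks")
        rmap <- read_recomb_map(rmap_path, rmap_dialect(
          block_size = bp$block_size))
        blocks <- sim$blocks
        blocks <- locf_blocks(blocks)
        results$block_truth <- sim$truth
      } else {
        rmap <- read_recomb_map(config$inputs$rmap)
        vt <- read_variants(config$inputs$vcf)
        genome <- if (!is.null(config$inputs$fasta))
          read_genome(config$inputs$fasta) else NULL
        blocks <- build_block_series(vt, rmap, genome = genome)
      }
      ana <- analyze_recombination(
        blocks,
        p_max = rg$p_max %||% 10L, q_max = rg$q_max %||% 4L,
        chains = rg$chains %||% 4L, draws = rg$draws %||% 2000L,
        tune = rg$tune %||% 1000L, seed = derive_seed(seed, 2),
        mu = rg$mu %||% 1.19e-8, xover = rg$xover %||% 1.16e-8,
        mean_cM_per_block = rg$mean_cM %||% 0.0116
      )
      results$recombination <- ana
      sm_path <- file.path(out_dir, "recombination_summary.tsv")
      readr::write_tsv(tidy(ana$summary), sm_path)
      emit(sm_path); sidecar(sm_path, "fit-recombination")
      dr_path <- file.path(out_dir, "recombination_draws.tsv")
      readr::write_tsv(ana$posterior$draws, dr_path)
      emit(dr_path); sidecar(dr_path, "fit-recombination")
    }

    # --- context stage -------------------------------------------------
    if (!is.null(config$genome) || !is.null(config$inputs$fasta)) {
      cx <- config$context %||% list()
      if (!is.null(config$genome)) {
        gcfg <- config$genome
        rt <- context_rate_table(
          k = gcfg$k %||% 3, base_rate = gcfg$base_rate %||% 0.003,
          transition_mult = gcfg$transition_mult %||% 3,
          cpg_mult = gcfg$cpg_mult %||% 10
        )
        gp <- genome_sim_params(
          length = gcfg$length %||% 1e6, rate_table = rt,
          fraction_multiallelic = gcfg$fraction_multiallelic %||% 0.01,
          cluster_rate = gcfg$cluster_rate %||% 0.01,
          seed = derive_seed(seed, 3)
        )
        sim <- simulate_genome(gp)
        fa <- file.path(out_dir, "genome.fa")
        vcf <- file.path(out_dir, "variants.vcf")
        bed <- file.path(out_dir, "regions.bed")
        write_genome_fasta(sim$genome, fa); emit(fa)
        write_variants_vcf(sim$variants, vcf,
                           contigs = setNames(Biostrings::width(sim$genome),
                                              names(sim$genome)))
        emit(vcf)
        write_regions_bed(sim$regions, bed); emit(bed)
        sidecar(fa, "simulate-genome")
        genome <- read_genome(fa)
        variants <- read_variants(vcf)
        mask <- read_regions(bed)
        results$genome_truth <- sim$truth
      } else {
        genome <- read_genome(config$inputs$fasta)
        variants <- read_variants(config$inputs$vcf)
        mask <- read_regions(config$inputs$bed)
      }
      cls <- cx$class %||% "intronic"
      mask_cls <- mask[mask$class == cls, , drop = FALSE]
      n_in <- nrow(variants)
      qual <- qualify_context_variants(variants, mask_cls, genome = genome,
                                       neighborhood = cx$neighborhood %||% 4L)
      inform(sprintf("context filters: %d variants in, %d qualified (%s mask)",
                     n_in, nrow(qual), cls))
      summaries <- list()
      for (k in (cx$k %||% 3)) {
        tab <- tally_cells(qual, genome, mask_cls, k = k)
        vp <- variance_total(tab, n_draws = cx$n_draws %||% 10000L,
                             seed = derive_seed(seed, 40 + k))
        vp_path <- file.path(out_dir, sprintf("context_variance_k%d.tsv", k))
        write_variance_posterior(vp, vp_path)
        emit(vp_path); sidecar(vp_path, sprintf("context-variance k=%d", k))
        summaries[[as.character(k)]] <- tidy(vp)
        results$context[[as.character(k)]] <- vp
      }
      cs_path <- file.path(out_dir, "context_summary.tsv")
      readr::write_tsv(dplyr::bind_rows(summaries), cs_path)
      emit(cs_path); sidecar(cs_path, "context-variance")

      if (isTRUE(cx$strand_asymmetry)) {
        k_sa <- max(cx$k %||% 3)
        tab <- tally_cells(qual, genome, mask_cls, k = k_sa)
        nd <- cx$n_draws %||% 10000L
        rep_sa <- purrr::map_dfr(
          c("C>T", "T>C", "C>G", "C>A", "T>A", "T>G"), function(d) {
            pa <- variance_by_direction(tab, d, n_draws = nd,
                                        seed = derive_seed(seed, 60))
            pb <- variance_by_direction(tab, strand_complement_direction(d),
                                        n_draws = nd,
                                        seed = derive_seed(seed, 60))
            sa <- strand_asymmetry(pa, pb)
            tibble::tibble(direction = d,
                           complement = sa$direction_b,
                           asymmetric = sa$asymmetric,
                           q2.5_a = sa$q2.5_a, q97.5_a = sa$q97.5_a,
                           q2.5_b = sa$q2.5_b, q97.5_b = sa$q97.5_b)
          })
        sa_path <- file.path(out_dir, "strand_asymmetry.tsv")
        readr::write_tsv(rep_sa, sa_path)
        emit(sa_path); sidecar(sa_path, "strand-asymmetry")
        results$strand_asymmetry <- rep_sa
      }
    }
    results
  }

  results <- tryCatch(run(), error = function(e) {
    unlink(written)
    abort(paste0("pipeline stage failed: ", conditionMessage(e)),
          parent = e)
  })
  invisible(list(results = results, paths = written))
}
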