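# Per-direction reporting: the per-mutation-direction regression driver and
# the direction-table renderer (Mutation / SNV Density / Probability /
# sigma2_rec / credibility limits).

#' Fit the recombination regression per mutation direction
#'
#' Runs [analyze_recombination()] once per requested direction, using the
#' per-direction density columns of a block series (denominator: count of
#' ancestral-base sites per block).
#'
#' @param blocks A `block_series` containing per-direction density columns
#'   (from [build_block_series()] with a genome).
#' @param directions Directions to fit (default all 12).
#' @param ... Passed on to [analyze_recombination()].
#' @return A named list of `recomb_summary` objects (entries `NULL` where
#'   the direction column is absent).
#' @export
fit_directions <- function(blocks, directions = mutation_directions(), ...) {
  res <- lapply(directions, function(d) {
    if (!d %in% names(blocks)) return(NULL)
    analyze_recombination(blocks, response = d, ...)$summary
  })
  names(res) <- directions
  res
}

#' Render a per-direction results table
#'
#' Collects per-direction recombination summaries into the standard
#' reporting layout: `Mutation`, `SNV Density` (the mean per-direction
#' density), `Probability` (posterior probability that the slope is <= 0),
#' `sigma2_rec` and its 95% credibility limits. Directions are reported in
#' the canonical order; a missing direction produces a blank row flagged in
#' the `flag` column. Negative `sigma2_rec` values (fits worse than a flat
#' line) are printed as-is.
#'
#' @param summaries Named list of `recomb_summary` objects (names are
#'   directions; `NULL` entries allowed).
#' @param directions Row order (default the canonical 12).
#' @return A tibble, one row per direction.
#' @export
render_direction_table <- function(summaries,
                                   directions = mutation_directions()) {
  purrr::map_dfr(directions, function(d) {
    s <- summaries[[d]]
    if (is.null(s)) {
      return(tibble::tibble(
        Mutation = d, `SNV Density` = NA_real_, Probability = NA_real_,
        sigma2_rec = NA_real_, `Lower CL 95%` = NA_real_,
        `Upper CL 95%` = NA_real_, flag = "missing"
      ))
    }
    row <- s$stats[s$stats$quantity == "sigma2_rec", ]
    tibble::tibble(
      Mutation = d, `SNV Density` = s$m_bar,
      Probability = s$prob_slope_le_0,
      sigma2_rec = row$mean, `Lower CL 95%` = row$lower95,
      `Upper CL 95%` = row$upper95, flag = NA_character_
    )
  })
}

#' Write a rendered direction table as TSV
#'
#' @param table Output of [render_direction_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_direction_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Dump a variance posterior (draws + percentiles) as TSV
#'
#' Posterior figures are emitted as data: the draws themselves plus a
#' percentile summary, with run metadata in a JSON sidecar written by
#' [run_pipeline()].
#'
#' @param post A `variance_posterior`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variance_posterior <- function(post, path) {
  readr::write_tsv(tibble::tibble(draw = seq_along(post$draws),
                                  value = post$draws), path)
  invisible(path)
}
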