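# Writers. Synthetic data is emitted in the same external formats the
# readers consume, so simulated inputs exercise the real I/O path.

#' Write a recombination map
#'
#' @param map A `recomb_map` tibble (see [read_recomb_map()]).
#' @param path Output path.
#' @param dialect An [rmap_dialect()]; missing rates are written as the
#'   dialect's marker.
#' @return `path`, invisibly.
#' @export
write_recomb_map <- function(map, path, dialect = rmap_dialect()) {
  rate <- ifelse(map$missing, dialect$missing,
                 formatC(map$rate, format = "g", digits = 15))
  cols <- lapply(dialect$columns, function(cn) {
    switch(cn,
      chrom = map$chrom,
      start = format(map$start, scientific = FALSE, trim = TRUE),
      index = format(map$start / attr(map, "block_size"),
                     scientific = FALSE, trim = TRUE),
      end = format(map$end, scientific = FALSE, trim = TRUE),
      rate = rate,
      rep(".", nrow(map))
    )
  })
  lines <- do.call(paste, c(cols, sep = dialect$delim))
  if (dialect$header) {
    lines <- c(paste(dialect$columns, collapse = dialect$delim), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write variants as VCF
#'
#' Emits a minimal plain-text VCF 4.2 with the ancestral allele in the `AA`
#' INFO key, 1-based positions, REF from the `ref` column and the remaining
#' alleles as ALT.
#'
#' @param variants A `variant_tbl` (see [read_variants()]).
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">"
  )
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  }
  hdr <- c(hdr, paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT",
                                    "QUAL", "FILTER", "INFO"),
                                  collapse = "\t")))
  allele_sets <- strsplit(variants$alleles, ",", fixed = TRUE)
  alt <- mapply(function(r, s) {
    a <- setdiff(s, r)
    if (!length(a)) "." else paste(a, collapse = ",")
  }, variants$ref, allele_sets)
  info <- ifelse(is.na(variants$ancestral), ".",
                 paste0("AA=", variants$ancestral))
  rows <- paste(variants$chrom, format(variants$pos + 1, scientific = FALSE,
                                       trim = TRUE),
                ".", variants$ref, alt, ".", ".", info, sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a region mask as BED6
#'
#' @param mask A `region_mask` (see [read_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(mask, path) {
  lines <- paste(mask$chrom,
                 format(mask$start, scientific = FALSE, trim = TRUE),
                 format(mask$end, scientific = FALSE, trim = TRUE),
                 mask$class, 0L, mask$strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Write and read a block series dump
#'
#' Tab-delimited dump of a block series (rates, densities, per-direction
#' densities, exclusion and LOCF flags) for inspection and for feeding the
#' regression stage from disk.
#'
#' @param blocks A `block_series` tibble (see [build_block_series()]).
#' @param path Output path.
#' @return `write_block_series()` returns `path` invisibly;
#'   `read_block_series()` returns the `block_series` tibble.
#' @export
write_block_series <- function(blocks, path) {
  out <- as.data.frame(blocks)
  attr_line <- sprintf("# block_size=%d", attr(blocks, "block_size") %||% 10000L)
  writeLines(attr_line, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_block_series
#' @export
read_block_series <- function(path) {
  first <- readLines(path, n = 1)
  block_size <- 10000L
  if (grepl("^# block_size=", first)) {
    block_size <- as.integer(sub("^# block_size=", "", first))
  }
  tbl <- readr::read_tsv(path, comment = "#", progress = FALSE,
                         show_col_types = FALSE)
  structure(tibble::as_tibble(tbl), block_size = block_size,
            class = c("block_series", class(tibble::tibble())))
}
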