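# Readers for the four external file kinds: recombination map, variants,
# genome sequence, region masks. Internally everything is 0-based half-open;
# 1-based coordinates appear only at the VCF boundary.

#' Recombination-map file dialect
#'
#' deCODE-style rmap files are tab-delimited but their exact schema is not
#' standardised, so the reader takes a dialect: column order, header
#' presence, missing-rate marker, block size and the calibration constant
#' converting one standardized rate unit to centimorgans per block.
#'
#' @param columns Character vector naming the file's columns in order. Must
#'   contain `"chrom"` and `"rate"`, plus either `"start"` (0-based block
#'   start in bp) or `"index"` (block number, start = index * block_size).
#'   Unrecognised names are read and ignored.
#' @param header Logical, does the file carry a header line?
#' @param missing Marker string denoting a missing rate (default `"NA"`).
#' @param delim Field delimiter.
#' @param block_size Block length in bp (default 10000).
#' @param mean_cM_per_block Average genetic distance per block in
#'   centimorgans; the deCODE standardized rates are normalised so one rate
#'   unit corresponds to this genetic length (default 0.0116 cM).
#' @return A list of class `"rmap_dialect"`.
#' @export
rmap_dialect <- function(columns = c("chrom", "start", "rate"),
                         header = FALSE,
                         missing = "NA",
                         delim = "\t",
                         block_size = 10000L,
                         mean_cM_per_block = 0.0116) {
  if (!"chrom" %in% columns || !"rate" %in% columns) {
    abort("rmap dialect must name 'chrom' and 'rate' columns")
  }
  if (!any(c("start", "index") %in% columns)) {
    abort("rmap dialect must name a 'start' or 'index' column")
  }
  structure(
    list(columns = columns, header = header, missing = missing,
         delim = delim, block_size = as.integer(block_size),
         mean_cM_per_block = mean_cM_per_block),
    class = "rmap_dialect"
  )
}

#' Read a recombination map
#'
#' Reads per-block standardized recombination rates (deCODE-style
#' tab-delimited text) into a validated, sorted block table. Rows whose rate
#' equals the dialect's missing marker are retained with `missing = TRUE`;
#' the downstream exclusion logic needs them.
#'
#' @param path Path to the map file.
#' @param dialect An [rmap_dialect()] describing the file schema.
#' @return A tibble of class `"recomb_map"` with columns `chrom`, `start`,
#'   `end`, `rate`, `missing`, sorted by (chrom, start), and attributes
#'   `block_size` and `mean_cM_per_block`.
#' @export
read_recomb_map <- function(path, dialect = rmap_dialect()) {
  stopifnot(inherits(dialect, "rmap_dialect"))
  raw <- readr::read_delim(
    path, delim = dialect$delim, col_names = dialect$columns,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),  # keep the dialect marker literal
    skip = if (dialect$header) 1L else 0L, progress = FALSE
  )
  n_skip <- if (dialect$header) 1L else 0L
  if (ncol(raw) < length(dialect$columns)) {
    abort("recombination map has fewer columns than the dialect declares")
  }

  parse_num <- function(x, what) {
    miss <- !is.na(x) & x == dialect$missing
    out <- suppressWarnings(as.numeric(x))
    bad <- which((is.na(out) & !miss) | is.na(x))
    if (length(bad)) {
      abort(sprintf("malformed %s field at line %d of %s",
                    what, bad[1] + n_skip, path))
    }
    out[miss] <- NA_real_
    out
  }

  rate <- parse_num(raw$rate, "rate")
  if ("start" %in% names(raw)) {
    start <- parse_num(raw$start, "start")
    if (anyNA(start)) abort("missing marker not allowed in start column")
  } else {
    idx <- parse_num(raw$index, "index")
    start <- idx * dialect$block_size
  }

  map <- tibble::tibble(
    chrom = raw$chrom,
    start = as.numeric(start),
    end = as.numeric(start) + dialect$block_size,
    rate = rate,
    missing = is.na(rate)
  )
  if ("end" %in% names(raw)) {
    end_in <- parse_num(raw$end, "end")
    if (any(end_in - map$start != dialect$block_size)) {
      abort(sprintf("block length differs from the configured %d bp",
                    dialect$block_size))
    }
  }
  validate_recomb_map(map, dialect$block_size)
  if (any(map$rate < 0, na.rm = TRUE)) {
    abort("negative recombination rate in map")
  }
  new_recomb_map(map, dialect$block_size, dialect$mean_cM_per_block)
}

new_recomb_map <- function(map, block_size, mean_cM_per_block = 0.0116) {
  structure(
    tibble::as_tibble(map),
    block_size = as.integer(block_size),
    mean_cM_per_block = mean_cM_per_block,
    class = c("recomb_map", class(tibble::tibble()))
  )
}

validate_recomb_map <- function(map, block_size) {
  if (any(map$end - map$start != block_size)) {
    abort(sprintf("block length differs from the configured %d bp", block_size))
  }
  by_chrom <- split(map$start, map$chrom)
  for (ch in names(by_chrom)) {
    s <- by_chrom[[ch]]
    if (is.unsorted(s, strictly = TRUE)) {
      abort(sprintf("blocks unsorted or duplicated within %s", ch))
    }
    if (any(diff(s) < block_size)) {
      abort(sprintf("overlapping blocks within %s", ch))
    }
  }
  invisible(map)
}

#' Read a variant table
#'
#' Reads variants from VCF (ancestral allele in the `AA` INFO key) or from a
#' simple TSV with columns `chrom`, `pos` (1-based), `ancestral`, `alleles`
#' (comma-separated observed bases). Positions are converted to 0-based.
#' Records whose alleles contain characters outside ACGTN are skipped with a
#' warning naming the count. Records with unknown ancestral allele are
#' retained with an undefined direction: they still count towards total SNV
#' density but are excluded from per-direction and context analyses.
#'
#' @param path Path to the variant file.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return A tibble of class `"variant_tbl"` with columns `chrom`, `pos`
#'   (0-based), `ref`, `ancestral` (NA if unknown), `alleles`
#'   (comma-separated string), `biallelic`, `derived`, `direction`
#'   (`"from>to"`, NA unless biallelic with known ancestral among alleles).
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  }
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                         dimnames = list(NULL, names(fix)))
    aa <- suppressWarnings(vcfR::extract.info(vcf, "AA"))
    if (is.null(aa)) aa <- rep(NA_character_, nrow(fix))
    tbl <- tibble::tibble(
      chrom = fix[, "CHROM"],
      pos = as.numeric(fix[, "POS"]) - 1,
      ref = toupper(fix[, "REF"]),
      alt = toupper(fix[, "ALT"]),
      ancestral = toupper(aa)
    )
  } else {
    tbl <- readr::read_tsv(path, col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      ancestral = readr::col_character(), alleles = readr::col_character()
    ), progress = FALSE)
    allele_sets <- strsplit(toupper(tbl$alleles), ",", fixed = TRUE)
    tbl <- tibble::tibble(
      chrom = tbl$chrom,
      pos = tbl$pos - 1,
      ref = vapply(allele_sets, `[`, "", 1L),
      alt = vapply(allele_sets, function(a) paste(a[-1], collapse = ","), ""),
      ancestral = toupper(tbl$ancestral)
    )
  }
  finalize_variants(tbl)
}

# Shared post-processing: allele validation, biallelic flag, direction.
finalize_variants <- function(tbl) {
  allele_sets <- Map(function(r, a) {
    alts <- if (is.na(a) || a == "" || a == ".") character(0) else
      strsplit(a, ",", fixed = TRUE)[[1]]
    c(r, alts)
  }, tbl$ref, tbl$alt)

  ok <- vapply(allele_sets, function(a) {
    all(nchar(a) == 1) && all(a %in% c(BASES, "N"))
  }, logical(1))
  if (any(!ok)) {
    warn(sprintf("skipped %d variant record(s) with alleles outside {A,C,G,T,N}",
                 sum(!ok)))
    tbl <- tbl[ok, , drop = FALSE]
    allele_sets <- allele_sets[ok]
  }

  anc <- unname(tbl$ancestral)
  anc[!anc %in% BASES] <- NA_character_
  biallelic <- unname(lengths(allele_sets) == 2L)
  anc_in <- unname(mapply(function(a, s) !is.na(a) && a %in% s,
                          anc, allele_sets))
  derived <- rep(NA_character_, nrow(tbl))
  idx <- which(biallelic & anc_in)
  derived[idx] <- unname(mapply(function(a, s) setdiff(s, a)[1],
                                anc[idx], allele_sets[idx]))

  out <- tibble::tibble(
    chrom = unname(tbl$chrom),
    pos = unname(tbl$pos),
    ref = unname(tbl$ref),
    ancestral = anc,
    alleles = vapply(allele_sets, paste, "", collapse = ","),
    biallelic = biallelic,
    derived = derived,
    direction = make_direction(anc, derived)
  )
  class(out) <- c("variant_tbl", class(tibble::tibble()))
  out
}

#' Read a region mask
#'
#' Reads a BED6 file (chrom, start, end, class, score, strand; 0-based
#' half-open) of intronic/intergenic/other intervals. Overlapping intervals
#' of the same class and strand are merged. Genic classes carry the
#' annotated strand so contexts and directions can be oriented to the
#' transcribed strand.
#'
#' @param path Path to the BED file.
#' @return A tibble of class `"region_mask"` with columns `chrom`, `start`,
#'   `end` (0-based half-open), `class`, `strand`.
#' @export
read_regions <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  if (!length(txt)) {
    return(new_region_mask(tibble::tibble(
      chrom = character(), start = numeric(), end = numeric(),
      class = character(), strand = character()
    )))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) abort(paste0("invalid BED file: ", conditionMessage(e)))
  )
  tbl <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    class = if (!is.null(gr$name)) gr$name else "other",
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(tbl$end <= tbl$start)) {
    abort("region with start >= end")
  }
  new_region_mask(merge_regions(tbl))
}

new_region_mask <- function(tbl) {
  structure(tibble::as_tibble(tbl),
            class = c("region_mask", class(tibble::tibble())))
}

# Merge overlapping intervals within each (class, strand) group.
merge_regions <- function(tbl) {
  if (!nrow(tbl)) return(tbl)
  parts <- dplyr::group_split(
    dplyr::group_by(tbl, .data$chrom, .data$class, .data$strand))
  merged <- purrr::map_dfr(parts, function(g) {
    r <- IRanges::reduce(IRanges::IRanges(start = g$start + 1, end = g$end))
    tibble::tibble(chrom = g$chrom[1], start = IRanges::start(r) - 1,
                   end = as.numeric(IRanges::end(r)),
                   class = g$class[1], strand = g$strand[1])
  })
  dplyr::arrange(merged, .data$chrom, .data$start, .data$class)
}

#' Read a genome sequence
#'
#' Reads a FASTA file into a `DNAStringSet`, upper-casing bases and trimming
#' sequence names to their first whitespace-delimited token. N bases are
#' allowed; context counting skips windows containing them.
#'
#' @param path Path to the FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
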