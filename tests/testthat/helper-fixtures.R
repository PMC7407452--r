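# Shared fixtures and independent brute-force oracles, all built in code.

# A tiny genome from an explicit sequence string.
toy_genome <- function(seq, name = "chr1") {
  g <- Biostrings::DNAStringSet(seq)
  names(g) <- name
  g
}

# Random genome with given base frequencies.
random_genome <- function(n, freq = c(A = .25, C = .25, G = .25, T = .25),
                          seed = 1, name = "chr1") {
  set.seed(seed)
  toy_genome(paste(sample(names(freq), n, replace = TRUE, prob = freq),
                   collapse = ""), name)
}

# Region mask tibble helper.
toy_mask <- function(chrom, start, end, class = "intronic", strand = "+") {
  structure(tibble::tibble(chrom = chrom, start = start, end = end,
                           class = class, strand = strand),
            class = c("region_mask", class(tibble::tibble())))
}

# Variant table helper: biallelic ancestral-known variants unless stated.
toy_variants <- function(pos, anc, der, chrom = "chr1",
                         biallelic = TRUE) {
  n <- length(pos)
  anc <- rep_len(anc, n); der <- rep_len(der, n)
  biallelic <- rep_len(biallelic, n)
  direction <- ifelse(biallelic, paste0(anc, ">", der), NA_character_)
  structure(tibble::tibble(
    chrom = chrom, pos = as.numeric(pos), ref = anc, ancestral = anc,
    alleles = ifelse(biallelic, paste(anc, der, sep = ","),
                     paste(anc, der, "G", sep = ",")),
    biallelic = biallelic, derived = ifelse(biallelic, der, NA_character_),
    direction = direction
  ), class = c("variant_tbl", class(tibble::tibble())))
}

# Independent O(n^2) brute force for the context-variant filters.
brute_force_qualify <- function(variants, mask, neighborhood = 4) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$biallelic || is.na(v$direction)) next
    crowded <- FALSE
    for (j in seq_len(nrow(variants))) {
      if (i == j) next
      if (variants$chrom[j] == v$chrom &&
          abs(variants$pos[j] - v$pos) <= neighborhood) crowded <- TRUE
    }
    if (crowded) next
    inside <- FALSE
    for (r in seq_len(nrow(mask))) {
      if (mask$chrom[r] == v$chrom && v$pos >= mask$start[r] &&
          v$pos < mask$end[r]) inside <- TRUE
    }
    keep[i] <- inside
  }
  variants$pos[keep]
}

# Weighted variance of per-kmer total rates, straight from definitions.
brute_force_weighted_variance <- function(probs, weights) {
  m_bar <- sum(weights * probs)
  sum(weights * (probs - m_bar)^2)
}

# Group a k-mer truth table down to a smaller, centred context size and
# return the weighted variance of the pooled rates (conditional means).
collapse_truth_variance <- function(rate_table, pc, to_k) {
  k <- attr(rate_table, "k")
  stopifnot(to_k <= k, (k - to_k) %% 2 == 0)
  kmers <- names(pc)
  m_tot <- vapply(kmers, function(km) {
    sum(rate_table$prob[rate_table$kmer == km])
  }, numeric(1))
  trim <- (k - to_k) %/% 2
  group <- substr(kmers, trim + 1, k - trim)
  pg <- tapply(pc, group, sum)
  mg <- tapply(pc * m_tot, group, sum) / pg
  brute_force_weighted_variance(as.numeric(mg), as.numeric(pg))
}

# Per-kmer weight vector from independent base frequencies.
kmer_weights_from_freq <- function(k, freq) {
  grids <- rep(list(c("A", "C", "G", "T")), k)
  kms <- do.call(paste0, rev(expand.grid(rev(grids), stringsAsFactors = FALSE)))
  w <- vapply(strsplit(kms, NULL), function(ch) prod(freq[ch]), numeric(1))
  setNames(w / sum(w), kms)
}

# Minimal VCF text for reader tests.
write_toy_vcf <- function(lines, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"AA\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, lines), path)
  path
}
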