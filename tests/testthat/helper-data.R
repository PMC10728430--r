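# shared builders for small in-code fixtures

toy_beta_matrix <- function(betas_by_sample,
                            chrom = "chr11",
                            pos = NULL) {
  n <- length(betas_by_sample[[1]])
  if (is.null(pos)) pos <- seq(2020000L, by = 100L, length.out = n)
  df <- data.frame(probe_id = sprintf("cg%03d", seq_len(n)),
                   chrom = rep_len(chrom, n), pos = as.integer(pos),
                   stringsAsFactors = FALSE)
  for (s in names(betas_by_sample)) df[[s]] <- betas_by_sample[[s]]
  as_beta_matrix(df)
}

toy_germline_variant <- function(gene = "WT1", variant_class = "missense",
                                 clinvar = "vus", provean = "missing",
                                 polyphen = "missing",
                                 germline_ref = 50L, germline_alt = 50L,
                                 tumor_ref = 50L, tumor_alt = 50L,
                                 patient_id = "P1",
                                 protein_change = "p.A1T") {
  as_germline_variants(data.frame(
    patient_id = patient_id, gene = gene, variant_class = variant_class,
    protein_change = protein_change, clinvar = clinvar, provean = provean,
    polyphen = polyphen, germline_ref = germline_ref,
    germline_alt = germline_alt, tumor_ref = tumor_ref,
    tumor_alt = tumor_alt, stringsAsFactors = FALSE))
}

toy_variant_set <- function(...) {
  # toy_variant_set("CTNNB1 p.S45F", "TP53") -> coding set
  entries <- c(...)
  if (length(entries) == 0L) {
    return(data.frame(gene = character(), protein_change = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(entries, " ", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[`, "", 1L),
    protein_change = vapply(parts, function(p)
      if (length(p) > 1L) p[2] else NA_character_, ""),
    stringsAsFactors = FALSE)
}

toy_noncoding <- function(pos, chrom = "chr1", ref = "A", alt = "T") {
  if (length(pos) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(chrom = rep_len(chrom, length(pos)), pos = as.integer(pos),
             ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
             stringsAsFactors = FALSE)
}

toy_segments <- function(sample_id, start, end, value, cnloh = FALSE,
                         chrom = "chr11") {
  data.frame(sample_id = sample_id, chrom = rep_len(chrom, length(start)),
             start = as.integer(start), end = as.integer(end),
             value = value, cnloh = rep_len(cnloh, length(start)),
             stringsAsFactors = FALSE)
}

# independent oracle: one-sided (greater-in-tumor) exact test by full
# hypergeometric enumeration over tables with the observed margins
exact_test_oracle <- function(germline_ref, germline_alt, tumor_ref,
                              tumor_alt) {
  m <- germline_alt + tumor_alt   # total alt
  n <- germline_ref + tumor_ref   # total ref
  k <- tumor_ref + tumor_alt      # tumor depth
  ks <- max(0, k - n):min(k, m)
  sum(dhyper(ks[ks >= tumor_alt], m, n, k))
}

# independent oracle: two-pass mean/SD then mean + 2 SD
gom_threshold_oracle <- function(x, multiplier = 2) {
  m <- sum(x) / length(x)
  ss <- 0
  for (xi in x) ss <- ss + (xi - m)^2
  m + multiplier * sqrt(ss / (length(x) - 1))
}

# independent oracle: Pearson chi-square from the textbook formula
chisq_oracle <- function(tab) {
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}
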