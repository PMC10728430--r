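#' @importFrom stats complete.cases cor cor.test pnorm rbeta rbinom rnorm
#'   rpois runif sd setNames var aov chisq.test fisher.test ks.test p.adjust
#'   pairwise.t.test t.test
#' @importFrom utils read.delim write.table head
NULL

stop_format <- function(...) stop(errorCondition(sprintf(...),
                                                 class = c("bwt_format_error", "error")))
stop_validation <- function(...) stop(errorCondition(sprintf(...),
                                                     class = c("bwt_validation_error", "error")))

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, na.strings = c("NA", ""), ...)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a probe-level methylation beta matrix
#'
#' Expects a TSV with header columns `probe_id`, `chrom`, `pos` followed by one
#' column per sample holding beta values in \[0, 1\]. Coordinates are 1-based
#' GRCh38.
#'
#' @param path TSV file path.
#' @return a data.frame of class `ProbeBetaMatrix`: `probe_id`, `chrom`,
#'   `pos`, then numeric sample columns.
#' @export
read_beta_matrix <- function(path) {
  df <- read_tsv(path)
  required <- c("probe_id", "chrom", "pos")
  if (!identical(names(df)[seq_len(3)], required)) {
    stop_format("beta matrix header must start with %s; got %s",
                paste(required, collapse = ", "),
                paste(head(names(df), 3), collapse = ", "))
  }
  if (ncol(df) < 4L) stop_format("beta matrix has no sample columns")
  df$pos <- as.integer(df$pos)
  as_beta_matrix(df)
}

#' Validate and class a probe beta matrix
#'
#' @param df data.frame with `probe_id`, `chrom`, `pos` and sample columns.
#' @return the validated `ProbeBetaMatrix`.
#' @export
as_beta_matrix <- function(df) {
  if (anyDuplicated(df$probe_id)) {
    stop_validation("duplicate probe ids: %s",
                    paste(unique(df$probe_id[duplicated(df$probe_id)]),
                          collapse = ", "))
  }
  key <- paste(df$chrom, df$pos)
  if (anyDuplicated(key)) stop_validation("duplicate (chrom, pos) coordinates")
  samp <- setdiff(names(df), c("probe_id", "chrom", "pos"))
  for (s in samp) {
    b <- as.numeric(df[[s]])
    if (any(!is.na(b) & (b < 0 | b > 1))) {
      stop_validation("beta values outside [0,1] in sample '%s'", s)
    }
    df[[s]] <- b
  }
  class(df) <- c("ProbeBetaMatrix", "data.frame")
  df
}

#' Write a probe beta matrix to TSV
#'
#' Betas are written with six decimal digits; a write/read round trip is
#' identical to six decimals.
#'
#' @param mat a `ProbeBetaMatrix`.
#' @param path output TSV path.
#' @export
write_beta_matrix <- function(mat, path) {
  out <- as.data.frame(mat)
  samp <- setdiff(names(out), c("probe_id", "chrom", "pos"))
  for (s in samp) out[[s]] <- sprintf("%.6f", out[[s]])
  write_tsv(out, path)
}

#' Sample names of a beta matrix
#' @param mat a `ProbeBetaMatrix`.
#' @return character vector of sample ids.
#' @export
beta_samples <- function(mat) setdiff(names(mat), c("probe_id", "chrom", "pos"))

#' Read a sample sheet
#'
#' Columns: `sample_id`, `patient_id`, `tissue` (blood/kidney/tumor),
#' `laterality` (left/right/unknown), `purity` (tumors only; empty = missing,
#' 0 is a legal purity), `cohort`.
#'
#' @param path TSV path.
#' @return validated data.frame of class `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- read_tsv(path, colClasses = list(purity = "character"))
  as_sample_sheet(df)
}

#' Validate a sample sheet
#' @param df data.frame with sample sheet columns.
#' @return `SampleSheet` data.frame.
#' @export
as_sample_sheet <- function(df) {
  required <- c("sample_id", "patient_id", "tissue", "laterality", "purity",
                "cohort")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop_format("sample sheet missing columns: %s",
                                   paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop_validation("duplicate sample ids")
  bad <- setdiff(unique(df$tissue), c("blood", "kidney", "tumor"))
  if (length(bad)) stop_validation("unknown tissue values: %s",
                                   paste(bad, collapse = ", "))
  df$purity <- suppressWarnings(as.numeric(df$purity))
  has_purity <- !is.na(df$purity)
  if (any(has_purity & df$tissue != "tumor")) {
    stop_validation("purity recorded for a non-tumor sample")
  }
  if (any(has_purity & (df$purity < 0 | df$purity > 1))) {
    stop_validation("purity outside [0,1]")
  }
  n_blood <- table(df$patient_id[df$tissue == "blood"])
  if (any(n_blood > 1L)) stop_validation("patient with >1 blood sample")
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Write a sample sheet to TSV
#' @param sheet a `SampleSheet`.
#' @param path output path.
#' @export
write_sample_sheet <- function(sheet, path) write_tsv(as.data.frame(sheet), path)

#' Read copy-number segments
#'
#' BED-like TSV but 1-based and end-inclusive, with columns `sample_id`,
#' `chrom`, `start`, `end`, `value` (log2-ratio scale) and `cnloh` (0/1 or
#' TRUE/FALSE).
#'
#' @param path TSV path.
#' @return data.frame of class `CnvSegments`.
#' @export
read_cnv_segments <- function(path) {
  df <- read_tsv(path)
  as_cnv_segments(df)
}

#' Validate copy-number segments
#' @param df data.frame with segment columns.
#' @return `CnvSegments` data.frame.
#' @export
as_cnv_segments <- function(df) {
  required <- c("sample_id", "chrom", "start", "end", "value", "cnloh")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop_format("CNV table missing columns: %s",
                                   paste(missing, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$value <- as.numeric(df$value)
  df$cnloh <- as.logical(df$cnloh) | (suppressWarnings(as.numeric(df$cnloh)) %in% 1)
  if (any(df$start > df$end)) stop_validation("segment with start > end")
  # non-overlap within sample and chromosome
  sp <- split(df, paste(df$sample_id, df$chrom))
  for (seg in sp) {
    seg <- seg[order(seg$start), ]
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop_validation("overlapping segments for sample %s on %s",
                      seg$sample_id[1], seg$chrom[1])
    }
  }
  class(df) <- c("CnvSegments", "data.frame")
  df
}

#' Write copy-number segments to TSV
#' @param segs a `CnvSegments` data.frame.
#' @param path output path.
#' @export
write_cnv_segments <- function(segs, path) {
  out <- as.data.frame(segs)
  out$cnloh <- as.integer(out$cnloh)
  write_tsv(out, path)
}

#' Read a somatic variant table
#'
#' Minimal exchange format: `sample_id`, `class` (`coding`/`noncoding`),
#' `gene`, `protein_change` (coding rows), `chrom`, `pos`, `ref`, `alt`
#' (noncoding rows).
#'
#' @param path TSV path.
#' @return data.frame of somatic variant calls.
#' @export
read_somatic_variants <- function(path) {
  df <- read_tsv(path)
  required <- c("sample_id", "class", "gene", "protein_change", "chrom",
                "pos", "ref", "alt")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop_format("somatic table missing columns: %s",
                                   paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Write a somatic variant table to TSV
#' @param df somatic variant data.frame.
#' @param path output path.
#' @export
write_somatic_variants <- function(df, path) write_tsv(df, path)

#' Read a germline variant annotation table
#'
#' Columns: `patient_id`, `gene`, `variant_class`
#' (indel/nonsense/missense/splice/other_snv), `protein_change`, `clinvar`,
#' `provean`, `polyphen`, and read counts `germline_ref`, `germline_alt`,
#' `tumor_ref`, `tumor_alt`.
#'
#' @param path TSV path.
#' @return data.frame of class `GermlineVariants`.
#' @export
read_germline_variants <- function(path) {
  df <- read_tsv(path)
  as_germline_variants(df)
}

#' Validate a germline variant table
#' @param df data.frame with germline annotation columns.
#' @return `GermlineVariants` data.frame.
#' @export
as_germline_variants <- function(df) {
  required <- c("patient_id", "gene", "variant_class", "protein_change",
                "clinvar", "provean", "polyphen", "germline_ref",
                "germline_alt", "tumor_ref", "tumor_alt")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop_format("germline table missing columns: %s",
                                   paste(missing, collapse = ", "))
  df$gene <- toupper(df$gene)
  enum_check <- function(col, allowed) {
    vals <- df[[col]]
    bad <- setdiff(unique(vals[!is.na(vals)]), allowed)
    if (length(bad)) stop_validation("unknown %s value: %s", col,
                                     paste(bad, collapse = ", "))
  }
  enum_check("variant_class",
             c("indel", "nonsense", "missense", "splice", "other_snv"))
  enum_check("clinvar", c("benign", "likely_benign", "vus", "no_assertion",
                          "unreported", "likely_pathogenic", "pathogenic"))
  enum_check("provean", c("deleterious", "neutral", "missing"))
  enum_check("polyphen", c("benign", "possibly_damaging", "damaging",
                           "missing"))
  for (col in c("germline_ref", "germline_alt", "tumor_ref", "tumor_alt")) {
    df[[col]] <- as.integer(df[[col]])
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) {
      stop_validation("negative read count in %s", col)
    }
  }
  class(df) <- c("GermlineVariants", "data.frame")
  df
}

#' Write a germline variant table (optionally with verdict columns)
#' @param df `GermlineVariants` data.frame.
#' @param path output path.
#' @export
write_germline_variants <- function(df, path) write_tsv(as.data.frame(df), path)

#' Write a JSON report
#'
#' @param x report list.
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
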