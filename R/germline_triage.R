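#' Gene panel membership
#'
#' Case-insensitive membership of a gene symbol in a panel.
#'
#' @param gene character vector of symbols.
#' @param panel character vector of panel symbols (default the 21-gene Wilms
#'   tumor predisposition panel, [default_panel()]).
#' @return logical vector.
#' @export
in_panel <- function(gene, panel = default_panel()) {
  if (length(panel) == 0L) stop_validation("gene panel is empty")
  toupper(gene) %in% toupper(panel)
}

#' Variant allele frequency enrichment test (tumor vs germline)
#'
#' One-sided Fisher exact test on the 2x2 table of alt/ref read counts in
#' tumor vs germline, testing whether the tumor alt fraction is higher —
#' the signature of retention of the mutated allele in the tumor (loss of
#' heterozygosity). `enriched` additionally requires the VAF difference to
#' reach `min_delta`, an effect-size floor that keeps ultra-deep sequencing
#' from flagging negligible shifts.
#'
#' @param germline_ref,germline_alt,tumor_ref,tumor_alt read counts.
#' @param alpha significance level (default 0.05).
#' @param min_delta minimum tumor VAF - germline VAF (default 0.15).
#' @return list with `p_value` (NA when untestable), `enriched`,
#'   `germline_vaf`, `tumor_vaf`.
#' @export
vaf_enrichment_test <- function(germline_ref, germline_alt, tumor_ref,
                                tumor_alt, alpha = bwt_config()$vaf_alpha,
                                min_delta = bwt_config()$vaf_min_delta) {
  gd <- germline_ref + germline_alt
  td <- tumor_ref + tumor_alt
  if (is.na(gd) || is.na(td) || gd == 0L || td == 0L) {
    return(list(p_value = NA_real_, enriched = FALSE,
                germline_vaf = NA_real_, tumor_vaf = NA_real_))
  }
  tab <- matrix(c(tumor_alt, tumor_ref, germline_alt, germline_ref),
                nrow = 2, dimnames = list(allele = c("alt", "ref"),
                                          tissue = c("tumor", "germline")))
  p <- fisher.test(tab, alternative = "greater")$p.value
  gv <- germline_alt / gd
  tv <- tumor_alt / td
  list(p_value = p, enriched = (p < alpha) && (tv - gv >= min_delta),
       germline_vaf = gv, tumor_vaf = tv)
}

#' Triage a candidate germline predisposition variant
#'
#' Ordered decision rules; exactly one fires:
#' \enumerate{
#'   \item gene not in the panel: exclude (`panel_miss`)
#'   \item insertion/deletion or nonsense variant: include (`indel_nonsense`)
#'   \item ClinVar pathogenic / likely pathogenic: include
#'     (`clinvar_pathogenic`)
#'   \item ClinVar benign / likely benign: exclude (`clinvar_benign_excluded`)
#'   \item VUS, no-assertion or unreported with PROVEAN deleterious OR
#'     PolyPhen-2 possibly damaging/damaging: include (`predictor_damaging`)
#'   \item significant tumor VAF enrichment over germline: include
#'     (`vaf_enrichment`)
#'   \item otherwise exclude (`none_matched`)
#' }
#'
#' @param variant one-row data.frame (or list) with `GermlineVariants`
#'   columns.
#' @param panel gene panel (default [default_panel()]).
#' @param config a [bwt_config()] list (VAF test knobs).
#' @return list of class `TriageVerdict`: `include`, `rule_fired`,
#'   `vaf_test_p`.
#' @export
triage_variant <- function(variant, panel = default_panel(),
                           config = bwt_config()) {
  v <- as.list(variant)
  verdict <- function(include, rule, p = NA_real_) {
    structure(list(include = include, rule_fired = rule, vaf_test_p = p),
              class = "TriageVerdict")
  }
  if (!in_panel(v$gene, panel)) return(verdict(FALSE, "panel_miss"))
  if (v$variant_class %in% c("indel", "nonsense")) {
    return(verdict(TRUE, "indel_nonsense"))
  }
  if (v$clinvar %in% c("pathogenic", "likely_pathogenic")) {
    return(verdict(TRUE, "clinvar_pathogenic"))
  }
  if (v$clinvar %in% c("benign", "likely_benign")) {
    return(verdict(FALSE, "clinvar_benign_excluded"))
  }
  # ClinVar VUS / no assertion / unreported from here on
  provean <- if (is.null(v$provean) || is.na(v$provean)) "missing" else v$provean
  polyphen <- if (is.null(v$polyphen) || is.na(v$polyphen)) "missing" else v$polyphen
  if (provean == "deleterious" ||
      polyphen %in% c("possibly_damaging", "damaging")) {
    return(verdict(TRUE, "predictor_damaging"))
  }
  vt <- vaf_enrichment_test(v$germline_ref, v$germline_alt, v$tumor_ref,
                            v$tumor_alt, alpha = config$vaf_alpha,
                            min_delta = config$vaf_min_delta)
  if (isTRUE(vt$enriched)) return(verdict(TRUE, "vaf_enrichment", vt$p_value))
  verdict(FALSE, "none_matched", vt$p_value)
}

#' Triage a whole germline variant table
#'
#' @param variants a `GermlineVariants` data.frame.
#' @param panel gene panel.
#' @param config a [bwt_config()] list.
#' @return the input with appended columns `include`, `rule_fired`,
#'   `vaf_test_p`.
#' @export
triage_table <- function(variants, panel = default_panel(),
                         config = bwt_config()) {
  if (nrow(variants) == 0L) {
    variants$include <- logical(0)
    variants$rule_fired <- character(0)
    variants$vaf_test_p <- numeric(0)
    return(variants)
  }
  verdicts <- lapply(seq_len(nrow(variants)), function(i) {
    triage_variant(variants[i, , drop = FALSE], panel, config)
  })
  variants$include <- vapply(verdicts, `[[`, TRUE, "include")
  variants$rule_fired <- vapply(verdicts, `[[`, "", "rule_fired")
  variants$vaf_test_p <- vapply(verdicts, `[[`, 0, "vaf_test_p")
  variants
}

#' Per-patient predisposition flags and per-gene counts
#'
#' A patient is germline-positive iff at least one variant is included by
#' triage; patients with several included variants count once. The gene
#' tally counts included variants per gene for cohort reporting.
#'
#' @param variants a `GermlineVariants` data.frame.
#' @param panel gene panel.
#' @param config a [bwt_config()] list.
#' @return list with `patients` (data.frame `patient_id`,
#'   `germline_positive`, `n_included`, `genes`) and `gene_counts`
#'   (data.frame `gene`, `n_variants`, `n_patients`).
#' @export
patients_with_predisposition <- function(variants, panel = default_panel(),
                                         config = bwt_config()) {
  tv <- triage_table(variants, panel, config)
  ids <- unique(tv$patient_id)
  inc <- tv[tv$include, , drop = FALSE]
  patients <- data.frame(
    patient_id = ids,
    germline_positive = ids %in% inc$patient_id,
    n_included = vapply(ids, function(p) sum(inc$patient_id == p), 0L),
    genes = vapply(ids, function(p) {
      paste(sort(unique(inc$gene[inc$patient_id == p])), collapse = ",")
    }, ""),
    stringsAsFactors = FALSE
  )
  genes <- sort(unique(inc$gene))
  gene_counts <- data.frame(
    gene = genes,
    n_variants = vapply(genes, function(g) sum(inc$gene == g), 0L),
    n_patients = vapply(genes, function(g) {
      length(unique(inc$patient_id[inc$gene == g]))
    }, 0L),
    stringsAsFactors = FALSE
  )
  list(patients = patients, gene_counts = gene_counts)
}
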