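#' Run the full predisposition pipeline over a cohort
#'
#' Ties the modules together the way the study design does: imprinting
#' calls for every sample (with sequencing cnLOH overriding tumor calls),
#' germline triage per patient, blood low-level GOM against a control
#' cohort, pair concordance for patients with two tumors, and a per-patient
#' mode/tier assignment.
#'
#' @param beta a `ProbeBetaMatrix` covering all cohort samples.
#' @param samples a `SampleSheet`.
#' @param germline a `GermlineVariants` table (may be empty).
#' @param somatic somatic variant table (may be NULL).
#' @param cnv a `CnvSegments` table (may be NULL).
#' @param control_betas healthy-control blood H19/ICR1 betas (for the GOM
#'   threshold); NULL disables blood GOM calls.
#' @param panel triage gene panel.
#' @param config a [bwt_config()] list.
#' @return list with `icr_calls`, `triage`, `control_stats`, `pairs` (list
#'   of `PairConcordance`), `reports` (list of `PatientReport`), `summary`.
#' @export
analyze_cohort <- function(beta, samples, germline = NULL, somatic = NULL,
                           cnv = NULL, control_betas = NULL,
                           panel = default_panel(), config = bwt_config()) {
  region11p <- config$region_11p15
  cnloh_samples <- character(0)
  if (!is.null(cnv) && nrow(cnv)) {
    hit <- cnv$chrom == region11p$chrom & as.logical(cnv$cnloh) &
      cnv$start <= region11p$end & cnv$end >= region11p$start
    cnloh_samples <- unique(cnv$sample_id[hit])
  }
  icr <- call_icr_status(beta, samples, cnloh_samples, config)
  icr <- merge(icr, as.data.frame(samples)[, c("sample_id", "patient_id",
                                               "tissue")], by = "sample_id")

  pp <- if (!is.null(germline) && nrow(germline)) {
    patients_with_predisposition(germline, panel, config)
  } else {
    list(patients = data.frame(patient_id = character(),
                               germline_positive = logical(),
                               n_included = integer(), genes = character()),
         gene_counts = data.frame())
  }

  control_stats <- if (!is.null(control_betas)) gom_threshold(control_betas,
                                                              config$gom_multiplier)

  pids <- unique(samples$patient_id)
  pairs <- list()
  reports <- list()
  for (p in pids) {
    pi <- icr[icr$patient_id == p, , drop = FALSE]
    tum <- pi[pi$tissue == "tumor", , drop = FALSE]
    kid <- pi[pi$tissue == "kidney", , drop = FALSE]
    bld <- pi[pi$tissue == "blood", , drop = FALSE]
    gp_row <- pp$patients[pp$patients$patient_id == p, , drop = FALSE]
    gpos <- nrow(gp_row) > 0 && isTRUE(gp_row$germline_positive)
    genes <- if (nrow(gp_row)) gp_row$genes else ""
    blood_gom <- if (!is.null(control_stats) && nrow(bld)) {
      call_low_level_gom(bld$h19_beta[1], control_stats)
    } else NA
    if (nrow(tum) == 2L && !is.null(somatic) && nrow(somatic)) {
      get_set <- function(sid, cls) {
        s <- somatic[somatic$sample_id == sid & somatic$class == cls, ,
                     drop = FALSE]
        if (cls == "coding") s[, c("gene", "protein_change"), drop = FALSE]
        else s[, c("chrom", "pos", "ref", "alt"), drop = FALSE]
      }
      seg <- function(sid) if (!is.null(cnv))
        cnv[cnv$sample_id == sid, , drop = FALSE] else NULL
      pairs[[p]] <- pair_concordance(
        p,
        get_set(tum$sample_id[1], "coding"), get_set(tum$sample_id[2], "coding"),
        get_set(tum$sample_id[1], "noncoding"), get_set(tum$sample_id[2], "noncoding"),
        tum$status[1], tum$status[2],
        seg(tum$sample_id[1]), seg(tum$sample_id[2]), config)
    }
    reports[[p]] <- assign_mode(
      patient_id = p,
      germline_positive = gpos,
      tumor_statuses = tum$status,
      kidney_status = if (nrow(kid)) kid$status[1] else NA_character_,
      blood_gom = blood_gom,
      blood_cnloh_mosaic = if (nrow(bld))
        bld$sample_id[1] %in% cnloh_samples else NA,
      germline_genes = genes,
      blood_h19_beta = if (nrow(bld)) bld$h19_beta[1] else NA_real_)
  }
  list(icr_calls = icr, triage = pp, control_stats = control_stats,
       pairs = pairs, reports = reports, summary = cohort_summary(reports))
}
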