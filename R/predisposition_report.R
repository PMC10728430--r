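#' Assign the per-patient predisposition mode and mosaicism tier
#'
#' Two predominant routes to bilateral Wilms tumor are distinguished: a
#' pre-zygotic germline genetic variant detectable in blood
#' (`GERMLINE_GENETIC`), and post-zygotic mosaic 11p15.5 H19/ICR1
#' hypermethylation (`POSTZYGOTIC_MOSAIC_LOI`). A germline-positive triage
#' result takes precedence — tumor 11p15.5 LOH in such patients is a somatic
#' second hit, and germline carriers can rarely also show tumor LOI
#' (recorded as `loi_coannotation`). Otherwise any tumor with LOI yields the
#' mosaic mode; patients with neither are `UNCLASSIFIED`.
#'
#' The mosaicism evidence tier escalates with the anatomical spread of the
#' 11p15.5 alteration: `tumor_only`, `tumor_plus_kidney` (also in adjacent
#' non-diseased kidney), `tumor_kidney_blood` (additionally low-level blood
#' gain of methylation or a mosaic blood cnLOH call).
#'
#' @param patient_id patient identifier.
#' @param germline_positive logical triage outcome; `germline_genes` optional
#'   comma string.
#' @param tumor_statuses character vector of tumor imprinting statuses (>= 1).
#' @param kidney_status adjacent kidney status or NA.
#' @param blood_gom logical or NA: blood low-level gain of methylation.
#' @param blood_cnloh_mosaic logical or NA: mosaic 11p15.5 cnLOH in blood
#'   (sequencing-derived input flag).
#' @param germline_genes comma-separated gene list for reporting.
#' @param blood_h19_beta optional blood H19/ICR1 beta for reporting.
#' @return list of class `PatientReport`.
#' @export
assign_mode <- function(patient_id, germline_positive, tumor_statuses,
                        kidney_status = NA_character_, blood_gom = NA,
                        blood_cnloh_mosaic = NA, germline_genes = "",
                        blood_h19_beta = NA_real_) {
  if (length(tumor_statuses) == 0L) {
    stop_validation("patient %s has no tumor imprinting call", patient_id)
  }
  tumor_altered <- any(tumor_statuses %in% c("LOI", "LOH"))
  mode <- if (isTRUE(germline_positive)) {
    "GERMLINE_GENETIC"
  } else if (any(tumor_statuses == "LOI")) {
    "POSTZYGOTIC_MOSAIC_LOI"
  } else {
    "UNCLASSIFIED"
  }
  tier <- "none"
  if (tumor_altered) {
    tier <- "tumor_only"
    kidney_altered <- !is.na(kidney_status) &&
      kidney_status %in% c("LOI", "LOH")
    if (kidney_altered) {
      tier <- "tumor_plus_kidney"
      if (isTRUE(blood_gom) || isTRUE(blood_cnloh_mosaic)) {
        tier <- "tumor_kidney_blood"
      }
    }
  }
  structure(list(
    patient_id = patient_id,
    germline_positive = isTRUE(germline_positive),
    germline_genes = germline_genes,
    tumor_icr_statuses = tumor_statuses,
    kidney_icr_status = kidney_status,
    blood_h19_beta = blood_h19_beta,
    blood_gom = blood_gom,
    blood_cnloh_mosaic = blood_cnloh_mosaic,
    mode = mode,
    loi_coannotation = isTRUE(germline_positive) &&
      any(tumor_statuses == "LOI"),
    mosaic_tier = tier
  ), class = "PatientReport")
}

#' Imprinting status counts and fractions over a set of tumor calls
#'
#' @param statuses character vector of statuses.
#' @return data.frame `status`, `n`, `fraction` over
#'   `{ROI, LOI, LOH, INDETERMINATE}`; fractions sum to 1.
#' @export
icr_status_fractions <- function(statuses) {
  if (length(statuses) == 0L) stop_validation("no imprinting calls")
  levels <- c("ROI", "LOI", "LOH", "INDETERMINATE")
  bad <- setdiff(unique(statuses), levels)
  if (length(bad)) stop_validation("unknown status: %s",
                                   paste(bad, collapse = ", "))
  n <- vapply(levels, function(s) sum(statuses == s), 0L)
  data.frame(status = levels, n = as.integer(n),
             fraction = as.numeric(n) / length(statuses),
             stringsAsFactors = FALSE)
}

#' Association between germline status and tumor imprinting status
#'
#' Pearson chi-square (no continuity correction) on the contingency table of
#' per-tumor germline-positivity against imprinting status. INDETERMINATE
#' calls are excluded (their count is reported).
#'
#' @param germline_flag logical vector, one entry per tumor.
#' @param icr_status character vector of the tumors' statuses.
#' @return list with `statistic`, `p_value`, `table`,
#'   `n_indeterminate_excluded`.
#' @export
germline_icr_association <- function(germline_flag, icr_status) {
  stopifnot(length(germline_flag) == length(icr_status))
  keep <- icr_status != "INDETERMINATE"
  n_excl <- sum(!keep)
  g <- factor(ifelse(germline_flag[keep], "germline", "no_germline"))
  s <- factor(icr_status[keep])
  tab <- table(g, s)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop_validation("degenerate contingency table for association test")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       table = tab, n_indeterminate_excluded = n_excl)
}

#' Compare blood H19/ICR1 beta values between patient groups
#'
#' Two groups: Welch two-tailed t-test. Three or more: one-way ANOVA with
#' pairwise Welch t-tests corrected for multiple comparisons (Holm by
#' default). A Kolmogorov-Smirnov normality check per group is reported as a
#' diagnostic, not a gate.
#'
#' @param groups named list of numeric vectors (each n >= 2).
#' @param p_adjust_method correction for the pairwise tests
#'   (`"holm"`, `"bonferroni"`, ...; see [stats::p.adjust()]).
#' @return list with `test` (`"welch_t"` or `"anova"`), `p_value` (global),
#'   `pairwise` (data.frame of corrected pairwise p-values), `normality`
#'   (per-group KS p-values).
#' @export
blood_beta_group_comparison <- function(groups, p_adjust_method = "holm") {
  if (length(groups) < 2L) stop_validation("need at least 2 groups")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2L)) stop_validation("every group needs n >= 2")
  normality <- vapply(groups, function(x) {
    if (sd(x) == 0) return(NA_real_)
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x))$p.value)
  }, 0)
  if (length(groups) == 2L) {
    tt <- t.test(groups[[1]], groups[[2]], var.equal = FALSE)
    pw <- data.frame(group1 = names(groups)[1], group2 = names(groups)[2],
                     p_adj = tt$p.value, stringsAsFactors = FALSE)
    return(list(test = "welch_t", statistic = unname(tt$statistic),
                p_value = tt$p.value, pairwise = pw, normality = normality))
  }
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), ns))
  fit <- aov(values ~ grp)
  p_global <- summary(fit)[[1]][["Pr(>F)"]][1]
  combos <- utils::combn(names(groups), 2)
  raw <- apply(combos, 2, function(pair) {
    t.test(groups[[pair[1]]], groups[[pair[2]]], var.equal = FALSE)$p.value
  })
  pw <- data.frame(group1 = combos[1, ], group2 = combos[2, ],
                   p_adj = p.adjust(raw, method = p_adjust_method),
                   stringsAsFactors = FALSE)
  list(test = "anova", statistic = summary(fit)[[1]][["F value"]][1],
       p_value = p_global, pairwise = pw, normality = normality)
}

#' Correlation between tumor purity and region methylation
#'
#' Pearson product-moment correlation with a two-sided test. Positive for
#' H19/ICR1 in hypermethylated (LOI/LOH) tumors and negative for ICR2 in LOH
#' tumors: low-purity samples are pulled towards the normal-tissue baseline,
#' which confounds threshold classification.
#'
#' @param purities,betas numeric vectors, n >= 3.
#' @return list with `r` and `p_value`.
#' @export
purity_beta_correlation <- function(purities, betas) {
  ok <- is.finite(purities) & is.finite(betas)
  if (sum(ok) < 3L) stop_validation("need at least 3 finite pairs")
  if (sd(purities[ok]) == 0 || sd(betas[ok]) == 0) {
    stop_validation("constant input: correlation undefined")
  }
  ct <- cor.test(purities[ok], betas[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Cohort summary across patient reports
#'
#' @param reports list of `PatientReport` objects.
#' @return list with `n_patients`, `mode_counts`, `tier_counts`,
#'   `icr_fractions` (over all tumor calls).
#' @export
cohort_summary <- function(reports) {
  modes <- vapply(reports, `[[`, "", "mode")
  tiers <- vapply(reports, `[[`, "", "mosaic_tier")
  statuses <- unlist(lapply(reports, `[[`, "tumor_icr_statuses"))
  list(
    n_patients = length(reports),
    mode_counts = as.list(table(modes)),
    tier_counts = as.list(table(tiers)),
    icr_fractions = icr_status_fractions(statuses)
  )
}
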