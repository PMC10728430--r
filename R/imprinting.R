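#' Mean beta over an imprinting control region
#'
#' Arithmetic mean of beta over probes with
#' `region$start <= pos <= region$end` on `region$chrom` (1-based,
#' end-inclusive at both ends).
#'
#' @param mat a `ProbeBetaMatrix`.
#' @param sample_id sample column to summarise.
#' @param region a region list as returned by [icr_region()].
#' @return list with `mean_beta` and `n_probes`.
#' @export
region_mean_beta <- function(mat, sample_id, region) {
  if (!sample_id %in% beta_samples(mat)) {
    stop_validation("sample '%s' not in beta matrix", sample_id)
  }
  in_region <- mat$chrom == region$chrom &
    mat$pos >= region$start & mat$pos <= region$end
  b <- mat[[sample_id]][in_region]
  b <- b[!is.na(b)]
  if (length(b) == 0L) {
    stop(errorCondition(
      sprintf("no probes in region %s for sample %s", region$name, sample_id),
      class = c("bwt_empty_region_error", "error")))
  }
  list(mean_beta = mean(b), n_probes = length(b))
}

#' Convert beta to M value
#'
#' M = log2(beta / (1 - beta)), after clipping beta to `[eps, 1 - eps]` so the
#' transform is defined at 0 and 1.
#'
#' @param beta numeric vector in \[0, 1\].
#' @param eps clipping epsilon (default from [bwt_config()]).
#' @return numeric vector of M values.
#' @export
beta_to_m <- function(beta, eps = bwt_config()$clip_eps) {
  b <- pmin(pmax(beta, eps), 1 - eps)
  log2(b / (1 - b))
}

#' Classify 11p15.5 imprinting status from region betas
#'
#' Threshold rules on the two region means:
#' \itemize{
#'   \item H19/ICR1 < 0.7 and ICR2 > 0.3: ROI (retention of imprinting)
#'   \item H19/ICR1 > 0.7 and ICR2 > 0.3: LOI (loss of imprinting,
#'     H19/ICR1 hypermethylation)
#'   \item H19/ICR1 > 0.7 and ICR2 < 0.3: LOH (copy-neutral loss of
#'     heterozygosity / paternal uniparental disomy)
#' }
#' Values exactly at a threshold fall in no stated cell and return
#' INDETERMINATE with a warning (the rules are strict inequalities). A
#' sequencing-derived cnLOH call (`cnloh_override = TRUE`) forces LOH
#' regardless of beta.
#'
#' @param h19_beta mean H19/ICR1 beta.
#' @param icr2_beta mean KCNQ1OT1/ICR2 beta.
#' @param cnloh_override logical; cnLOH detected from sequencing.
#' @param config a [bwt_config()] list.
#' @return one of `"ROI"`, `"LOI"`, `"LOH"`, `"INDETERMINATE"`.
#' @export
classify_icr_status <- function(h19_beta, icr2_beta, cnloh_override = FALSE,
                                config = bwt_config()) {
  if (isTRUE(cnloh_override)) return("LOH")
  if (is.na(h19_beta) || is.na(icr2_beta)) {
    stop_validation("missing region beta for imprinting classification")
  }
  hi <- config$thresholds$h19_hyper
  lo <- config$thresholds$icr2_hypo
  if (h19_beta < hi && icr2_beta > lo) return("ROI")
  if (h19_beta > hi && icr2_beta > lo) return("LOI")
  if (h19_beta > hi && icr2_beta < lo) return("LOH")
  warning("betas fall in no classification cell (boundary or hypomethylated H19); returning INDETERMINATE")
  "INDETERMINATE"
}

#' Call imprinting status for every sample in a beta matrix
#'
#' @param mat a `ProbeBetaMatrix`.
#' @param sheet optional `SampleSheet` restricting/ordering samples.
#' @param cnloh_samples character vector of sample ids with a
#'   sequencing-derived 11p15.5 cnLOH call.
#' @param config a [bwt_config()] list.
#' @return data.frame of class `IcrCalls`: `sample_id`, `h19_beta`,
#'   `icr2_beta`, `n_probes_h19`, `n_probes_icr2`, `cnloh_override`,
#'   `status`.
#' @export
call_icr_status <- function(mat, sheet = NULL, cnloh_samples = character(),
                            config = bwt_config()) {
  ids <- if (is.null(sheet)) beta_samples(mat) else
    intersect(sheet$sample_id, beta_samples(mat))
  h19 <- config$regions$H19_ICR1
  icr2 <- config$regions$KCNQ1OT1_ICR2
  rows <- lapply(ids, function(s) {
    a <- region_mean_beta(mat, s, h19)
    b <- region_mean_beta(mat, s, icr2)
    ov <- s %in% cnloh_samples
    status <- suppressWarnings(
      classify_icr_status(a$mean_beta, b$mean_beta, ov, config))
    data.frame(sample_id = s, h19_beta = a$mean_beta, icr2_beta = b$mean_beta,
               n_probes_h19 = a$n_probes, n_probes_icr2 = b$n_probes,
               cnloh_override = ov, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("IcrCalls", "data.frame")
  out
}

#' Expected observed region betas under the tumor-purity mixture model
#'
#' A tumor sample is modelled as a linear mixture of tumor cells in a pure
#' imprinting state and contaminating normal cells:
#' `beta_obs = p * beta_state + (1 - p) * beta_normal`. Pure-state betas
#' default to LOI (1.0, 0.5), LOH (1.0, 0.0), ROI (0.5, 0.5); the normal
#' baseline defaults to (0.5, 0.5).
#'
#' @param purity mixing fraction p in \[0, 1\].
#' @param state `"ROI"`, `"LOI"` or `"LOH"`.
#' @param config a [bwt_config()] list (pure-state and normal betas).
#' @return named numeric vector `c(h19 = ..., icr2 = ...)`.
#' @export
expected_observed_beta <- function(purity, state, config = bwt_config()) {
  if (is.na(purity) || purity < 0 || purity > 1) {
    stop_validation("purity must be in [0,1]")
  }
  pure <- config$pure_state_beta[[state]]
  if (is.null(pure)) stop_validation("unknown imprinting state '%s'", state)
  normal <- config$normal_beta
  purity * pure + (1 - purity) * normal
}

#' Estimate the mosaic fraction from observed region betas
#'
#' Closed-form inversion of the mixture model: a fraction f of cells in the
#' altered state shifts H19/ICR1 beta from 0.5 towards 1 (LOI and LOH) and,
#' for LOH, ICR2 beta from 0.5 towards 0. LOI uses `f = 2 * (h19 - 0.5)`;
#' LOH averages the H19 and ICR2 inversions. Estimates are clipped to
#' \[0, 1\], which absorbs measurement noise around the extremes.
#'
#' @param h19_beta observed mean H19/ICR1 beta.
#' @param icr2_beta observed mean ICR2 beta (required for LOH).
#' @param state `"LOI"` or `"LOH"`.
#' @return list of class `MosaicEstimate`: `fraction`, `state`, `basis`.
#' @export
estimate_mosaic_fraction <- function(h19_beta, icr2_beta = NA_real_,
                                     state = c("LOI", "LOH")) {
  state <- match.arg(state)
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  f_h19 <- 2 * (h19_beta - 0.5)
  if (state == "LOI") {
    f <- clip01(f_h19)
    basis <- "h19"
  } else {
    if (is.na(icr2_beta)) {
      f <- clip01(f_h19)
      basis <- "h19"
    } else {
      f <- clip01(mean(c(f_h19, 2 * (0.5 - icr2_beta))))
      basis <- "h19+icr2"
    }
  }
  structure(list(fraction = f, state = state, basis = basis),
            class = "MosaicEstimate")
}

#' Control-cohort statistics and the low-level GOM threshold
#'
#' Mean, sample standard deviation (n - 1 denominator) and the
#' gain-of-methylation threshold `mean + k * SD` (k = 2 by default) of a
#' healthy-control blood H19/ICR1 beta vector.
#'
#' @param control_betas numeric vector, n >= 2.
#' @param multiplier SD multiplier k.
#' @return list of class `ControlCohortStats`: `mean_beta`, `sd_beta`, `n`,
#'   `gom_threshold`.
#' @export
gom_threshold <- function(control_betas, multiplier = bwt_config()$gom_multiplier) {
  x <- control_betas[!is.na(control_betas)]
  if (length(x) < 2L) {
    stop(errorCondition("need at least 2 control betas",
                        class = c("bwt_insufficient_controls_error", "error")))
  }
  m <- mean(x); s <- sd(x)
  structure(list(mean_beta = m, sd_beta = s, n = length(x),
                 gom_threshold = m + multiplier * s),
            class = "ControlCohortStats")
}

#' Call low-level gain of methylation in blood
#'
#' TRUE iff the blood H19/ICR1 beta strictly exceeds the control-cohort
#' threshold (mean + 2 SD). A beta exactly at the threshold is not a call.
#'
#' @param blood_h19_beta numeric vector of blood H19/ICR1 betas.
#' @param stats a `ControlCohortStats` from [gom_threshold()].
#' @return logical vector.
#' @export
call_low_level_gom <- function(blood_h19_beta, stats) {
  blood_h19_beta > stats$gom_threshold
}

#' Select the most variable probes
#'
#' Ranks probes by variance of beta (or M values, per `scale`) across samples,
#' after excluding sex-chromosome probes, and keeps the top `n`. If fewer than
#' `n` probes remain after exclusion all are returned with a warning.
#'
#' @param mat a `ProbeBetaMatrix`.
#' @param n number of probes to keep (default 10000).
#' @param exclude_chroms chromosomes to drop (default chrX, chrY).
#' @param scale `"beta"` or `"M"`: scale on which variance is computed.
#' @return the reduced `ProbeBetaMatrix`, ordered by decreasing variance.
#' @export
select_top_variable_probes <- function(mat, n = 10000,
                                       exclude_chroms = c("chrX", "chrY"),
                                       scale = bwt_config()$top_variable_scale) {
  keep <- !(mat$chrom %in% exclude_chroms)
  sub <- mat[keep, , drop = FALSE]
  samp <- beta_samples(sub)
  vals <- as.matrix(sub[, samp, drop = FALSE])
  if (identical(scale, "M")) vals <- beta_to_m(vals)
  v <- apply(vals, 1L, var, na.rm = TRUE)
  if (nrow(sub) <= n) {
    if (nrow(sub) < n) warning(sprintf(
      "only %d probes available after exclusion; returning all", nrow(sub)))
    ord <- order(v, decreasing = TRUE)
    out <- sub[ord, , drop = FALSE]
  } else {
    ord <- order(v, decreasing = TRUE)[seq_len(n)]
    out <- sub[ord, , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("ProbeBetaMatrix", "data.frame")
  out
}
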