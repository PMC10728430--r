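#' Default analysis configuration
#'
#' Central store of the constants the pipeline uses: the GRCh38 coordinates of
#' the two 11p15.5 imprinting control regions, the imprinting classification
#' thresholds, the gain-of-methylation multiplier, the beta clipping epsilon
#' used for M-value conversion, the pure-state beta table for the tumor-purity
#' mixture model, and the atypical-pair cutoffs for origin classification.
#'
#' All values can be overridden by passing a named list of replacements; only
#' supplied names are changed.
#'
#' @param ... named overrides, e.g. `bwt_config(gom_multiplier = 3)`.
#' @return a named list with class `bwt_config`.
#' @examples
#' cfg <- bwt_config()
#' cfg$thresholds$h19_hyper
#' @export
bwt_config <- function(...) {
  cfg <- list(
    regions = list(
      H19_ICR1 = list(name = "H19_ICR1", chrom = "chr11",
                      start = 2019974L, end = 2024738L),
      KCNQ1OT1_ICR2 = list(name = "KCNQ1OT1_ICR2", chrom = "chr11",
                           start = 2721228L, end = 2722228L)
    ),
    thresholds = list(
      h19_hyper = 0.7,   # H19/ICR1 hypermethylation cutoff
      icr2_hypo = 0.3    # KCNQ1OT1/ICR2 hypomethylation cutoff
    ),
    gom_multiplier = 2,  # control mean + k * SD defines low-level GOM
    clip_eps = 1e-6,     # beta clipping before logit2 (M value)
    # pure-state region betas for the purity mixture model
    pure_state_beta = list(
      ROI = c(h19 = 0.5, icr2 = 0.5),
      LOI = c(h19 = 1.0, icr2 = 0.5),
      LOH = c(h19 = 1.0, icr2 = 0.0)
    ),
    normal_beta = c(h19 = 0.5, icr2 = 0.5),
    # germline triage
    vaf_alpha = 0.05,
    vaf_min_delta = 0.15,
    # pair concordance
    atypical_shared_noncoding = 20L,
    atypical_cnv_similarity = 0.9,
    cnv_bin_size = 1e6,
    breakpoint_tol_bp = 10000L,
    # window used to locate the 11p15.5 cnLOH segment (spans both ICRs)
    region_11p15 = list(chrom = "chr11", start = 2000000L, end = 2800000L),
    top_variable_scale = "beta"  # or "M"
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1]]
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "bwt_config")
}

#' Read configuration overrides from a JSON file
#'
#' @param path path to a JSON file whose top-level names match [bwt_config()]
#'   entries.
#' @return a `bwt_config` list with the file's entries applied over defaults.
#' @export
read_config <- function(path) {
  overrides <- jsonlite::read_json(path, simplifyVector = TRUE)
  bwt_config(overrides)
}

#' Imprinting control region coordinates
#'
#' @param name one of `"H19_ICR1"`, `"KCNQ1OT1_ICR2"`.
#' @param config a [bwt_config()] list.
#' @return list with `name`, `chrom`, `start`, `end` (1-based, end-inclusive,
#'   GRCh38).
#' @export
icr_region <- function(name = c("H19_ICR1", "KCNQ1OT1_ICR2"),
                       config = bwt_config()) {
  name <- match.arg(name)
  config$regions[[name]]
}
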