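#' Synthetic cohort configuration
#'
#' Defaults encode the cohort structure the pipeline is meant to emulate:
#' the mode mixture approximates the reported cohort fractions (41%
#' germline-positive; most of the remainder mosaic 11p15.5 LOI), kidney
#' mosaic fractions centre on 0.6 (clonal nephrogenesis is extensive in
#' adjacent kidney), blood fractions on 0.05 (low-level GOM only), tumor
#' purity is Uniform(0.5, 1), probe noise SD is 0.02 on the beta scale,
#' LOI pairs share a truncated-Poisson(2) >= 1 number of noncoding variants
#' against ~Poisson(80) private ones, and 71.4% of germline WT1-carrier
#' tumors acquire a CTNNB1 exon-3 variant.
#'
#' @param n_patients number of patients.
#' @param mode_mix named numeric: probabilities for `germline`, `mosaic_loi`,
#'   `other`; must sum to 1.
#' @param wt1_fraction fraction of germline carriers whose variant is WT1.
#' @param kidney_frac_shape Beta shape parameters for the kidney mosaic
#'   fraction (mean 0.6).
#' @param blood_frac_shape Beta shape parameters for the blood mosaic
#'   fraction (mean 0.05).
#' @param purity_range Uniform range for tumor purity.
#' @param noise_sd probe-level beta noise SD (truncated to \[0,1\]).
#' @param n_probes_h19,n_probes_icr2,n_background probe counts.
#' @param shared_noncoding_lambda,private_noncoding_lambda Poisson rates.
#' @param ctnnb1_prob probability a WT1-carrier tumor has a CTNNB1 exon-3
#'   variant.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 50,
                          mode_mix = c(germline = 0.41, mosaic_loi = 0.45,
                                       other = 0.14),
                          wt1_fraction = 0.36,
                          kidney_frac_shape = c(6, 4),
                          blood_frac_shape = c(1, 19),
                          purity_range = c(0.5, 1),
                          noise_sd = 0.02,
                          n_probes_h19 = 10L,
                          n_probes_icr2 = 5L,
                          n_background = 500L,
                          shared_noncoding_lambda = 2,
                          private_noncoding_lambda = 80,
                          ctnnb1_prob = 0.714) {
  if (abs(sum(mode_mix) - 1) > 1e-8) {
    stop(errorCondition("mode mixture must sum to 1",
                        class = c("bwt_config_error", "error")))
  }
  if (any(mode_mix < 0) || noise_sd < 0 || shared_noncoding_lambda < 0 ||
      private_noncoding_lambda < 0) {
    stop(errorCondition("rates and probabilities must be >= 0",
                        class = c("bwt_config_error", "error")))
  }
  structure(as.list(environment()), class = "cohort_config")
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

rtrunc_pois <- function(n, lambda, min = 1L) {
  out <- rpois(n, lambda)
  while (any(out < min)) out[out < min] <- rpois(sum(out < min), lambda)
  out
}

random_noncoding <- function(n, id_pool) {
  # draws distinct genomic point variants
  if (n == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample(id_pool, n),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic multi-tissue cohort
#'
#' Each patient contributes a blood sample, an adjacent-kidney sample and two
#' tumors (synchronous bilateral disease). Latent region betas follow the
#' forward mixture model of [expected_observed_beta()]: germline WT1 carriers
#' get LOH tumors with 11p cnLOH segments (random, non-identical breakpoints
#' between the two tumors) and CTNNB1 exon-3 variants; mosaic-LOI patients
#' get LOI tumors arising from a clonally expanded kidney lineage (kidney and
#' blood carry the planted mosaic fractions) and their tumor pairs share
#' noncoding variants; other patients are ROI throughout. Per-probe beta is
#' the tissue's latent region beta plus truncated Gaussian noise.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return list of class `BwtCohort` with elements `beta`
#'   (`ProbeBetaMatrix`), `samples` (`SampleSheet`), `germline`
#'   (`GermlineVariants`), `somatic` (variant table), `cnv` (`CnvSegments`)
#'   and `truth` (per-patient ground-truth data.frame; never read by the
#'   pipeline).
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  set.seed(seed)
  n <- config$n_patients
  pid <- sprintf("P%03d", seq_len(n))
  modes <- sample(names(config$mode_mix), n, replace = TRUE,
                  prob = config$mode_mix)
  wt1 <- modes == "germline" & runif(n) < config$wt1_fraction
  f_kidney <- ifelse(modes == "mosaic_loi",
                     rbeta(n, config$kidney_frac_shape[1],
                           config$kidney_frac_shape[2]), 0)
  f_blood <- ifelse(modes == "mosaic_loi",
                    rbeta(n, config$blood_frac_shape[1],
                          config$blood_frac_shape[2]), 0)
  pur <- matrix(runif(2 * n, config$purity_range[1], config$purity_range[2]),
                ncol = 2)

  # probe scaffold: ICR probes inside the two windows + autosomal background
  # (with a few sex-chromosome probes so the exclusion filter has work to do)
  h19 <- icr_region("H19_ICR1")
  icr2 <- icr_region("KCNQ1OT1_ICR2")
  pos_h19 <- sort(sample(seq(h19$start, h19$end), config$n_probes_h19))
  pos_icr2 <- sort(sample(seq(icr2$start, icr2$end), config$n_probes_icr2))
  n_bg <- config$n_background
  n_sex <- max(2L, n_bg %/% 25L)
  bg_chrom <- c(sample(paste0("chr", 1:22), n_bg - n_sex, replace = TRUE),
                sample(c("chrX", "chrY"), n_sex, replace = TRUE))
  bg_pos <- sample(1e7:2e8, n_bg)
  probes <- data.frame(
    probe_id = c(sprintf("cg_h19_%02d", seq_along(pos_h19)),
                 sprintf("cg_icr2_%02d", seq_along(pos_icr2)),
                 sprintf("cg_bg_%04d", seq_len(n_bg))),
    chrom = c(rep("chr11", length(pos_h19) + length(pos_icr2)), bg_chrom),
    pos = as.integer(c(pos_h19, pos_icr2, bg_pos)),
    stringsAsFactors = FALSE
  )
  bg_baseline <- runif(n_bg, 0.2, 0.8)

  samples <- list(); betas <- list(); cnv <- list()
  somatic <- list(); germline <- list(); truth <- list()
  tumor_states <- character(0)
  ctnnb1_changes <- c("p.S45F", "p.S45P", "p.S45del", "p.T41A")
  noncoding_pool <- 1e6:9e6

  latent_pair <- function(state, f) {
    # region-level (h19, icr2) for a tissue with mosaic fraction f
    (1 - f) * bwt_config()$normal_beta + f * bwt_config()$pure_state_beta[[state]]
  }
  emit <- function(h19b, icr2b) {
    # per-probe beta: latent region mean + truncated Gaussian probe noise
    clip01(c(rnorm(length(pos_h19), h19b, config$noise_sd),
             rnorm(length(pos_icr2), icr2b, config$noise_sd),
             rnorm(n_bg, bg_baseline, config$noise_sd)))
  }

  for (i in seq_len(n)) {
    p <- pid[i]
    mode <- modes[i]
    tumor_state <- switch(mode, germline = if (wt1[i]) "LOH" else "ROI",
                          mosaic_loi = "LOI", other = "ROI")
    sid <- c(blood = paste0(p, "_blood"), kidney = paste0(p, "_kidney"),
             t1 = paste0(p, "_tumorR"), t2 = paste0(p, "_tumorL"))
    samples[[i]] <- data.frame(
      sample_id = unname(sid),
      patient_id = p,
      tissue = c("blood", "kidney", "tumor", "tumor"),
      laterality = c("unknown", "unknown", "right", "left"),
      purity = c(NA, NA, pur[i, 1], pur[i, 2]),
      cohort = "synthetic",
      stringsAsFactors = FALSE
    )
    lat_blood <- latent_pair(if (mode == "mosaic_loi") "LOI" else "ROI",
                             f_blood[i])
    lat_kidney <- latent_pair(if (mode == "mosaic_loi") "LOI" else "ROI",
                              f_kidney[i])
    lat_t1 <- expected_observed_beta(pur[i, 1], tumor_state)
    lat_t2 <- expected_observed_beta(pur[i, 2], tumor_state)
    betas[[sid["blood"]]] <- emit(lat_blood["h19"], lat_blood["icr2"])
    betas[[sid["kidney"]]] <- emit(lat_kidney["h19"], lat_kidney["icr2"])
    betas[[sid["t1"]]] <- emit(lat_t1["h19"], lat_t1["icr2"])
    betas[[sid["t2"]]] <- emit(lat_t2["h19"], lat_t2["icr2"])

    # germline variants: carriers get an including variant, everyone may get
    # a benign panel variant (excluded by triage)
    if (mode == "germline") {
      gene <- if (wt1[i]) "WT1" else
        sample(c("TRIM28", "NYNRIN", "REST", "BLM", "CDC73", "ASXL1"), 1)
      germline[[length(germline) + 1L]] <- data.frame(
        patient_id = p, gene = gene,
        variant_class = sample(c("nonsense", "indel"), 1),
        protein_change = "p.X1*", clinvar = "unreported",
        provean = "missing", polyphen = "missing",
        germline_ref = 50L, germline_alt = 48L,
        tumor_ref = 20L, tumor_alt = 80L, stringsAsFactors = FALSE)
    }
    if (runif(1) < 0.3) {
      germline[[length(germline) + 1L]] <- data.frame(
        patient_id = p, gene = sample(c("TP53", "BRCA2", "DICER1"), 1),
        variant_class = "missense", protein_change = "p.A100T",
        clinvar = "benign", provean = "neutral", polyphen = "benign",
        germline_ref = 50L, germline_alt = 50L,
        tumor_ref = 50L, tumor_alt = 50L, stringsAsFactors = FALSE)
    }

    # somatic noncoding variants: shared set (mosaic-LOI pairs) + private
    n_shared <- if (mode == "mosaic_loi")
      rtrunc_pois(1, config$shared_noncoding_lambda) else 0L
    shared_nc <- random_noncoding(n_shared, noncoding_pool)
    som_rows <- list()
    for (tj in c("t1", "t2")) {
      priv <- random_noncoding(rpois(1, config$private_noncoding_lambda),
                               noncoding_pool)
      nc <- rbind(shared_nc, priv)
      if (nrow(nc)) som_rows[[tj]] <- data.frame(
        sample_id = sid[[tj]], class = "noncoding", gene = NA_character_,
        protein_change = NA_character_, nc, stringsAsFactors = FALSE)
    }
    # WT1-carrier tumors: cnLOH at 11p with non-identical breakpoints and
    # CTNNB1 exon-3 coding variants
    if (wt1[i]) {
      used <- character(0)
      for (tj in c("t1", "t2")) {
        cnv[[length(cnv) + 1L]] <- data.frame(
          sample_id = sid[[tj]], chrom = "chr11",
          start = 1L + sample(0:2e6, 1), end = as.integer(3e6 + sample(0:2e6, 1)),
          value = 0, cnloh = TRUE, stringsAsFactors = FALSE)
        if (runif(1) < config$ctnnb1_prob) {
          change <- sample(setdiff(ctnnb1_changes, used), 1)
          used <- c(used, change)
          som_rows[[paste0(tj, "_ctnnb1")]] <- data.frame(
            sample_id = sid[[tj]], class = "coding", gene = "CTNNB1",
            protein_change = change, chrom = "chr3", pos = 41224610L,
            ref = "C", alt = "T", stringsAsFactors = FALSE)
        }
      }
    }
    if (length(som_rows)) somatic[[i]] <- do.call(rbind, som_rows)

    truth[[i]] <- data.frame(
      patient_id = p, mode = mode, wt1_carrier = wt1[i],
      tumor_state = tumor_state,
      f_kidney = f_kidney[i], f_blood = f_blood[i],
      purity_t1 = pur[i, 1], purity_t2 = pur[i, 2],
      n_shared_noncoding = n_shared, stringsAsFactors = FALSE)
  }

  beta_df <- cbind(probes, as.data.frame(betas, check.names = FALSE))
  structure(list(
    beta = as_beta_matrix(beta_df),
    samples = as_sample_sheet(do.call(rbind, samples)),
    germline = as_germline_variants(do.call(rbind, germline)),
    somatic = do.call(rbind, somatic[!vapply(somatic, is.null, TRUE)]),
    cnv = if (length(cnv)) as_cnv_segments(do.call(rbind, cnv)) else
      as_cnv_segments(data.frame(sample_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 value = numeric(), cnloh = logical())),
    truth = do.call(rbind, truth)
  ), class = "BwtCohort")
}

#' Generate a healthy-control blood H19/ICR1 beta vector
#'
#' Normal draws (defaults: the control cohort's summary, mean 0.499,
#' SD 0.0248) truncated to \[0, 1\].
#'
#' @param n number of controls (>= 2).
#' @param mean,sd Normal parameters.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
generate_control_blood <- function(n, mean = 0.499, sd = 0.0248,
                                   seed = NULL) {
  if (n < 2L) stop_validation("need n >= 2 controls")
  if (!is.null(seed)) set.seed(seed)
  clip01(rnorm(n, mean, sd))
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Emits the same formats the readers consume: `beta_matrix.tsv`,
#' `samples.tsv`, `germline_variants.tsv`, `somatic_variants.tsv`,
#' `cnv_segments.tsv` and `ground_truth.tsv`.
#'
#' @param cohort a `BwtCohort`.
#' @param dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta_matrix.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  write_germline_variants(cohort$germline,
                          file.path(dir, "germline_variants.tsv"))
  write_somatic_variants(cohort$somatic,
                         file.path(dir, "somatic_variants.tsv"))
  write_cnv_segments(cohort$cnv, file.path(dir, "cnv_segments.tsv"))
  write_tsv(cohort$truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
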