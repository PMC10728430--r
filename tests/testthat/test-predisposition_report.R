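test_that("mode assignment follows the germline-first decision order", {
  # germline WT1 carrier whose tumors show 11p15.5 LOH (the second-hit route)
  r <- assign_mode("P1", TRUE, c("LOH", "LOH"), germline_genes = "WT1")
  expect_equal(r$mode, "GERMLINE_GENETIC")
  expect_equal(r$mosaic_tier, "tumor_only")
  expect_false(r$loi_coannotation)

  # mosaic route with kidney and blood evidence
  r <- assign_mode("P2", FALSE, c("LOI", "LOI"), kidney_status = "LOI",
                   blood_gom = TRUE)
  expect_equal(r$mode, "POSTZYGOTIC_MOSAIC_LOI")
  expect_equal(r$mosaic_tier, "tumor_kidney_blood")

  # tier escalation requires kidney before blood counts
  r <- assign_mode("P3", FALSE, "LOI", kidney_status = "ROI",
                   blood_gom = TRUE)
  expect_equal(r$mosaic_tier, "tumor_only")
  r <- assign_mode("P4", FALSE, "LOI", kidney_status = "LOI",
                   blood_gom = FALSE)
  expect_equal(r$mosaic_tier, "tumor_plus_kidney")
  # a mosaic blood cnLOH flag also reaches the top tier
  r <- assign_mode("P5", FALSE, "LOH", kidney_status = "LOH",
                   blood_gom = FALSE, blood_cnloh_mosaic = TRUE)
  expect_equal(r$mosaic_tier, "tumor_kidney_blood")

  r <- assign_mode("P6", FALSE, c("ROI", "ROI"))
  expect_equal(r$mode, "UNCLASSIFIED")
  expect_equal(r$mosaic_tier, "none")

  # germline carrier with tumor LOI keeps the germline mode, co-annotated
  r <- assign_mode("P7", TRUE, c("LOI", "ROI"))
  expect_equal(r$mode, "GERMLINE_GENETIC")
  expect_true(r$loi_coannotation)

  expect_error(assign_mode("P8", FALSE, character(0)),
               class = "bwt_validation_error")
})

test_that("status fractions are exact and sum to one", {
  calls <- c(rep("ROI", 15), rep("LOH", 25), rep("LOI", 59))
  fr <- icr_status_fractions(calls)
  expect_equal(fr$n[fr$status == "LOI"], 59L)
  expect_equal(fr$fraction[fr$status == "ROI"], 15 / 99)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(round(100 * fr$fraction[fr$status == "LOI"], 1), 59.6)

  single <- icr_status_fractions("LOI")
  expect_equal(single$fraction[single$status == "LOI"], 1)
  expect_error(icr_status_fractions(character(0)),
               class = "bwt_validation_error")
})

test_that("germline-ICR association matches the chi-square formula oracle", {
  # perfectly separated 2x2: hand-computed statistic is 20
  g <- rep(c(TRUE, FALSE), each = 10)
  s <- rep(c("LOH", "LOI"), each = 10)
  res <- germline_icr_association(g, s)
  expect_equal(res$statistic, 20, tolerance = 1e-12)
  expect_equal(res$statistic, chisq_oracle(res$table), tolerance = 1e-12)

  # independence: statistic 0
  g2 <- rep(c(TRUE, FALSE), 10)
  s2 <- rep(c("LOH", "LOH", "LOI", "LOI"), 5)
  res2 <- germline_icr_association(g2, s2)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_gt(res2$p_value, 0.99)

  # permutation invariance + oracle on random tables
  set.seed(23)
  for (i in 1:20) {
    g3 <- sample(c(TRUE, FALSE), 60, replace = TRUE)
    s3 <- sample(c("ROI", "LOI", "LOH"), 60, replace = TRUE)
    if (length(unique(g3)) < 2 || length(unique(s3)) < 2) next
    res3 <- germline_icr_association(g3, s3)
    expect_equal(res3$statistic, chisq_oracle(res3$table), tolerance = 1e-10)
    perm <- sample(60)
    expect_equal(germline_icr_association(g3[perm], s3[perm])$statistic,
                 res3$statistic, tolerance = 1e-12)
  }

  # a strongly coupled synthetic cohort is detected
  g4 <- rep(c(TRUE, FALSE), c(30, 70))
  s4 <- c(rep("LOH", 27), rep("ROI", 3), rep("LOI", 60), rep("ROI", 10))
  expect_lt(germline_icr_association(g4, s4)$p_value, 0.001)

  expect_error(germline_icr_association(rep(TRUE, 5), rep("LOI", 5)),
               class = "bwt_validation_error")
})

test_that("group comparison: t statistic formula, identical groups, power", {
  # hand Welch t on a 3+3 toy
  x <- c(0.1, 0.2, 0.3); y <- c(0.4, 0.6, 0.8)
  res <- blood_beta_group_comparison(list(a = x, b = y))
  tt_hand <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  expect_equal(res$statistic, tt_hand, tolerance = 1e-12)
  expect_equal(res$test, "welch_t")

  same <- blood_beta_group_comparison(list(a = x, b = x))
  expect_gt(same$p_value, 0.99)

  # power: N(0.50, 0.025) vs N(0.53, 0.03), n = 40, significant in >=95% of reps
  set.seed(29)
  hits <- mean(replicate(200, {
    blood_beta_group_comparison(list(
      roi = rnorm(40, 0.50, 0.025),
      loi = rnorm(40, 0.53, 0.030)))$p_value < 0.05
  }))
  expect_gte(hits, 0.95)

  # three groups: ANOVA route with Holm-corrected pairwise tests
  set.seed(30)
  g3 <- list(ctrl = rnorm(30, 0.499, 0.0248),
             uwt = rnorm(30, 0.521, 0.0258),
             bwt = rnorm(30, 0.534, 0.0298))
  res3 <- blood_beta_group_comparison(g3)
  expect_equal(res3$test, "anova")
  expect_equal(nrow(res3$pairwise), 3L)
  expect_lt(res3$p_value, 0.01)
  expect_error(blood_beta_group_comparison(list(a = 1)),
               class = "bwt_validation_error")
  expect_error(blood_beta_group_comparison(list(a = 1:3, b = 2)),
               class = "bwt_validation_error")
})

test_that("purity-beta correlation equals the covariance formula", {
  p <- seq(0.1, 1, by = 0.1)
  b <- 0.5 + 0.5 * p
  expect_equal(purity_beta_correlation(p, b)$r, 1, tolerance = 1e-12)

  set.seed(33)
  b2 <- b + rnorm(10, 0, 0.05)
  r_hand <- sum((p - mean(p)) * (b2 - mean(b2))) /
    sqrt(sum((p - mean(p))^2) * sum((b2 - mean(b2))^2))
  expect_equal(purity_beta_correlation(p, b2)$r, r_hand, tolerance = 1e-12)
  expect_error(purity_beta_correlation(rep(0.5, 10), b),
               class = "bwt_validation_error")
  expect_error(purity_beta_correlation(p[1:2], b[1:2]),
               class = "bwt_validation_error")
})

test_that("purity confounding has the reported sign structure", {
  # simulated LOI tumors: positive purity-H19 correlation; LOH tumors:
  # negative purity-ICR2 correlation
  set.seed(37)
  p <- runif(60, 0.3, 1)
  loi <- t(vapply(p, function(pp) expected_observed_beta(pp, "LOI"),
                  c(h19 = 0, icr2 = 0)))
  loh <- t(vapply(p, function(pp) expected_observed_beta(pp, "LOH"),
                  c(h19 = 0, icr2 = 0)))
  noise <- function(x) pmin(pmax(x + rnorm(length(x), 0, 0.02), 0), 1)
  expect_gt(purity_beta_correlation(p, noise(loi[, "h19"]))$r, 0)
  expect_lt(purity_beta_correlation(p, noise(loh[, "icr2"]))$r, 0)
})
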