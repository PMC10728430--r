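test_that("panel membership is case-insensitive and matches a linear scan", {
  panel <- default_panel()
  expect_true(in_panel("WT1", panel))
  expect_true(in_panel("wt1", panel))
  expect_false(in_panel("MYH7", panel))
  set.seed(5)
  genes <- sample(c(panel, "MYH7", "TTN", "BRCA1"), 50, replace = TRUE)
  scan_oracle <- vapply(genes, function(g) {
    hit <- FALSE
    for (p in panel) if (toupper(g) == toupper(p)) hit <- TRUE
    hit
  }, TRUE)
  expect_equal(unname(in_panel(genes, panel)), unname(scan_oracle))
  expect_error(in_panel("WT1", character(0)), class = "bwt_validation_error")
})

test_that("VAF enrichment test agrees with hypergeometric enumeration", {
  res <- vaf_enrichment_test(50, 50, 10, 90)
  expect_true(res$enriched)
  expect_equal(res$p_value, exact_test_oracle(50, 50, 10, 90),
               tolerance = 1e-10)
  # random small instances against the enumeration oracle
  set.seed(9)
  for (i in 1:25) {
    cts <- sample(0:30, 4, replace = TRUE)
    if (cts[1] + cts[2] == 0 || cts[3] + cts[4] == 0) next
    res <- vaf_enrichment_test(cts[1], cts[2], cts[3], cts[4])
    expect_equal(res$p_value, exact_test_oracle(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-10)
  }
})

test_that("VAF enrichment edge cases: no difference, zero effect, zero depth", {
  expect_false(vaf_enrichment_test(40, 40, 40, 40)$enriched)
  # huge depth, zero effect: significant p impossible, and delta floor guards
  res <- vaf_enrichment_test(5000, 5000, 5000, 5000)
  expect_false(res$enriched)
  res0 <- vaf_enrichment_test(0, 0, 10, 90)
  expect_false(res0$enriched)
  expect_true(is.na(res0$p_value))
})

test_that("triage rules fire in order, exactly one per variant", {
  panel <- c(default_panel(), "BRCA1")
  t_ <- function(...) triage_variant(toy_germline_variant(...), panel)

  v <- t_(gene = "MYH7", variant_class = "nonsense")
  expect_false(v$include); expect_equal(v$rule_fired, "panel_miss")

  v <- t_(gene = "WT1", variant_class = "nonsense", protein_change = "p.Q253*")
  expect_true(v$include); expect_equal(v$rule_fired, "indel_nonsense")
  expect_true(t_(gene = "WT1", variant_class = "indel")$include)

  v <- t_(gene = "TP53", variant_class = "missense", clinvar = "pathogenic")
  expect_true(v$include); expect_equal(v$rule_fired, "clinvar_pathogenic")
  expect_true(t_(gene = "TP53", variant_class = "missense",
                 clinvar = "likely_pathogenic")$include)

  # ClinVar benign excludes even with a damaging predictor (rule order)
  v <- t_(gene = "TP53", variant_class = "missense", clinvar = "benign",
          provean = "deleterious")
  expect_false(v$include); expect_equal(v$rule_fired, "clinvar_benign_excluded")

  # the VUS-with-damaging-predictor route (BRCA1 p.Q687P style)
  v <- t_(gene = "BRCA1", variant_class = "missense", clinvar = "vus",
          polyphen = "possibly_damaging", protein_change = "p.Q687P")
  expect_true(v$include); expect_equal(v$rule_fired, "predictor_damaging")
  expect_true(t_(gene = "PALB2", variant_class = "missense",
                 clinvar = "unreported", provean = "deleterious")$include)

  # splice VUS flows through the same uncertainty-plus-evidence rules
  v <- t_(gene = "DICER1", variant_class = "splice", clinvar = "vus",
          provean = "neutral", polyphen = "benign")
  expect_false(v$include); expect_equal(v$rule_fired, "none_matched")

  # VAF enrichment rescues an otherwise-unmatched VUS
  v <- t_(gene = "DICER1", variant_class = "splice", clinvar = "vus",
          provean = "neutral", polyphen = "benign",
          germline_ref = 50L, germline_alt = 50L,
          tumor_ref = 10L, tumor_alt = 90L)
  expect_true(v$include); expect_equal(v$rule_fired, "vaf_enrichment")
})

test_that("every variant fires exactly one rule over a randomized grid", {
  set.seed(13)
  panel <- default_panel()
  rules <- character(0)
  for (i in 1:200) {
    v <- toy_germline_variant(
      gene = sample(c(panel, "MYH7"), 1),
      variant_class = sample(c("indel", "nonsense", "missense", "splice",
                               "other_snv"), 1),
      clinvar = sample(c("benign", "likely_benign", "vus", "no_assertion",
                         "unreported", "likely_pathogenic", "pathogenic"), 1),
      provean = sample(c("deleterious", "neutral", "missing"), 1),
      polyphen = sample(c("benign", "possibly_damaging", "damaging",
                          "missing"), 1),
      germline_ref = sample(0:100, 1), germline_alt = sample(0:100, 1),
      tumor_ref = sample(0:100, 1), tumor_alt = sample(0:100, 1))
    verdict <- triage_variant(v, panel)
    expect_true(verdict$rule_fired %in%
                  c("panel_miss", "indel_nonsense", "clinvar_pathogenic",
                    "clinvar_benign_excluded", "predictor_damaging",
                    "vaf_enrichment", "none_matched"))
    if (verdict$include) {
      expect_true(verdict$rule_fired %in%
                    c("indel_nonsense", "clinvar_pathogenic",
                      "predictor_damaging", "vaf_enrichment"))
    }
    rules <- c(rules, verdict$rule_fired)
    # disabling the VAF rule never flips an include from rules 2-5
    no_vaf <- triage_variant(v, panel, bwt_config(vaf_alpha = 0))
    if (verdict$include && verdict$rule_fired != "vaf_enrichment") {
      expect_true(no_vaf$include)
      expect_equal(no_vaf$rule_fired, verdict$rule_fired)
    }
  }
  expect_gt(length(unique(rules)), 3L)  # the grid exercises several rules
})

test_that("patient-level rollup counts each patient once and tallies genes", {
  vs <- rbind(
    toy_germline_variant(patient_id = "P1", gene = "WT1",
                         variant_class = "nonsense"),
    toy_germline_variant(patient_id = "P1", gene = "TRIM28",
                         variant_class = "missense", clinvar = "pathogenic"),
    toy_germline_variant(patient_id = "P2", gene = "TP53",
                         variant_class = "missense", clinvar = "benign"))
  res <- patients_with_predisposition(vs)
  expect_equal(sum(res$patients$germline_positive), 1L)
  expect_equal(res$patients$n_included[res$patients$patient_id == "P1"], 2L)
  expect_equal(res$patients$genes[res$patients$patient_id == "P1"],
               "TRIM28,WT1")
  expect_equal(res$gene_counts$n_patients[res$gene_counts$gene == "WT1"], 1L)

  empty <- patients_with_predisposition(vs[0, ])
  expect_equal(nrow(empty$patients), 0L)

  # group-by oracle on a random table
  set.seed(3)
  ids <- sample(paste0("P", 1:8), 40, replace = TRUE)
  vs2 <- do.call(rbind, lapply(seq_along(ids), function(i)
    toy_germline_variant(patient_id = ids[i],
                         gene = sample(default_panel(), 1),
                         variant_class = sample(c("nonsense", "missense"), 1))))
  res2 <- patients_with_predisposition(vs2)
  tv <- triage_table(vs2)
  oracle <- tapply(tv$include, tv$patient_id, any)
  expect_equal(res2$patients$germline_positive,
               as.vector(oracle[res2$patients$patient_id]))
})
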