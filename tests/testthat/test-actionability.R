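# Biomarker matching, ESCAT tiering, trial-rule evaluation, germline alerts.

mk_call <- function(gene, label = "functionally_relevant",
                    direction = "loss_of_function", tier = "B",
                    origin = "somatic", zygosity = "heterozygous",
                    vaf = 0.3, key = NULL) {
  tibble::tibble(
    gene_symbol = gene, transcript_id = paste0("TX_", gene),
    chrom = paste0("ctg_", gene), pos = 1000L, ref = "A", alt = "T",
    variant_key = key %||% paste0(gene, ":g.1000A>T"),
    cdna_change = "c.1A>T", protein_change = "p.K1*",
    consequence = "nonsense", exon_number = 1L, ptc_codon = 1L,
    fs_codon = NA_integer_, vaf = vaf, origin = origin, zygosity = zygosity,
    label = label, effect_direction = direction, evidence_tier = tier,
    strength = if (tier == "none") "none" else "strong",
    criteria_codes = "TEST")
}

mk_profile <- function(calls, tmb = 3, cna = NULL, paired = TRUE,
                       cancer_type = "breast_carcinoma", id = "PX") {
  tumor_profile(id, cancer_type, calls, copy_number = cna,
                signatures = list(TMB = tmb), paired = paired)
}

test_that("biomarker matching covers exact, category and functional-entity kinds", {
  fx <- fx_bundle()
  lib <- fx$kn$library
  kit <- classify_variants(lib[lib$variant_id == "kit_d572a", ], fx$db, fx$kb)
  m <- match_biomarkers(kit, "gist", fx$kb)
  expect_equal(m$match_kind, "exact_change")
  expect_equal(m$type_relation, "same")

  egfr <- classify_variants(lib[lib$variant_id == "egfr_ex19del", ], fx$db, fx$kb)
  m2 <- match_biomarkers(egfr, "lung_adenocarcinoma", fx$kb)
  expect_true("category" %in% m2$match_kind)
  expect_true(all(m2$type_relation == "patient_is_subtype"))

  flt3 <- classify_variants(lib[lib$variant_id == "flt3_itd", ], fx$db, fx$kb)
  m3 <- match_biomarkers(flt3, "aml", fx$kb)
  expect_true("functional_entity" %in% m3$match_kind)
  # an unknown-relevance variant never satisfies an entity biomarker
  flt3_unknown <- flt3
  flt3_unknown$label <- "unknown"
  flt3_unknown$effect_direction <- "none"
  m4 <- match_biomarkers(flt3_unknown, "aml", fx$kb)
  expect_false("functional_entity" %in% m4$match_kind)

  # off-tumor-type matches are retained but flagged
  m5 <- match_biomarkers(kit, "melanoma", fx$kb)
  expect_true(all(m5$off_tumor_type))
})

test_that("ESCAT assignment follows the configured matrix", {
  cfg <- interpretation_config()
  m <- tibble::tibble(
    variant_key = "x", gene_symbol = "g", protein_change = "p",
    match_kind = "exact_change", association = "sensitivity",
    drug_or_context = "d",
    evidence_level = c("approved_or_guideline", "clinical_trial",
                       "clinical_trial", "case_report", "preclinical",
                       "retrospective_clinical"),
    biomarker_cancer_type = "t",
    type_relation = c("same", "patient_is_subtype", "other", "same", "same",
                      "other"),
    off_tumor_type = FALSE, source = "s")
  out <- assign_escat(m, cfg)
  expect_equal(out$escat_tier, c("I", "II", "III", "III", "IV", "III"))
  bad <- m[1, ]; bad$evidence_level <- "hearsay"
  expect_error(assign_escat(bad, cfg), "hearsay")
})

test_that("ESCAT tiers never improve as evidence or disease match degrades", {
  matrix_cfg <- interpretation_config()$escat_matrix
  tier_rank <- c(I = 1, II = 2, III = 3, IV = 4, unassigned = 5)
  ranks <- apply(matrix_cfg, c(1, 2), function(t) tier_rank[[t]])
  # rows ordered strongest -> weakest evidence, columns same -> subtype -> other
  for (j in seq_len(ncol(ranks))) expect_true(all(diff(ranks[, j]) >= 0))
  for (i in seq_len(nrow(ranks))) expect_true(all(diff(ranks[i, ]) >= 0))
})

test_that("the six fixture arms over twenty hand-built profiles match a hand-derived table", {
  fx <- fx_bundle()
  rules <- fx$kb$trial_rules
  cfg <- interpretation_config()
  no_call <- mk_call("BRAF")[0, ]
  amp <- tibble::tibble(gene_symbol = "CD274", type = "amplification")
  profiles <- list(
    mk_profile(mk_call("BRCA1", tier = "B")),                          # 1
    mk_profile(mk_call("BRCA2", tier = "A")),                          # 2
    mk_profile(mk_call("BRCA1", tier = "C")),                          # 3
    mk_profile(mk_call("PALB2", tier = "C")),                          # 4
    mk_profile(mk_call("MLH1", tier = "B")),                           # 5
    mk_profile(mk_call("MSH6", tier = "B")),                           # 6
    mk_profile(mk_call("POLE", direction = "switch_of_function", tier = "A")), # 7
    mk_profile(mk_call("POLD1", direction = "switch_of_function", tier = "A")), # 8
    mk_profile(mk_call("POLE", direction = "loss_of_function", tier = "B")),   # 9
    mk_profile(no_call, tmb = 25),                                     # 10
    mk_profile(no_call, tmb = 10),                                     # 11
    mk_profile(mk_call("ATM", tier = "B"), tmb = 25),                  # 12
    mk_profile(no_call, tmb = 3),                                      # 13
    mk_profile(mk_call("ATM", tier = "B")),                            # 14
    mk_profile(mk_call("CHEK2", tier = "A")),                          # 15
    mk_profile(no_call, cna = amp),                                    # 16
    mk_profile(mk_call("BRCA1", tier = "B"), cna = amp),               # 17
    mk_profile(dplyr::bind_rows(mk_call("BRCA2", tier = "B"),
                                mk_call("MSH2", tier = "B")), tmb = 25), # 18
    mk_profile(mk_call("KRAS", label = "functionally_relevant",
                       direction = "gain_of_function", tier = "C"),
               tmb = 25),                                              # 19
    mk_profile(mk_call("FLT3", direction = "gain_of_function", tier = "A")) # 20
  )
  expected <- list("1A", "1A", character(0), character(0), "1B", "1B",
                   "1C", "1C", character(0), "1D", "1D", "1E", character(0),
                   "1E", "1E", "1F", c("1A", "1F"), c("1A", "1B"), "1D",
                   character(0))
  for (i in seq_along(profiles)) {
    got <- evaluate_trial_rules(profiles[[i]], rules, cfg)$arm_id
    expect_identical(got, expected[[i]], label = paste("profile", i))
  }
})

test_that("per-gene evidence-floor overrides admit tier-C calls", {
  fx <- fx_bundle()
  cfg <- interpretation_config()
  prof <- mk_profile(mk_call("BRCA1", tier = "C"))
  expect_equal(nrow(evaluate_trial_rules(prof, fx$kb$trial_rules, cfg)), 0)
  rules2 <- fx$kb$trial_rules
  rules2[[1]]$evidence_floor_overrides <- list(BRCA1 = list("A", "B", "C"))
  got <- evaluate_trial_rules(prof, rules2, cfg)
  expect_equal(got$arm_id, "1A")
})

test_that("recommendations come out sorted by priority, stable under rule reordering", {
  fx <- fx_bundle()
  cfg <- interpretation_config()
  prof <- mk_profile(
    dplyr::bind_rows(mk_call("ATM", tier = "B"), mk_call("BRCA1", tier = "B")),
    cna = tibble::tibble(gene_symbol = "CD274", type = "amplification"))
  r1 <- evaluate_trial_rules(prof, fx$kb$trial_rules, cfg)
  expect_equal(r1$arm_id, c("1A", "1E", "1F"))
  shuffled <- structure(rev(unclass(fx$kb$trial_rules)), class = "trial_rules")
  r2 <- evaluate_trial_rules(prof, shuffled, cfg)
  expect_identical(r1, r2)
})

test_that("malformed trial rules are rejected at load", {
  d <- tempfile(fileext = ".json")
  jsonlite::write_json(list(list(trial_id = "T", arm_id = "x", priority = 1,
                                 expression = list(op = "MAYBE",
                                                   children = list()))),
                       d, auto_unbox = TRUE)
  expect_error(read_trial_rules(d), "MAYBE|children")
  jsonlite::write_json(list(list(trial_id = "T", arm_id = "x", priority = 1,
                                 expression = list(pred = "alteration",
                                                   genes = list(),
                                                   class = "LoF_mutation"))),
                       d, auto_unbox = TRUE)
  expect_error(read_trial_rules(d), "empty gene set")
})

test_that("germline alerts respect the panel, the tier floor and MUTYH biallelism", {
  fx <- fx_bundle()
  panel <- fx$kb$germline_panel
  alert_of <- function(calls, paired = TRUE) {
    issue_germline_alerts(mk_profile(calls, paired = paired), panel)
  }
  # tier B loss of function in a panel gene, paired germline: alert
  a <- alert_of(mk_call("PALB2", origin = "germline"))
  expect_equal(a$gene_symbol, "PALB2")
  expect_equal(a$origin_basis, "paired")
  # tier C never alerts
  expect_equal(nrow(alert_of(mk_call("PALB2", tier = "C",
                                     origin = "germline"))), 0)
  # non-panel gene never alerts
  expect_equal(nrow(alert_of(mk_call("FLT3", origin = "germline"))), 0)
  # monoallelic MUTYH: no alert; biallelic (hom or two hets): alert
  expect_equal(nrow(alert_of(mk_call("MUTYH", origin = "germline"))), 0)
  hom <- alert_of(mk_call("MUTYH", origin = "germline",
                          zygosity = "homozygous"))
  expect_equal(hom$zygosity, "homozygous")
  two <- alert_of(dplyr::bind_rows(
    mk_call("MUTYH", origin = "germline", key = "MUTYH:g.1A>T"),
    mk_call("MUTYH", origin = "germline", key = "MUTYH:g.9A>T")))
  expect_equal(nrow(two), 2)
  expect_true(all(two$zygosity == "compound_heterozygous"))
  # tumor-only: VAF window decides; missing VAF is indeterminate, not dropped
  inf <- alert_of(mk_call("PALB2", origin = "unknown", vaf = 0.48),
                  paired = FALSE)
  expect_equal(inf$origin_basis, "inferred_vaf")
  low <- alert_of(mk_call("PALB2", origin = "unknown", vaf = 0.12),
                  paired = FALSE)
  expect_equal(nrow(low), 0)
  ind <- alert_of(mk_call("PALB2", origin = "unknown", vaf = NA),
                  paired = FALSE)
  expect_equal(ind$origin_basis, "indeterminate")
})
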