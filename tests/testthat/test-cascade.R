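# The functional classification cascade: the full decision grid against an
# independently coded flat decision table (helper-oracles.R), precedence,
# allele-centricity, strength mapping.

test_that("the cascade matches an independent flat decision table over the full grid", {
  g <- cascade_grid()
  expect_gte(nrow(g), 2500)
  res <- functional_cascade(g, interpretation_config())
  for (i in seq_len(nrow(g))) {
    want <- oracle_decide(g[i, ])
    expect_identical(unname(c(res$label[i], res$evidence_tier[i],
                              res$strength[i])), unname(want),
                     label = paste0("grid row ", i, ": ",
                                    paste(g[i, 1:8], collapse = "/")))
  }
})

test_that("criteria codes and strength follow the PVS1 hierarchy", {
  cfg <- interpretation_config()
  base <- tibble::tibble(
    assertion_verdict = "none", assertion_direction = NA_character_,
    consequence = "nonsense", nmd_predicted = FALSE,
    in_critical_region = FALSE, truncated_fraction = 0.4,
    hotspot_significant = FALSE, phred_score = NA_real_,
    mechanism = "tumor_suppressor", is_common = FALSE)
  r <- functional_cascade(base, cfg)
  expect_equal(r$criteria_codes, "PVS1S_TRUNC_GT10")
  expect_equal(r$strength, "strong")
  nmd <- base; nmd$nmd_predicted <- TRUE
  r2 <- functional_cascade(nmd, cfg)
  expect_equal(r2$criteria_codes, "PVS1_NMD")
  expect_equal(r2$strength, "very_strong")
  both <- base; both$in_critical_region <- TRUE
  r3 <- functional_cascade(both, cfg)
  expect_equal(r3$criteria_codes, "PVS1S_CRITICAL_REGION;PVS1S_TRUNC_GT10")
  expect_equal(r3$strength, "strong")
  # conflict code carried into an unknown verdict
  conf <- base; conf$assertion_verdict <- "conflicting"
  conf$consequence <- "missense"; conf$truncated_fraction <- NA
  conf$nmd_predicted <- NA
  r4 <- functional_cascade(conf, cfg)
  expect_equal(r4$label, "unknown")
  expect_equal(r4$criteria_codes, "CONFLICT")
})

test_that("evidence A conclusive calls are unchanged when hotspot and score tables vanish", {
  fx <- fx_bundle()
  lib <- fx$kn$library
  conclusive_ab <- lib[lib$intended_tier %in% c("A", "B"), ]
  calls1 <- classify_variants(conclusive_ab, fx$db, fx$kb)
  kb2 <- fx$kb
  kb2$hotspots <- kb2$hotspots[0, ]
  kb2$scores <- kb2$scores[0]
  calls2 <- classify_variants(conclusive_ab, fx$db, kb2)
  cols <- c("label", "effect_direction", "evidence_tier", "strength",
            "criteria_codes")
  expect_identical(calls1[cols], calls2[cols])
})

test_that("weak-rated assertions never change any downstream verdict", {
  fx <- fx_bundle()
  lib <- fx$kn$library
  calls1 <- classify_variants(lib, fx$db, fx$kb)
  kb2 <- fx$kb
  kb2$assertions <- kb2$assertions[kb2$assertions$usable, ]
  calls2 <- classify_variants(lib, fx$db, kb2)
  cols <- c("label", "effect_direction", "evidence_tier", "strength",
            "criteria_codes")
  expect_identical(calls1[cols], calls2[cols])
})

test_that("classification is allele-centric: cancer type, VAF and origin never matter", {
  fx <- fx_bundle()
  lib <- fx$kn$library
  set.seed(3)
  # 500 randomized observation contexts over the planted alleles
  idx <- sample(nrow(lib), 500, replace = TRUE)
  v <- lib[idx, ]
  base_calls <- classify_variants(v, fx$db, fx$kb)
  v2 <- v
  v2$vaf <- stats::runif(nrow(v2))
  v2$origin <- sample(c("somatic", "germline", "unknown"), nrow(v2), TRUE)
  v2$zygosity <- sample(c("heterozygous", "homozygous", "unknown"), nrow(v2), TRUE)
  perm_calls <- classify_variants(v2, fx$db, fx$kb)
  cols <- c("label", "effect_direction", "evidence_tier", "strength",
            "criteria_codes")
  expect_identical(base_calls[cols], perm_calls[cols])
})

test_that("a common polymorphism outranks a high deleteriousness score", {
  fx <- fx_bundle()
  lib <- fx$kn$library
  v <- lib[lib$variant_id == "tp53_common", ]   # AF 0.05 and Phred 35 planted
  call <- classify_variants(v, fx$db, fx$kb)
  expect_equal(call$label, "functionally_neutral")
  expect_equal(call$criteria_codes, "COMMON_POLYMORPHISM")
})

test_that("hotspot membership is checked before CADD inside evidence C", {
  fx <- fx_bundle()
  v <- fx$kn$library[fx$kn$library$variant_id == "tp53_hotspot", ]
  call <- classify_variants(v, fx$db, fx$kb)   # Phred 35 also on record
  expect_equal(call$criteria_codes, "HOTSPOT")
  expect_equal(call$evidence_tier, "C")
})

test_that("evidence_a/b/c wrappers return tiered calls or NULL", {
  fx <- fx_bundle()
  db <- fx$db; kb <- fx$kb
  splice <- normalize_variants("BRCA1:c.5468-1G>A", db)
  a <- evidence_a(splice, db, kb)
  expect_equal(a$evidence_tier, "A")
  expect_equal(a$effect_direction, "loss_of_function")
  kras <- normalize_variants("KRAS:c.35G>A", db)
  expect_null(evidence_a(kras, db, kb))
  lib <- fx$kn$library
  nmdv <- lib[lib$variant_id == "mlh1_nmd", ]
  b <- evidence_b(nmdv, db)
  expect_equal(b$strength, "very_strong")
  expect_true(grepl("PVS1_NMD", b$criteria_codes))
  c_ <- evidence_c(kras, db, kb)
  expect_equal(c_$criteria_codes, "HOTSPOT")
  expect_equal(c_$effect_direction, "gain_of_function")
  # oncogene nonsense: evidence B does not apply
  e <- oncoboard:::find_codon_expr(db, "EGFR", 100, 140, "stop")
  onc <- normalize_variants(paste0("EGFR:", e$expr), db)
  expect_null(evidence_b(onc, db))
})

test_that("boundary values: fraction 0.10, Phred 30/10, hotspot p = 0.05", {
  toy <- make_toy_db()
  cfg <- interpretation_config()
  # 10% truncation is strict: codon 91 of 100 does not fire, codon 90 does
  v91 <- normalize_variants(toy_stop_expr(91), toy)
  v90 <- normalize_variants(toy_stop_expr(90), toy)
  empty_kb <- local({
    fx <- fx_bundle()
    kb <- fx$kb
    kb$assertions <- kb$assertions[0, ]
    kb$hotspots <- kb$hotspots[0, ]
    kb$scores <- kb$scores[0]; kb$frequencies <- kb$frequencies[0]
    kb
  })
  c91 <- classify_variants(v91, toy, empty_kb, cfg)
  c90 <- classify_variants(v90, toy, empty_kb, cfg)
  expect_equal(c91$label, "unknown")
  expect_equal(c90$criteria_codes, "PVS1S_TRUNC_GT10")
  # CADD exactly at the thresholds stays unknown (strict > 30 / < 10)
  fx <- fx_bundle()
  lib <- fx$kn$library
  for (vid in c("chek2_cadd_30", "pms2_cadd_10")) {
    call <- classify_variants(lib[lib$variant_id == vid, ], fx$db, fx$kb)
    expect_equal(call$label, "unknown")
  }
  # hotspot p exactly 0.05 is not significant (strict < 5%)
  call <- classify_variants(lib[lib$variant_id == "fgfr3_hs_boundary", ],
                            fx$db, fx$kb)
  expect_equal(call$label, "unknown")
})
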