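# Report assembly, serialization round-trip, pipeline determinism, CLI.

test_that("variants partition into the three report tables by label", {
  fx <- fx_bundle()
  lib <- fx$kn$library
  ids <- c("brca1_splice", "mlh1_nmd", "kit_d572a", "brip1_cadd_mid",
           "pms2_benign")
  calls <- classify_variants(lib[match(ids, lib$variant_id), ], fx$db, fx$kb)
  prof <- tumor_profile("P1", "breast_carcinoma", calls,
                        signatures = list(TMB = 3), paired = TRUE)
  matches <- assign_escat(match_biomarkers(calls, "breast_carcinoma", fx$kb))
  report <- build_report(prof, matches,
                         evaluate_trial_rules(prof, fx$kb$trial_rules),
                         issue_germline_alerts(prof, fx$kb$germline_panel),
                         fx$kb$manifest)
  expect_equal(nrow(report$tables$functionally_relevant), 2)
  expect_equal(nrow(report$tables$unknown), 2)
  expect_equal(nrow(report$tables$functionally_neutral), 1)
  # each classified variant appears in exactly one table
  all_keys <- c(report$tables$functionally_relevant$variant_key,
                report$tables$unknown$variant_key,
                report$tables$functionally_neutral$variant_key)
  expect_setequal(all_keys, calls$variant_key)
  expect_equal(anyDuplicated(all_keys), 0)
  # manifest embedded verbatim
  expect_identical(report$manifest, fx$kb$manifest)
})

test_that("a variant without a functional call fails report integrity", {
  fx <- fx_bundle()
  calls <- classify_variants(fx$kn$library[1, ], fx$db, fx$kb)
  calls$label <- NA_character_
  prof <- tumor_profile("P1", "melanoma", calls)
  empty <- tibble::tibble()
  expect_error(
    build_report(prof, empty, empty, empty, fx$kb$manifest),
    class = "oncoboard_integrity")
})

test_that("reports serialize round-trip and repeated runs differ only in timestamp", {
  fx <- fx_bundle()
  i <- which(fx$inputs$patient_id == "P0008")
  meta <- read_patient_profile(fx$inputs$profile[i])
  raw <- read_variants_vcf(fx$inputs$vcf[i], fx$db)
  r1 <- interpret_patient(raw, meta, fx$db, fx$kb)
  Sys.sleep(1)
  r2 <- interpret_patient(raw, meta, fx$db, fx$kb)
  expect_identical(serialize_report(r1, drop_timestamp = TRUE),
                   serialize_report(r2, drop_timestamp = TRUE))
  path <- tempfile(fileext = ".json")
  write_report(r1, path)
  back <- read_report(path)
  expect_equal(glance(back), glance(r1))
  for (nm in names(r1$tables)) {
    expect_equal(as.data.frame(back$tables[[nm]]),
                 as.data.frame(r1$tables[[nm]]))
  }
  expect_equal(as.data.frame(back$germline_alerts),
               as.data.frame(r1$germline_alerts))
})

test_that("an empty variant set still yields a valid report with three empty tables", {
  fx <- fx_bundle()
  empty_vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), empty_vcf)
  meta <- list(patient_id = "P_EMPTY", cancer_type = "melanoma",
               paired = FALSE, copy_number = NULL,
               signatures = list(TMB = 1))
  raw <- read_variants_vcf(empty_vcf, fx$db)
  r <- interpret_patient(raw, meta, fx$db, fx$kb)
  expect_equal(r$counts$n_variants, 0)
  expect_true(all(vapply(r$tables, nrow, integer(1)) == 0))
})

test_that("malformed VCF input fails fast naming the line, before any report", {
  fx <- fx_bundle()
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "ctg_BRAF\t100\t.\tA"), bad)
  expect_error(read_variants_vcf(bad, fx$db), "line 3",
               class = "oncoboard_integrity")
  out <- tempfile()
  inputs <- tibble::tibble(vcf = bad, profile = fx$inputs$profile[1])
  expect_error(run_pipeline(fx$config_path, inputs, out),
               class = "oncoboard_integrity")
  expect_false(dir.exists(out))
})

test_that("profiles with identifier-like fields are refused", {
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(patient_id = "P1", cancer_type = "melanoma",
                        paired = TRUE, name = "John Doe"), p)
  expect_error(read_patient_profile(p), "identifier-like")
})

test_that("the pipeline log carries per-stage record counts matching the generator", {
  fx <- fx_bundle()
  sub <- fx$inputs[1:6, ]
  out <- file.path(tempdir(), "reports_test")
  log <- run_pipeline(fx$config_path, sub[, c("vcf", "profile")], out)
  expect_equal(nrow(log), 6)
  obs <- fx$cohort$observations
  for (i in seq_len(nrow(sub))) {
    expect_equal(log$n_input[i],
                 sum(obs$patient_id == sub$patient_id[i]))
    expect_equal(log$n_classified[i], log$n_input[i])
    expect_true(file.exists(log$report_path[i]))
  }
})

test_that("cli_main implements the documented commands and exit codes", {
  fx <- fx_bundle()
  out <- file.path(tempdir(), "cli_out")
  expect_equal(suppressMessages(cli_main(character(0))), 2L)
  expect_equal(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_equal(suppressMessages(
    cli_main(c("validate-resources", "--config", fx$config_path))), 0L)
  expect_equal(suppressMessages(
    cli_main(c("interpret", "--config", fx$config_path,
               "--vcf", fx$inputs$vcf[1],
               "--profile", fx$inputs$profile[1], "--out", out))), 0L)
  expect_true(file.exists(file.path(out, "P0001.json")))
  # missing flag -> validation failure
  expect_equal(suppressMessages(
    cli_main(c("interpret", "--config", fx$config_path))), 2L)
  # malformed VCF -> integrity failure
  bad <- tempfile(fileext = ".vcf")
  writeLines("not a vcf", bad)
  expect_equal(suppressMessages(
    cli_main(c("interpret", "--config", fx$config_path, "--vcf", bad,
               "--profile", fx$inputs$profile[1], "--out", out))), 3L)
})

test_that("tidiers and autoplot produce well-formed summaries", {
  fx <- fx_bundle()
  calls <- classify_variants(fx$kn$library, fx$db, fx$kb)
  td <- tidy(calls)
  expect_true(all(c("gene_symbol", "label", "evidence_tier") %in% names(td)))
  gl <- glance(calls)
  expect_equal(gl$n_variants, nrow(calls))
  expect_equal(gl$n_relevant + gl$n_neutral + gl$n_unknown, gl$n_variants)
  p <- autoplot(calls)
  expect_s3_class(p, "ggplot")
})
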