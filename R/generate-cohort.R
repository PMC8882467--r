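# Synthetic patient cohorts with planted truth.
#
# The first twenty patients are engineered: one per cascade branch, trial arm
# (including arm 1D's absence condition), germline-alert scenario (paired and
# tumor-only, MUTYH mono-/biallelic, tier-C exclusion, the low-VAF
# tumor-only miss). Remaining patients draw 1-6 somatic variants at random
# from the planted library. Every generated variant carries exactly one truth
# record.

MMR_GENES <- c("MLH1", "MSH2", "MSH6", "PMS2")

intended_arms_for <- function(lib_rows, cna, tmb, config) {
  lofAB <- lib_rows$gene_symbol[
    lib_rows$intended_label == "functionally_relevant" &
      lib_rows$intended_direction == "loss_of_function" &
      lib_rows$intended_tier %in% c("A", "B")]
  sofA <- lib_rows$gene_symbol[
    lib_rows$intended_label == "functionally_relevant" &
      lib_rows$intended_direction == "switch_of_function" &
      lib_rows$intended_tier %in% c("A", "B")]
  arms <- character(0)
  if (any(c("BRCA1", "BRCA2") %in% lofAB)) arms <- c(arms, "1A")
  if (any(MMR_GENES %in% lofAB)) arms <- c(arms, "1B")
  if (any(c("POLE", "POLD1") %in% sofA)) arms <- c(arms, "1C")
  if (tmb_category(tmb, config) %in% c("intermediate", "high") &&
      !any(DDR_GENES %in% lofAB)) arms <- c(arms, "1D")
  if (any(setdiff(DDR_GENES, c("BRCA1", "BRCA2", MMR_GENES)) %in% lofAB)) {
    arms <- c(arms, "1E")
  }
  if (nrow(cna) > 0 && any(cna$gene_symbol == "CD274" &
                           cna$type == "amplification")) {
    arms <- c(arms, "1F")
  }
  arms
}

alert_expected_for <- function(lib_row, origin, zygosity, vaf, paired, panel,
                               n_germline_same_gene, config) {
  germ <- if (paired) {
    origin == "germline"
  } else {
    !is.na(vaf) && any(vapply(config$germline_vaf_windows,
                              function(w) vaf >= w[1] && vaf <= w[2],
                              logical(1)))
  }
  if (!germ) return(FALSE)
  if (!lib_row$gene_symbol %in% panel$gene_symbol) return(FALSE)
  if (lib_row$intended_label != "functionally_relevant" ||
      lib_row$intended_direction != "loss_of_function" ||
      !lib_row$intended_tier %in% c("A", "B")) return(FALSE)
  biall <- panel$biallelic_only[panel$gene_symbol == lib_row$gene_symbol][1]
  if (isTRUE(biall)) {
    return(zygosity == "homozygous" || n_germline_same_gene >= 2)
  }
  TRUE
}

#' Generate a synthetic patient cohort with planted truth
#'
#' @param db a [transcript_db()].
#' @param kn knowledge fixtures from [generate_knowledge_fixtures()] (the
#'   planted library drives variant selection).
#' @param n_patients number of patients (minimum 20: the engineered scenarios).
#' @param seed integer seed.
#' @param config an [interpretation_config()].
#' @return list with `patients`, `observations`, `truth_variants`,
#'   `truth_patients` tibbles.
#' @export
generate_cohort <- function(db, kn, n_patients = 20, seed = 1,
                            config = interpretation_config()) {
  if (n_patients < 20) abort("n_patients must be >= 20 (engineered scenarios)")
  withr::with_seed(seed, generate_cohort_impl(db, kn, n_patients, config))
}

generate_cohort_impl <- function(db, kn, n_patients, config) {
  lib <- kn$library
  panel <- kn$germline_panel
  pid <- function(i) sprintf("P%04d", i)
  som <- function(...) {
    ids <- c(...)
    tibble(variant_id = ids, vaf = round(stats::runif(length(ids), 0.10, 0.38), 2),
           origin = "somatic", zygosity = "heterozygous")
  }
  germ <- function(ids, vaf = 0.52, zygosity = "heterozygous") {
    tibble(variant_id = ids, vaf = vaf, origin = "germline",
           zygosity = zygosity)
  }
  no_cna <- tibble(gene_symbol = character(), type = character())

  eng <- list(
    list(ct = "melanoma", paired = TRUE, tmb = 3, cna = no_cna,
         obs = som("braf_v600e")),
    list(ct = "breast_carcinoma", paired = TRUE, tmb = 2, cna = no_cna,
         obs = som("brca1_nmd")),
    list(ct = "colorectal_adenocarcinoma", paired = TRUE, tmb = 4, cna = no_cna,
         obs = som("mlh1_nmd")),
    list(ct = "colorectal_adenocarcinoma", paired = TRUE, tmb = 4, cna = no_cna,
         obs = som("pole_sof")),
    list(ct = "ovarian_epithelial", paired = TRUE, tmb = 25, cna = no_cna,
         obs = som("kras_g12d")),
    list(ct = "breast_carcinoma", paired = TRUE, tmb = 3, cna = no_cna,
         obs = som("atm_nmd")),
    list(ct = "lung_adenocarcinoma", paired = TRUE, tmb = 5, cna =
           tibble(gene_symbol = "CD274", type = "amplification"),
         obs = som("egfr_ex19del")),
    list(ct = "breast_carcinoma", paired = TRUE, tmb = 2, cna = no_cna,
         obs = germ("palb2_nmd")),
    list(ct = "colorectal_adenocarcinoma", paired = TRUE, tmb = 3, cna = no_cna,
         obs = germ(c("mutyh_stop1", "mutyh_stop2"), vaf = 0.49)),
    list(ct = "colorectal_adenocarcinoma", paired = TRUE, tmb = 3, cna = no_cna,
         obs = germ("mutyh_stop1", vaf = 0.51)),
    list(ct = "breast_carcinoma", paired = TRUE, tmb = 2, cna = no_cna,
         obs = germ("atm_cadd_high")),
    list(ct = "pancreatic_adenocarcinoma", paired = FALSE, tmb = 3, cna = no_cna,
         obs = tibble(variant_id = "brca2_nmd", vaf = 0.12,
                      origin = "unknown", zygosity = "unknown")),
    list(ct = "prostate_adenocarcinoma", paired = FALSE, tmb = 3, cna = no_cna,
         obs = tibble(variant_id = "brca1_nmd", vaf = 0.48,
                      origin = "unknown", zygosity = "unknown")),
    list(ct = "ovarian_epithelial", paired = TRUE, tmb = 25, cna = no_cna,
         obs = som("brca1_nmd")),
    list(ct = "breast_carcinoma", paired = TRUE, tmb = 3, cna = no_cna,
         obs = som("chek2_conflict")),
    list(ct = "breast_carcinoma", paired = TRUE, tmb = 3, cna = no_cna,
         obs = som("palb2_weak_only")),
    list(ct = "colorectal_adenocarcinoma", paired = TRUE, tmb = 4, cna = no_cna,
         obs = som("msh6_cadd_high", "rad51c_cadd_low", "brip1_cadd_mid")),
    list(ct = "colorectal_adenocarcinoma", paired = TRUE, tmb = 4, cna = no_cna,
         obs = som("tp53_common", "msh2_silent")),
    list(ct = "lung_adenocarcinoma", paired = TRUE, tmb = 5, cna = no_cna,
         obs = som("tp53_hotspot", "fgfr3_hs_boundary", "pten_splice",
                   "apc_critical", "apc_trunc_only")),
    list(ct = "gist", paired = TRUE, tmb = 2, cna = no_cna,
         obs = som("kit_d572a"))
  )

  leaf_types <- c("lung_adenocarcinoma", "breast_carcinoma",
                  "ovarian_epithelial", "colorectal_adenocarcinoma",
                  "esophagogastric_adenocarcinoma", "pancreatic_adenocarcinoma",
                  "cholangiocarcinoma", "melanoma", "gist",
                  "prostate_adenocarcinoma", "aml")
  pool <- lib$variant_id

  patients <- list(); observations <- list()
  truth_v <- list(); truth_p <- list()
  for (i in seq_len(n_patients)) {
    if (i <= length(eng)) {
      e <- eng[[i]]
      ct <- e$ct; paired <- e$paired; tmb <- e$tmb; cna <- e$cna; obs <- e$obs
    } else {
      ct <- sample(leaf_types, 1)
      paired <- stats::runif(1) < 0.75
      tmb <- round(stats::runif(1, 0.5, 5.5), 1)
      cna <- no_cna
      ids <- sample(pool, sample(1:6, 1))
      obs <- tibble(variant_id = ids,
                    vaf = round(stats::runif(length(ids), 0.05, 0.38), 2),
                    origin = if (paired) "somatic" else "unknown",
                    zygosity = "heterozygous")
    }
    obs$patient_id <- pid(i)
    lib_rows <- lib[match(obs$variant_id, lib$variant_id), ]
    germ_counts <- table(lib_rows$gene_symbol[
      if (paired) obs$origin == "germline" else rep(TRUE, nrow(obs))])
    alert_exp <- vapply(seq_len(nrow(obs)), function(k) {
      alert_expected_for(lib_rows[k, ], obs$origin[k], obs$zygosity[k],
                         obs$vaf[k], paired, panel,
                         germ_counts[lib_rows$gene_symbol[k]] %||% 0L, config)
    }, logical(1))
    arms <- intended_arms_for(lib_rows, cna, tmb, config)
    patients[[i]] <- tibble(patient_id = pid(i), cancer_type = ct,
                            paired = paired, tmb = tmb, cna = list(cna))
    observations[[i]] <- obs
    truth_v[[i]] <- tibble(
      patient_id = pid(i), variant_id = obs$variant_id,
      variant_key = lib_rows$variant_key,
      intended_label = lib_rows$intended_label,
      intended_tier = lib_rows$intended_tier,
      intended_direction = lib_rows$intended_direction,
      intended_codes = lib_rows$intended_codes,
      alert_expected = alert_exp
    )
    truth_p[[i]] <- tibble(patient_id = pid(i),
                           intended_arms = paste(arms, collapse = ";"))
  }
  list(patients = bind_rows(patients),
       observations = bind_rows(observations),
       truth_variants = bind_rows(truth_v),
       truth_patients = bind_rows(truth_p))
}

# ---- emission ----------------------------------------------------------------

write_patient_vcf <- function(db, vars, path, paired) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"somatic or germline (paired calling)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR")
  )
  rows <- character(0)
  if (nrow(vars) > 0) {
    vars <- arrange(vars, .data$chrom, .data$pos)
    for (i in seq_len(nrow(vars))) {
      vc <- canonical_to_vcf(db, vars$chrom[i], vars$pos[i], vars$ref[i],
                             vars$alt[i])
      info <- paste0("GENE=", vars$gene_symbol[i], ";AF=",
                     formatC(vars$vaf[i], format = "f", digits = 3))
      if (paired) info <- paste0(info, ";ORIGIN=", vars$origin[i])
      gt <- switch(vars$zygosity[i], homozygous = "1/1",
                   heterozygous = "0/1", "./.")
      rows <- c(rows, paste(vars$chrom[i], vc$pos, ".", vc$ref, vc$alt, ".",
                            "PASS", info, "GT", gt, sep = "\t"))
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write a generated cohort to disk (VCF 4.2 + profile YAML per patient)
#'
#' @param cohort output of [generate_cohort()].
#' @param db a [transcript_db()].
#' @param kn knowledge fixtures (for the variant library).
#' @param dir output directory.
#' @return tibble with columns `patient_id`, `vcf`, `profile`.
#' @export
write_cohort <- function(cohort, db, kn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- kn$library
  inputs <- list()
  for (i in seq_len(nrow(cohort$patients))) {
    p <- cohort$patients[i, ]
    obs <- cohort$observations[cohort$observations$patient_id == p$patient_id, ]
    vars <- lib[match(obs$variant_id, lib$variant_id), ]
    vars$vaf <- obs$vaf; vars$origin <- obs$origin
    vars$zygosity <- obs$zygosity
    vcf_path <- file.path(dir, paste0(p$patient_id, ".vcf"))
    write_patient_vcf(db, vars, vcf_path, p$paired)
    prof <- list(
      patient_id = p$patient_id, cancer_type = p$cancer_type,
      paired = p$paired, assay = list(panel = "synthetic-fixture-panel"),
      signatures = list(TMB = p$tmb)
    )
    cna <- p$cna[[1]]
    if (nrow(cna) > 0) {
      prof$copy_number <- lapply(seq_len(nrow(cna)), function(k)
        list(gene = cna$gene_symbol[k], type = cna$type[k]))
    }
    prof_path <- file.path(dir, paste0(p$patient_id, ".yaml"))
    yaml::write_yaml(prof, prof_path)
    inputs[[i]] <- tibble(patient_id = p$patient_id, vcf = vcf_path,
                          profile = prof_path)
  }
  readr::write_tsv(cohort$truth_variants, file.path(dir, "truth_variants.tsv"))
  readr::write_tsv(cohort$truth_patients, file.path(dir, "truth_patients.tsv"))
  bind_rows(inputs)
}

#' Generate, write and reload a complete fixture bundle
#'
#' One-stop orchestrator: gene models, knowledge resources, a patient cohort
#' and a run-configuration YAML are generated deterministically, written under
#' `dir`, and loaded back through the production readers.
#'
#' @param dir target directory (created); defaults to a session temp dir.
#' @param n_patients cohort size (>= 20).
#' @param seed integer seed; sub-generators derive seeds seed+1, seed+2.
#' @param config an [interpretation_config()].
#' @return list with `db`, `kn`, `kb`, `cohort`, `inputs`, `config_path`,
#'   `dir`.
#' @export
generate_fixture_bundle <- function(dir = tempfile("oncoboard_fixtures"),
                                    n_patients = 20, seed = 1,
                                    config = interpretation_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  db <- generate_gene_models(seed = seed)
  write_transcript_db(db, file.path(dir, "models"))
  kn <- generate_knowledge_fixtures(db, seed = seed + 1L)
  paths <- write_knowledge_fixtures(kn, file.path(dir, "knowledge"))
  cohort <- generate_cohort(db, kn, n_patients = n_patients, seed = seed + 2L,
                            config = config)
  inputs <- write_cohort(cohort, db, kn, file.path(dir, "cohort"))
  cfg <- list(resources = c(list(models = "models"),
                            as.list(stats::setNames(
                              file.path("knowledge", basename(paths)),
                              names(paths)))))
  config_path <- file.path(dir, "run_config.yaml")
  yaml::write_yaml(cfg, config_path)
  kb <- load_resources(paths, db, config)
  list(db = db, kn = kn, kb = kb, cohort = cohort, inputs = inputs,
       config_path = config_path, dir = dir)
}
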