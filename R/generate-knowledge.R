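# Synthetic knowledge resources with planted ground truth.
#
# Each planted variant is constructed as an HGVS-style expression against the
# synthetic gene models, normalized through the engine's own front door, and
# recorded in a library together with the label/tier/criteria the planted
# evidence is designed to produce. The library drives the cohort generator and
# the recovery tests.

# -- variant construction helpers ---------------------------------------------

codon_sub_expr <- function(db, gene, codon, target = c("stop", "missense",
                                                       "synonymous")) {
  target <- match.arg(target)
  st <- canonical_struct(db, gene)
  cod <- substr(st$cds_seq, (codon - 1L) * 3L + 1L, codon * 3L)
  ref_aa <- translate_cds(cod)
  for (j in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (substr(cod, j, j) == b) next
      mut <- cod; substr(mut, j, j) <- b
      aa <- translate_cds(mut)
      ok <- switch(target,
        stop = aa == "*",
        synonymous = aa == ref_aa,
        missense = aa != ref_aa && aa != "*" && ref_aa != "*"
      )
      if (ok) {
        cpos <- (codon - 1L) * 3L + j
        return(paste0("c.", cpos, substr(cod, j, j), ">", b))
      }
    }
  }
  NA_character_
}

find_codon_expr <- function(db, gene, lo, hi, target) {
  for (k in lo:hi) {
    e <- codon_sub_expr(db, gene, k, target)
    if (!is.na(e)) return(list(codon = k, expr = e))
  }
  abort(paste0("no ", target, " substitution found in ", gene,
               " codons ", lo, "-", hi))
}

acceptor_splice_expr <- function(db, gene, junction = 1L) {
  st <- canonical_struct(db, gene)
  ex <- st$exons
  # use the first junction at or after `junction` whose acceptor is in the CDS
  ok <- which(ex$tstart - st$cds_t_start + 1L >= 1L &
                ex$tstart <= st$cds_t_end) - 1L
  ok <- ok[ok >= 1L]
  if (length(ok) == 0) abort(paste0("no CDS acceptor junction in ", gene))
  junction <- if (any(ok >= junction)) min(ok[ok >= junction]) else max(ok)
  ct <- ex$tstart[junction + 1L] - st$cds_t_start + 1L
  g <- if (st$strand == "+") ex$gstart[junction + 1L] - 1L
       else ex$gend[junction + 1L] + 1L
  seq <- chrom_seq(db, st$chrom)
  ref_g <- substr(seq, g, g)
  ref_t <- if (st$strand == "-") revcomp(ref_g) else ref_g
  alt_t <- setdiff(c("A", "C", "G", "T"), ref_t)[1]
  paste0("c.", ct, "-1", ref_t, ">", alt_t)
}

frameshift_del_expr <- function(db, gene, codon) {
  cpos <- (codon - 1L) * 3L + 1L
  paste0("c.", cpos, "del")
}

inframe_del_expr <- function(gene, c_start, n_codons) {
  paste0("c.", c_start, "_", c_start + 3L * n_codons - 1L, "del")
}

inframe_ins_expr <- function(db, gene, codon, n_codons = 2L) {
  st <- canonical_struct(db, gene)
  cpos <- codon * 3L                              # insert after this codon
  dup <- substr(st$cds_seq, cpos - 3L * n_codons + 1L, cpos)
  paste0("c.", cpos, "_", cpos + 1L, "ins", dup)
}

# -- the planted library ------------------------------------------------------

#' Generate synthetic knowledge fixtures with planted ground truth
#'
#' Emits assertion, biomarker, hotspot, deleteriousness-score, population
#' frequency, ontology, germline-panel and trial-rule tables designed so that
#' every branch of the classification cascade, every
#' (evidence level x cancer-type relation) cell of the actionability matrix,
#' conflicting and sub-threshold assertion pairs, and all six trial arms are
#' exercised. The returned `library` tibble records, per planted variant, the
#' label, tier, direction and criteria codes the planted evidence is designed
#' to produce.
#'
#' @param db a [transcript_db()] from [generate_gene_models()].
#' @param seed integer seed.
#' @return list of fixture tibbles plus `trial_rules` (R list), `library`.
#' @export
generate_knowledge_fixtures <- function(db, seed = 1) {
  withr::with_seed(seed, generate_knowledge_impl(db))
}

generate_knowledge_impl <- function(db) {
  lib <- list(); assertions <- list(); biomarkers <- list()
  hotspots <- list(); scores <- list(); freqs <- list()

  plant <- function(id, gene, expr, label, tier, direction, codes,
                    germline_gene = FALSE) {
    v <- normalize_variants(paste0(gene, ":", expr), db)
    v$variant_id <- id
    v$intended_label <- label
    v$intended_tier <- tier
    v$intended_direction <- direction
    v$intended_codes <- codes
    lib[[id]] <<- v
    v
  }
  assert <- function(source, gene, match_type, match_value, effect,
                     rating, gp = NA_character_, version = "2024-01") {
    assertions[[length(assertions) + 1]] <<- tibble(
      source = source, source_version = version, gene_symbol = gene,
      match_type = match_type, match_value = match_value, effect = effect,
      rating = rating, germline_pathogenicity = gp)
  }
  biom <- function(gene, match_type, match_value, cancer_type, association,
                   drug, level, source = "CIViC") {
    biomarkers[[length(biomarkers) + 1]] <<- tibble(
      gene_symbol = gene, match_type = match_type, match_value = match_value,
      cancer_type = cancer_type, association = association,
      drug_or_context = drug, evidence_level = level, source = source,
      source_version = "2024-01")
  }

  # --- evidence A plants ---
  v <- plant("brca1_splice", "BRCA1", "c.5468-1G>A",
             "functionally_relevant", "A", "loss_of_function", "KB_MATCH")
  assert("ClinVar", "BRCA1", "exact_change", "c.5468-1G>A", "uncertain", 3,
         gp = "pathogenic")
  assert("BRCAExchange", "BRCA1", "exact_change", "c.5468-1G>A",
         "loss_of_function", 1, gp = "pathogenic")
  biom("BRCA1", "exact_change", "c.5468-1G>A", "ovarian_epithelial",
       "sensitivity", "olaparib", "clinical_trial")

  braf <- plant("braf_v600e", "BRAF", "c.1799T>A",
                "functionally_relevant", "A", "gain_of_function", "KB_MATCH")
  assert("CIViC", "BRAF", "exact_change", "p.V600E", "gain_of_function", 4)
  assert("CGI", "BRAF", "exact_change", "c.1799T>A", "gain_of_function", 1)
  hotspots[[length(hotspots) + 1]] <- tibble(
    gene_symbol = "BRAF", aa_start = 600, aa_end = 600,
    variant_class = "missense", p_value = 1e-6)
  # full (evidence level x relation) coverage through one well-known allele
  for (lev in EVIDENCE_LEVELS) {
    for (ct in c("melanoma", "solid_tumor", "aml")) {
      biom("BRAF", "exact_change", "p.V600E", ct, "sensitivity",
           paste0("BRAFi[", lev, "]"), lev)
    }
  }

  pm <- find_codon_expr(db, "PMS2", 300, 340, "missense")
  plant("pms2_benign", "PMS2", pm$expr,
        "functionally_neutral", "A", "none", "KB_MATCH")
  assert("ClinVar", "PMS2", "exact_change", pm$expr, "neutral", 3,
         gp = "benign")

  ck <- find_codon_expr(db, "CHEK2", 200, 240, "missense")
  plant("chek2_conflict", "CHEK2", ck$expr, "unknown", "none", "none",
        "CONFLICT")
  assert("ClinVar", "CHEK2", "exact_change", ck$expr, "uncertain", 2,
         gp = "pathogenic")
  assert("OncoKB", "CHEK2", "exact_change", ck$expr, "neutral", 1)

  pw <- find_codon_expr(db, "PALB2", 300, 340, "missense")
  plant("palb2_weak_only", "PALB2", pw$expr, "unknown", "none", "none", "")
  assert("ClinVar", "PALB2", "exact_change", pw$expr, "uncertain", 1,
         gp = "pathogenic")

  pole <- find_codon_expr(db, "POLE", 286, 320, "missense")
  plant("pole_sof", "POLE", pole$expr,
        "functionally_relevant", "A", "switch_of_function", "KB_MATCH")
  assert("OncoKB", "POLE", "exact_change", pole$expr, "switch_of_function", 1)
  pold <- find_codon_expr(db, "POLD1", 478, 520, "missense")
  plant("pold1_sof", "POLD1", pold$expr,
        "functionally_relevant", "A", "switch_of_function", "KB_MATCH")
  assert("CGI", "POLD1", "exact_change", pold$expr, "switch_of_function", 1)

  # category assertion + entity biomarker: FLT3 internal tandem duplication
  st_flt3 <- canonical_struct(db, "FLT3")
  ex14 <- st_flt3$exons[14, ]
  cod14 <- ((ex14$tstart + ex14$tend) %/% 2 - st_flt3$cds_t_start) %/% 3 + 1L
  plant("flt3_itd", "FLT3", inframe_ins_expr(db, "FLT3", cod14),
        "functionally_relevant", "A", "gain_of_function", "KB_MATCH")
  assert("CIViC", "FLT3", "category",
         paste0("consequence=inframe_insertion;exon=14"),
         "gain_of_function", 3)
  biom("FLT3", "functional_entity", "oncogenic", "aml", "sensitivity",
       "midostaurin", "clinical_trial", source = "OncoKB")

  # category biomarker: EGFR exon-19 in-frame deletion
  plant("egfr_ex19del", "EGFR", inframe_del_expr("EGFR", 2236L, 5L),
        "functionally_relevant", "A", "gain_of_function", "KB_MATCH")
  assert("CIViC", "EGFR", "category", "consequence=inframe_deletion;exon=19",
         "gain_of_function", 3)
  biom("EGFR", "category", "consequence=inframe_deletion;exon=19", "nsclc",
       "sensitivity", "erlotinib", "approved_or_guideline")

  kit <- plant("kit_d572a", "KIT", "p.D572A", "unknown", "none", "none", "")
  biom("KIT", "exact_change", "p.D572A", "gist", "sensitivity", "sunitinib",
       "clinical_trial")
  # a resistance biomarker: reported, never a trial trigger
  biom("KRAS", "exact_change", "c.35G>A", "colorectal_adenocarcinoma",
       "resistance", "cetuximab", "approved_or_guideline", source = "CGI")

  # --- evidence B plants ---
  nm <- function(id, gene, lo, hi, codes = "PVS1_NMD") {
    e <- find_codon_expr(db, gene, lo, hi, "stop")
    plant(id, gene, e$expr, "functionally_relevant", "B", "loss_of_function",
          codes)
  }
  nm("mlh1_nmd", "MLH1", 100, 140)
  nm("brca2_nmd", "BRCA2", 150, 190)
  nm("brca1_nmd", "BRCA1", 120, 160)
  nm("palb2_nmd", "PALB2", 80, 120)
  nm("mutyh_stop1", "MUTYH", 60, 100)
  nm("mutyh_stop2", "MUTYH", 150, 190)
  nm("atm_nmd", "ATM", 500, 540)
  nm("msh6_nmd", "MSH6", 200, 240)

  # frameshift: single-base deletion early in MSH2; the conceptual translation
  # must reach a stop upstream of the last junction (searched, then frozen)
  fs_codon <- NULL
  for (k in 120:160) {
    e <- frameshift_del_expr(db, "MSH2", k)
    vv <- normalize_variants(paste0("MSH2:", e), db)
    if (!is.na(vv$ptc_codon) &&
        predict_nmd_one(vv$ptc_codon, vv$ref, vv$alt, vv$pos,
                        canonical_struct(db, "MSH2"),
                        interpretation_config())) {
      fs_codon <- k
      plant("msh2_fs", "MSH2", e, "functionally_relevant", "B",
            "loss_of_function", "PVS1_NMD")
      break
    }
  }
  if (is.null(fs_codon)) abort("could not place an NMD-triggering frameshift in MSH2")

  plant("pten_splice", "PTEN", acceptor_splice_expr(db, "PTEN", 3),
        "functionally_relevant", "B", "loss_of_function", "PVS1_SPLICE")

  # critical-region landmarks for APC from curated truncating assertions
  for (k in c(800L, 1400L, 2000L)) {
    e <- find_codon_expr(db, "APC", k, k + 30, "stop")
    assert("ClinVar", "APC", "exact_change", e$expr, "loss_of_function", 3,
           gp = "pathogenic")
  }
  apc1 <- find_codon_expr(db, "APC", 1500, 1540, "stop")
  plant("apc_critical", "APC", apc1$expr, "functionally_relevant", "B",
        "loss_of_function", "PVS1S_CRITICAL_REGION;PVS1S_TRUNC_GT10")
  apc2 <- find_codon_expr(db, "APC", 2450, 2490, "stop")
  plant("apc_trunc_only", "APC", apc2$expr, "functionally_relevant", "B",
        "loss_of_function", "PVS1S_TRUNC_GT10")
  apc3 <- find_codon_expr(db, "APC", 2760, 2800, "stop")
  plant("apc_small_trunc", "APC", apc3$expr, "unknown", "none", "none", "")

  # --- evidence C plants ---
  score_plant <- function(id, gene, lo, hi, phred, label, tier, dir, codes) {
    e <- find_codon_expr(db, gene, lo, hi, "missense")
    v <- plant(id, gene, e$expr, label, tier, dir, codes)
    scores[[length(scores) + 1]] <<- tibble(variant_key = v$variant_key,
                                            phred_score = phred)
    v
  }
  score_plant("msh6_cadd_high", "MSH6", 700, 740, 35,
              "functionally_relevant", "C", "loss_of_function", "CADD_HIGH")
  score_plant("rad51c_cadd_low", "RAD51C", 100, 140, 8,
              "functionally_neutral", "C", "none", "CADD_LOW")
  score_plant("brip1_cadd_mid", "BRIP1", 300, 340, 20,
              "unknown", "none", "none", "")
  score_plant("chek2_cadd_30", "CHEK2", 400, 440, 30,
              "unknown", "none", "none", "")
  score_plant("pms2_cadd_10", "PMS2", 500, 540, 10,
              "unknown", "none", "none", "")
  score_plant("erbb2_cadd35", "ERBB2", 300, 340, 35,
              "unknown", "none", "none", "")
  score_plant("atm_cadd_high", "ATM", 1000, 1040, 35,
              "functionally_relevant", "C", "loss_of_function", "CADD_HIGH")

  kras <- plant("kras_g12d", "KRAS", "c.35G>A",
                "functionally_relevant", "C", "gain_of_function", "HOTSPOT")
  hotspots[[length(hotspots) + 1]] <- tibble(
    gene_symbol = "KRAS", aa_start = 12, aa_end = 13,
    variant_class = "missense", p_value = 0.001)
  tph <- find_codon_expr(db, "TP53", 175, 175, "missense")
  tp53h <- plant("tp53_hotspot", "TP53", tph$expr,
                 "functionally_relevant", "C", "loss_of_function", "HOTSPOT")
  hotspots[[length(hotspots) + 1]] <- tibble(
    gene_symbol = "TP53", aa_start = 170, aa_end = 180,
    variant_class = "missense", p_value = 0.01)
  scores[[length(scores) + 1]] <- tibble(variant_key = tp53h$variant_key,
                                         phred_score = 35)  # hotspot precedence
  fg <- find_codon_expr(db, "FGFR3", 249, 280, "missense")
  plant("fgfr3_hs_boundary", "FGFR3", fg$expr, "unknown", "none", "none", "")
  hotspots[[length(hotspots) + 1]] <- tibble(
    gene_symbol = "FGFR3", aa_start = 249, aa_end = 249,
    variant_class = "missense", p_value = 0.05)   # exactly alpha: not significant

  # --- assumed-neutral plants ---
  tc <- find_codon_expr(db, "TP53", 72, 90, "missense")
  tp53c <- plant("tp53_common", "TP53", tc$expr,
                 "functionally_neutral", "A", "none", "COMMON_POLYMORPHISM")
  freqs[[length(freqs) + 1]] <- tibble(variant_key = tp53c$variant_key,
                                       max_af = 0.05)
  scores[[length(scores) + 1]] <- tibble(variant_key = tp53c$variant_key,
                                         phred_score = 35)  # pre-filter wins
  mb <- find_codon_expr(db, "MLH1", 400, 440, "missense")
  mlb <- plant("mlh1_af_boundary", "MLH1", mb$expr,
               "functionally_neutral", "A", "none", "COMMON_POLYMORPHISM")
  freqs[[length(freqs) + 1]] <- tibble(variant_key = mlb$variant_key,
                                       max_af = 0.01)
  sil <- find_codon_expr(db, "MSH2", 500, 540, "synonymous")
  plant("msh2_silent", "MSH2", sil$expr,
        "functionally_neutral", "B", "none", "SILENT")
  rare <- find_codon_expr(db, "BRIP1", 600, 640, "missense")
  vr <- plant("brip1_rare", "BRIP1", rare$expr, "unknown", "none", "none", "")
  freqs[[length(freqs) + 1]] <- tibble(variant_key = vr$variant_key,
                                       max_af = 1e-4)   # below threshold

  # filler unknowns in filler genes (when present)
  fillers <- grep("^GENE\\d+$", db$genes$gene_symbol, value = TRUE)
  for (g in utils::head(fillers, 3)) {
    e <- find_codon_expr(db, g, 50, 90, "missense")
    plant(paste0(tolower(g), "_vus"), g, e$expr, "unknown", "none", "none", "")
  }

  list(
    assertions = bind_rows(assertions),
    biomarkers = bind_rows(biomarkers),
    hotspots = bind_rows(hotspots),
    scores = bind_rows(scores),
    frequencies = bind_rows(freqs),
    ontology_edges = fixture_ontology_edges(),
    ontology_labels = fixture_ontology_labels(),
    germline_panel = fixture_germline_panel(),
    trial_rules = fixture_trial_rules(),
    library = bind_rows(lib)
  )
}

fixture_ontology_labels <- function() {
  tibble::tribble(
    ~term_id, ~label,
    "cancer", "Cancer",
    "solid_tumor", "Solid tumor",
    "hematologic_malignancy", "Hematologic malignancy",
    "lung_cancer", "Lung cancer",
    "nsclc", "Non-small cell lung cancer",
    "lung_adenocarcinoma", "Lung adenocarcinoma",
    "breast_carcinoma", "Breast carcinoma",
    "ovarian_epithelial", "Ovarian epithelial tumor",
    "gastrointestinal_cancer", "Gastrointestinal cancer",
    "colorectal_adenocarcinoma", "Colorectal adenocarcinoma",
    "esophagogastric_adenocarcinoma", "Esophagogastric adenocarcinoma",
    "pancreatic_adenocarcinoma", "Pancreatic adenocarcinoma",
    "cholangiocarcinoma", "Cholangiocarcinoma",
    "melanoma", "Melanoma",
    "sarcoma", "Sarcoma",
    "gist", "Gastrointestinal stromal tumor",
    "prostate_adenocarcinoma", "Prostate adenocarcinoma",
    "aml", "Acute myeloid leukemia"
  )
}

fixture_ontology_edges <- function() {
  tibble::tribble(
    ~child_id, ~parent_id,
    "solid_tumor", "cancer",
    "hematologic_malignancy", "cancer",
    "lung_cancer", "solid_tumor",
    "nsclc", "lung_cancer",
    "lung_adenocarcinoma", "nsclc",
    "breast_carcinoma", "solid_tumor",
    "ovarian_epithelial", "solid_tumor",
    "gastrointestinal_cancer", "solid_tumor",
    "colorectal_adenocarcinoma", "gastrointestinal_cancer",
    "esophagogastric_adenocarcinoma", "gastrointestinal_cancer",
    "pancreatic_adenocarcinoma", "gastrointestinal_cancer",
    "cholangiocarcinoma", "gastrointestinal_cancer",
    "melanoma", "solid_tumor",
    "sarcoma", "solid_tumor",
    "gist", "sarcoma",
    "gist", "gastrointestinal_cancer",
    "prostate_adenocarcinoma", "solid_tumor",
    "aml", "hematologic_malignancy"
  )
}

fixture_germline_panel <- function() {
  genes <- c("APC", "ATM", "BMPR1A", "BRCA1", "BRCA2", "BRIP1", "CDH1",
             "CHEK2", "MEN1", "MLH1", "MSH2", "MSH6", "MUTYH", "NF2",
             "PALB2", "PMS2", "PTEN", "RAD51C", "RAD51D", "RB1", "RET",
             "SDHB", "SDHC", "SDHD", "SMAD3", "SMAD4", "STK11", "TGFBR1",
             "TGFBR2", "TP53", "TSC1", "TSC2", "VHL", "WT1")
  tibble(gene_symbol = genes, biallelic_only = genes == "MUTYH")
}

DDR_GENES <- c("BRCA1", "BRCA2", "MLH1", "MSH2", "MSH6", "PMS2",
               "ATM", "PALB2", "CHEK2", "RAD51C", "BRIP1")

fixture_trial_rules <- function() {
  alter <- function(genes, class) list(pred = "alteration",
                                       genes = as.list(genes), class = class)
  mmr <- c("MLH1", "MSH2", "MSH6", "PMS2")
  ddr_other <- setdiff(DDR_GENES, c("BRCA1", "BRCA2", mmr))
  list(
    list(trial_id = "BoB", arm_id = "1A", priority = 1,
         expression = alter(c("BRCA1", "BRCA2"), "LoF_mutation")),
    list(trial_id = "BoB", arm_id = "1B", priority = 2,
         expression = alter(mmr, "LoF_mutation")),
    list(trial_id = "BoB", arm_id = "1C", priority = 3,
         expression = alter(c("POLE", "POLD1"), "SoF_mutation")),
    list(trial_id = "BoB", arm_id = "1D", priority = 4,
         expression = list(op = "ALL", children = list(
           list(pred = "signature", name = "TMB",
                categories = list("intermediate", "high")),
           list(op = "NONE", children = list(
             alter(DDR_GENES, "LoF_mutation")))
         ))),
    list(trial_id = "BoB", arm_id = "1E", priority = 5,
         expression = alter(ddr_other, "LoF_mutation")),
    list(trial_id = "BoB", arm_id = "1F", priority = 6,
         expression = alter("CD274", "amplification"))
  )
}

#' Write knowledge fixtures to a directory
#'
#' @param kn output of [generate_knowledge_fixtures()].
#' @param dir target directory.
#' @return named vector of paths (the `paths` argument for
#'   [load_resources()]).
#' @export
write_knowledge_fixtures <- function(kn, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drop_cols <- c("match_level", "match_key", "norm_variant_key",
                 "norm_protein_key", "cat_consequence", "cat_exon",
                 "cat_aa_start", "cat_aa_end", "entity", "usable")
  p <- c(
    assertions = file.path(dir, "assertions.tsv"),
    biomarkers = file.path(dir, "biomarkers.tsv"),
    hotspots = file.path(dir, "hotspots.tsv"),
    scores = file.path(dir, "scores.tsv"),
    frequencies = file.path(dir, "frequencies.tsv"),
    ontology_edges = file.path(dir, "ontology_edges.tsv"),
    ontology_labels = file.path(dir, "ontology_labels.tsv"),
    germline_panel = file.path(dir, "germline_panel.tsv"),
    trial_rules = file.path(dir, "trial_rules.json")
  )
  readr::write_tsv(kn$assertions[, setdiff(names(kn$assertions), drop_cols)],
                   p[["assertions"]])
  readr::write_tsv(kn$biomarkers[, setdiff(names(kn$biomarkers), drop_cols)],
                   p[["biomarkers"]])
  readr::write_tsv(kn$hotspots, p[["hotspots"]])
  readr::write_tsv(kn$scores, p[["scores"]])
  readr::write_tsv(kn$frequencies, p[["frequencies"]])
  readr::write_tsv(kn$ontology_edges, p[["ontology_edges"]])
  readr::write_tsv(kn$ontology_labels, p[["ontology_labels"]])
  readr::write_tsv(kn$germline_panel, p[["germline_panel"]])
  jsonlite::write_json(kn$trial_rules, p[["trial_rules"]],
                       auto_unbox = TRUE, pretty = TRUE)
  p
}
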