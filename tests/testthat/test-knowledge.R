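# Knowledge layer: loading, rating filters, aggregation, ontology relations,
# critical-region inference.

test_that("resource loading populates a manifest and fails on schema problems", {
  fx <- fx_bundle()
  kb <- fx$kb
  expect_s3_class(kb$manifest, "tbl_df")
  expect_setequal(kb$manifest$resource,
                  c("assertions", "biomarkers", "hotspots", "scores",
                    "frequencies", "ontology", "germline_panel"))
  expect_true(all(kb$manifest$n_records > 0))

  # biomarker with unknown cancer-type term is rejected at load
  d <- file.path(tempdir(), "bad_kb")
  paths <- write_knowledge_fixtures(fx$kn, d)
  bm <- readr::read_tsv(paths[["biomarkers"]], show_col_types = FALSE)
  bm$cancer_type[1] <- "no_such_term"
  readr::write_tsv(bm, paths[["biomarkers"]])
  expect_error(load_resources(paths, fx$db), "no_such_term")

  # missing column is named
  a <- readr::read_tsv(paths[["assertions"]], show_col_types = FALSE)
  readr::write_tsv(a[, -which(names(a) == "rating")], paths[["assertions"]])
  expect_error(load_resources(paths, fx$db), "rating")
})

test_that("two sources spelling the same allele differently share one key", {
  fx <- fx_bundle()
  v <- normalize_variants("BRAF:p.V600E", fx$db)
  agg <- aggregate_assertions(v, fx$kb)
  expect_setequal(unique(agg$records$source), c("CIViC", "CGI"))
  expect_equal(agg$verdict, "functional")
})

test_that("rating filter partitions usable vs weak, inclusive at the minimum", {
  cfg <- interpretation_config()
  a <- tibble::tibble(
    source = c("ClinVar", "ClinVar", "CIViC", "CIViC", "CIViC"),
    rating = c(1, 2, 2, 3, 5))
  out <- filter_by_rating(a, cfg)
  expect_equal(out$usable, c(FALSE, TRUE, FALSE, TRUE, TRUE))
  b <- tibble::tibble(source = "MysteryDB", rating = 5)
  expect_error(filter_by_rating(b, cfg), "MysteryDB")
})

test_that("assertion aggregation yields functional / neutral / conflicting / none", {
  fx <- fx_bundle()
  db <- fx$db; kb <- fx$kb
  splice <- normalize_variants("BRCA1:c.5468-1G>A", db)
  expect_equal(aggregate_assertions(splice, kb)$verdict, "functional")
  lib <- fx$kn$library
  benign <- lib[lib$variant_id == "pms2_benign", ]
  expect_equal(aggregate_assertions(benign, kb)$verdict, "neutral")
  confl <- lib[lib$variant_id == "chek2_conflict", ]
  expect_equal(aggregate_assertions(confl, kb)$verdict, "conflicting")
  nothing <- normalize_variants("KRAS:c.35G>A", db)
  expect_equal(aggregate_assertions(nothing, kb)$verdict, "none")
  # weak-only records match but carry no verdict
  weak <- lib[lib$variant_id == "palb2_weak_only", ]
  agg <- aggregate_assertions(weak, kb)
  expect_equal(agg$verdict, "none")
  expect_true(nrow(agg$records) == 1 && !agg$records$usable)
})

test_that("aggregation returns the union of per-source brute-force scans", {
  fx <- fx_bundle()
  kb <- fx$kb
  for (vid in c("braf_v600e", "brca1_splice", "chek2_conflict")) {
    v <- fx$kn$library[fx$kn$library$variant_id == vid, ]
    agg <- aggregate_assertions(v, kb)
    manual <- 0L
    for (src in unique(kb$assertions$source)) {
      sub <- kb
      sub$assertions <- kb$assertions[kb$assertions$source == src, ]
      manual <- manual + nrow(aggregate_assertions(v, sub)$records)
    }
    expect_equal(nrow(agg$records), manual)
  }
})

test_that("common polymorphism detection uses a >= threshold and defaults to FALSE", {
  fx <- fx_bundle()
  lib <- fx$kn$library
  cfg <- interpretation_config()
  common <- lib[lib$variant_id == "tp53_common", ]
  expect_true(is_common_polymorphism(common, fx$kb, cfg))
  boundary <- lib[lib$variant_id == "mlh1_af_boundary", ]   # AF exactly 0.01
  expect_true(is_common_polymorphism(boundary, fx$kb, cfg))
  rare <- lib[lib$variant_id == "brip1_rare", ]             # AF 1e-4
  expect_false(is_common_polymorphism(rare, fx$kb, cfg))
  absent <- normalize_variants("KRAS:c.35G>A", fx$db)
  expect_false(is_common_polymorphism(absent, fx$kb, cfg))
})

test_that("cancer-type relation distinguishes same / subtype / other and direction", {
  fx <- fx_bundle()
  ont <- fx$kb$ontology
  expect_equal(cancer_type_relation("lung_adenocarcinoma", "nsclc", ont),
               "patient_is_subtype")
  expect_equal(cancer_type_relation("nsclc", "nsclc", ont), "same")
  expect_equal(cancer_type_relation("nsclc", "lung_adenocarcinoma", ont),
               "other")   # reverse direction is not a match
  expect_equal(cancer_type_relation("melanoma", "aml", ont), "other")
  expect_error(cancer_type_relation("made_up", "nsclc", ont), "made_up")
})

test_that("cancer-type relation agrees with an igraph reachability oracle on a random DAG", {
  skip_if_not_installed("igraph")
  set.seed(11)
  n <- 200
  terms <- sprintf("T%03d", seq_len(n))
  # random DAG: each node gets 1-2 parents among lower-numbered nodes
  edges <- list()
  for (i in 2:n) {
    for (p in sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))) {
      edges[[length(edges) + 1]] <- c(terms[i], terms[p])
    }
  }
  em <- do.call(rbind, edges)
  ont <- list(labels = tibble::tibble(term_id = terms, label = terms),
              parents = split(em[, 2], em[, 1]))
  g <- igraph::graph_from_edgelist(em, directed = TRUE)
  for (k in 1:500) {
    a <- sample(terms, 1); b <- sample(terms, 1)
    got <- cancer_type_relation(a, b, ont)
    want <- if (a == b) "same" else {
      reachable <- is.finite(igraph::distances(g, v = a, to = b,
                                               mode = "out")[1, 1])
      if (reachable) "patient_is_subtype" else "other"
    }
    expect_identical(got, want)
  }
})

test_that("critical-region inference takes the most C-terminal curated truncation and grows monotonically", {
  fx <- fx_bundle()
  kb <- fx$kb
  regs <- infer_critical_regions("APC", kb)
  expect_length(regs, 1)
  expect_equal(regs[[1]][1, "start"], c(start = 1L))
  landmark <- regs[[1]][1, "end"]
  expect_true(landmark >= 2000 && landmark < 2100)
  # no curated truncating loss-of-function: empty
  expect_length(infer_critical_regions("PTEN", kb), 0)
  # adding a further curated truncation extends the interval
  found <- oncoboard:::find_codon_expr(fx$db, "APC", 2400, 2440, "stop")
  e <- found$expr
  v <- normalize_variants(paste0("APC:", e), fx$db)
  extra <- tibble::tibble(
    source = "ClinVar", source_version = "2024-01", gene_symbol = "APC",
    match_type = "exact_change", match_value = e, effect = "loss_of_function",
    rating = 3, germline_pathogenicity = "pathogenic",
    match_level = "nucleotide", match_key = v$variant_key,
    norm_variant_key = v$variant_key,
    norm_protein_key = paste0("APC:", v$protein_change),
    cat_consequence = NA, cat_exon = NA, cat_aa_start = NA, cat_aa_end = NA,
    entity = NA, usable = TRUE)
  kb2 <- kb
  kb2$assertions <- dplyr::bind_rows(kb$assertions, extra)
  regs2 <- infer_critical_regions("APC", kb2)
  expect_equal(unname(regs2[[1]][1, "end"]), as.integer(found$codon))
  expect_true(regs2[[1]][1, "end"] >= landmark)
})
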