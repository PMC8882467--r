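# Per-patient structured reports and the end-to-end pipeline.
#
# The canonical report artifact is a structured JSON document: a header, the
# resource manifest (version control of everything used to annotate), the
# signature table, three variant tables partitioned by functional label, the
# biomarker matches with their ESCAT tiers, trial recommendations and germline
# alerts. Content is deterministic; only the timestamp differs between
# identical runs.

#' Assemble a patient report
#'
#' @param profile a [tumor_profile()] whose `calls` cover every variant.
#' @param matches ESCAT-assigned biomarker matches ([assign_escat()]).
#' @param recommendations trial recommendations ([evaluate_trial_rules()]).
#' @param alerts germline alerts ([issue_germline_alerts()]).
#' @param manifest resource manifest (from the `knowledge_db`).
#' @return object of class `patient_report`.
#' @export
build_report <- function(profile, matches, recommendations, alerts, manifest) {
  calls <- profile$calls
  if (is.null(calls)) integrity_abort("profile carries no classified variants")
  if (nrow(calls) > 0 &&
      (anyNA(calls$label) || any(!nzchar(calls$label)))) {
    bad <- calls$variant_key[is.na(calls$label) | !nzchar(calls$label)][1]
    integrity_abort(paste0("variant without a functional call: ", bad))
  }
  order_tbl <- function(x) arrange(x, .data$gene_symbol, .data$pos)
  tbl_cols <- c("gene_symbol", "chrom", "pos", "ref", "alt", "variant_key",
                "cdna_change", "protein_change", "consequence", "exon_number",
                "vaf", "origin", "zygosity", "label", "effect_direction",
                "evidence_tier", "strength", "criteria_codes",
                "matched_sources", "assertion_conflict")
  decorate <- function(x) {
    x <- x[, intersect(tbl_cols, names(x))]
    x$n_biomarker_matches <- vapply(x$variant_key, function(k)
      sum(matches$variant_key == k), integer(1))
    x$best_escat <- vapply(x$variant_key, function(k) {
      t <- matches$escat_tier[matches$variant_key == k]
      if (length(t) == 0) NA_character_ else sort(t)[1]
    }, character(1))
    x$germline_alert <- x$variant_key %in% alerts$variant_key
    x
  }
  tables <- list(
    functionally_relevant =
      decorate(order_tbl(filter(calls, .data$label == "functionally_relevant"))),
    unknown = decorate(order_tbl(filter(calls, .data$label == "unknown"))),
    functionally_neutral =
      decorate(order_tbl(filter(calls, .data$label == "functionally_neutral")))
  )
  structure(
    list(
      header = list(patient_id = profile$patient_id,
                    cancer_type = profile$cancer_type,
                    paired = profile$paired,
                    assay = profile$assay %||% list()),
      manifest = manifest,
      signatures = profile$signatures,
      tables = tables,
      biomarker_matches = matches,
      trial_recommendations = recommendations,
      germline_alerts = alerts,
      counts = list(
        n_variants = nrow(calls),
        n_relevant = nrow(tables$functionally_relevant),
        n_unknown = nrow(tables$unknown),
        n_neutral = nrow(tables$functionally_neutral)
      ),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    ),
    class = "patient_report"
  )
}

#' @export
print.patient_report <- function(x, ...) {
  cat("<patient_report> ", x$header$patient_id, " (", x$header$cancer_type,
      ")\n", sep = "")
  cat("  variants: ", x$counts$n_relevant, " relevant / ",
      x$counts$n_unknown, " unknown / ", x$counts$n_neutral, " neutral\n",
      sep = "")
  cat("  trial recommendations: ", nrow(x$trial_recommendations),
      "; germline alerts: ", nrow(x$germline_alerts), "\n", sep = "")
  invisible(x)
}

#' Serialize / parse a patient report
#'
#' @param report a `patient_report`.
#' @param path file path (`.json`).
#' @param drop_timestamp drop the run timestamp (used to compare runs).
#' @return `serialize_report()` returns a JSON string; `write_report()` the
#'   path invisibly; `read_report()` a `patient_report`.
#' @export
serialize_report <- function(report, drop_timestamp = FALSE) {
  x <- unclass(report)
  if (drop_timestamp) x$timestamp <- NULL
  jsonlite::toJSON(x, dataframe = "columns", auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)
}

#' @rdname serialize_report
#' @export
write_report <- function(report, path) {
  writeLines(serialize_report(report), path)
  invisible(path)
}

#' @rdname serialize_report
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  variant_template <- tibble(
    gene_symbol = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), variant_key = character(),
    cdna_change = character(), protein_change = character(),
    consequence = character(), exon_number = integer(), vaf = double(),
    origin = character(), zygosity = character(), label = character(),
    effect_direction = character(), evidence_tier = character(),
    strength = character(), criteria_codes = character(),
    matched_sources = character(), assertion_conflict = logical(),
    n_biomarker_matches = integer(), best_escat = character(),
    germline_alert = logical())
  as_typed <- function(y, template) {
    if (is.null(y)) return(template)
    if (is.data.frame(y)) {
      return(if (nrow(y) > 0) as_tibble(y) else template)
    }
    # column-format object: named list of (possibly empty) vectors/lists
    n <- if (length(y)) max(lengths(y), 0L) else 0L
    if (n == 0L) return(template)
    cols <- lapply(y, function(col) {
      if (is.list(col)) {
        unlist(lapply(col, function(e) if (is.null(e)) NA else e))
      } else col
    })
    out <- as_tibble(cols)
    # all-NA columns lose their type in JSON; restore it from the template
    cast_like <- function(x, t) {
      if (is.character(t)) as.character(x)
      else if (is.integer(t)) as.integer(x)
      else if (is.double(t)) as.double(x)
      else if (is.logical(t)) as.logical(x)
      else x
    }
    for (nm in intersect(names(out), names(template))) {
      if (all(is.na(out[[nm]])) ||
          (is.integer(template[[nm]]) && is.numeric(out[[nm]]))) {
        out[[nm]] <- cast_like(out[[nm]], template[[nm]])
      }
    }
    out
  }
  for (nm in names(x$tables)) {
    x$tables[[nm]] <- as_typed(x$tables[[nm]], variant_template)
  }
  x$manifest <- as_tibble(x$manifest)
  x$biomarker_matches <- as_typed(x$biomarker_matches, tibble(
    variant_key = character(), gene_symbol = character(),
    protein_change = character(), match_kind = character(),
    association = character(), drug_or_context = character(),
    evidence_level = character(), biomarker_cancer_type = character(),
    type_relation = character(), off_tumor_type = logical(),
    source = character(), escat_tier = character(),
    escat_rationale = character()))
  x$trial_recommendations <- as_typed(x$trial_recommendations, tibble(
    trial_id = character(), arm_id = character(), priority = integer()))
  x$germline_alerts <- as_typed(x$germline_alerts, tibble(
    patient_id = character(), gene_symbol = character(),
    variant_key = character(), protein_change = character(),
    zygosity = character(), evidence_tier = character(),
    origin_basis = character()))
  structure(x, class = "patient_report")
}

#' Interpret one patient
#'
#' Runs normalization, classification, biomarker matching with ESCAT tiers,
#' trial-rule evaluation and germline alerting, and assembles the report.
#'
#' @param raw_variants raw variant tibble (e.g. [read_variants_vcf()]) or
#'   character vector of `GENE:expression` lines.
#' @param meta profile metadata ([read_patient_profile()] output or an
#'   equivalent list).
#' @param db a [transcript_db()].
#' @param kb a `knowledge_db`.
#' @param config an [interpretation_config()].
#' @return a `patient_report`.
#' @export
interpret_patient <- function(raw_variants, meta, db, kb,
                              config = interpretation_config()) {
  variants <- normalize_variants(raw_variants, db)
  calls <- classify_variants(variants, db, kb, config)
  profile <- tumor_profile(meta$patient_id, meta$cancer_type, calls,
                           copy_number = meta$copy_number,
                           signatures = meta$signatures,
                           paired = meta$paired)
  profile$assay <- meta$assay %||% list()
  matches <- match_biomarkers(calls, meta$cancer_type, kb) |>
    assign_escat(config)
  recommendations <- if (!is.null(kb$trial_rules)) {
    evaluate_trial_rules(profile, kb$trial_rules, config)
  } else {
    tibble(trial_id = character(), arm_id = character(), priority = integer())
  }
  alerts <- issue_germline_alerts(profile, kb$germline_panel, config)
  build_report(profile, matches, recommendations, alerts, kb$manifest)
}

#' Run the full pipeline over one or more patients
#'
#' Inputs are validated up front (fail-fast: no partial reports are written
#' when any input is malformed), then each patient is interpreted and a JSON
#' report written to `out_dir`.
#'
#' @param config_path path to the run-configuration YAML
#'   ([read_run_config()]).
#' @param inputs data frame with columns `vcf` and `profile` (file paths), or
#'   a list of such pairs.
#' @param out_dir output directory for `<patient_id>.json` reports.
#' @return tibble log with per-patient record counts per stage.
#' @export
run_pipeline <- function(config_path, inputs, out_dir) {
  rc <- read_run_config(config_path)
  config <- rc$config
  if (is.null(rc$paths[["models"]])) abort("run config lacks resources:models")
  db <- read_transcript_db(rc$paths[["models"]])
  kb <- load_resources(rc$paths[setdiff(names(rc$paths), "models")], db, config)
  inputs <- as_tibble(inputs)
  # integrity control before any classification runs
  for (i in seq_len(nrow(inputs))) {
    validate_vcf_lines(inputs$vcf[i])
    read_patient_profile(inputs$profile[i], config)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- vector("list", nrow(inputs))
  for (i in seq_len(nrow(inputs))) {
    meta <- read_patient_profile(inputs$profile[i], config)
    raw <- read_variants_vcf(inputs$vcf[i], db, config)
    report <- interpret_patient(raw, meta, db, kb, config)
    path <- file.path(out_dir, paste0(meta$patient_id, ".json"))
    write_report(report, path)
    log[[i]] <- tibble(
      patient_id = meta$patient_id,
      n_input = nrow(raw),
      n_classified = report$counts$n_variants,
      n_relevant = report$counts$n_relevant,
      n_unknown = report$counts$n_unknown,
      n_neutral = report$counts$n_neutral,
      n_biomarker_matches = nrow(report$biomarker_matches),
      n_trial_recommendations = nrow(report$trial_recommendations),
      n_germline_alerts = nrow(report$germline_alerts),
      report_path = path
    )
  }
  bind_rows(log)
}
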