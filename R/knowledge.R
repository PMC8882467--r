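# Knowledge layer: harmonized access to effect assertions, clinical
# biomarkers, hotspot catalogs, deleteriousness scores, population allele
# frequencies and the cancer-type ontology, all loaded from documented
# tab-separated fixtures behind one handle.

ASSERTION_COLS <- c("source", "source_version", "gene_symbol", "match_type",
                    "match_value", "effect", "rating", "germline_pathogenicity")
BIOMARKER_COLS <- c("gene_symbol", "match_type", "match_value", "cancer_type",
                    "association", "drug_or_context", "evidence_level",
                    "source", "source_version")
EFFECTS <- c("loss_of_function", "gain_of_function", "switch_of_function",
             "neutral", "uncertain")
EVIDENCE_LEVELS <- c("approved_or_guideline", "clinical_trial",
                     "retrospective_clinical", "case_report", "preclinical")

read_fixture_tsv <- function(path, required, file_label) {
  if (!file.exists(path)) abort(paste0(file_label, " not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(paste0(file_label, " (", path, "): missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  x
}

# Parse a category match specification of the form
# "consequence=missense|nonsense;exon=19;aa=1-300" (all parts optional).
parse_category_spec <- function(x) {
  out <- list(consequence = NA_character_, exon = NA_integer_,
              aa_start = NA_integer_, aa_end = NA_integer_)
  if (is.na(x) || !nzchar(x)) return(out)
  for (part in strsplit(x, ";", fixed = TRUE)[[1]]) {
    kv <- strsplit(part, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) abort(paste0("malformed category spec: '", x, "'"))
    val <- kv[2]
    switch(kv[1],
      consequence = out$consequence <- val,
      exon = out$exon <- as.integer(val),
      aa = {
        ab <- as.integer(strsplit(val, "-", fixed = TRUE)[[1]])
        out$aa_start <- ab[1]; out$aa_end <- ab[length(ab)]
      },
      abort(paste0("unknown category spec key: '", kv[1], "'"))
    )
  }
  out
}

# Normalize an exact-change match value through the same machinery as observed
# variants; protein-level specs are keyed on gene + protein change, nucleotide
# specs on the canonical genomic key.
normalize_match_value <- function(db, gene, value, context) {
  v <- tryCatch(
    normalize_variants(paste0(gene, ":", value), db),
    error = function(e) {
      abort(paste0(context, ": cannot normalize '", gene, ":", value, "': ",
                   conditionMessage(e)))
    }
  )
  level <- if (startsWith(value, "p.")) "protein" else "nucleotide"
  key <- if (level == "protein") {
    paste0(gene, ":", v$protein_change)
  } else {
    v$variant_key
  }
  list(level = level, key = key, protein_key = paste0(gene, ":", v$protein_change),
       variant_key = v$variant_key)
}

prepare_match_table <- function(x, db, file_label) {
  n <- nrow(x)
  level <- character(n); key <- character(n); vkey <- character(n)
  pkey <- character(n)
  cat_consequence <- character(n); cat_exon <- integer(n)
  cat_aa_start <- integer(n); cat_aa_end <- integer(n)
  entity <- character(n)
  for (i in seq_len(n)) {
    mt <- x$match_type[i]
    mv <- x$match_value[i]
    level[i] <- NA; key[i] <- NA; vkey[i] <- NA; pkey[i] <- NA
    cat_consequence[i] <- NA; cat_exon[i] <- NA
    cat_aa_start[i] <- NA; cat_aa_end[i] <- NA; entity[i] <- NA
    ctx <- paste0(file_label, " line ", i)
    if (mt == "exact_change") {
      nm <- normalize_match_value(db, x$gene_symbol[i], mv, ctx)
      level[i] <- nm$level; key[i] <- nm$key
      vkey[i] <- nm$variant_key; pkey[i] <- nm$protein_key
    } else if (mt == "category") {
      cs <- parse_category_spec(mv)
      cat_consequence[i] <- cs$consequence; cat_exon[i] <- cs$exon
      cat_aa_start[i] <- cs$aa_start; cat_aa_end[i] <- cs$aa_end
    } else if (mt == "functional_entity") {
      if (!mv %in% c("loss_of_function", "gain_of_function",
                     "switch_of_function", "oncogenic", "relevant")) {
        abort(paste0(ctx, ": unknown functional entity '", mv, "'"))
      }
      entity[i] <- mv
    } else {
      abort(paste0(ctx, ": unknown match_type '", mt, "'"))
    }
  }
  x$match_level <- level
  x$match_key <- key
  x$norm_variant_key <- vkey
  x$norm_protein_key <- pkey
  x$cat_consequence <- cat_consequence
  x$cat_exon <- cat_exon
  x$cat_aa_start <- cat_aa_start
  x$cat_aa_end <- cat_aa_end
  x$entity <- entity
  x
}

#' Load the knowledge resources behind one handle
#'
#' @param paths named character vector/list of fixture paths with entries
#'   `assertions`, `biomarkers`, `hotspots`, `scores`, `frequencies`,
#'   `ontology_edges`, `ontology_labels`, `germline_panel` and optionally
#'   `trial_rules`.
#' @param db a [transcript_db()]; exact-change match values are normalized
#'   through the same variant normalization as observed variants.
#' @param config an [interpretation_config()].
#' @return a `knowledge_db` handle with a populated resource manifest.
#' @export
load_resources <- function(paths, db, config = interpretation_config()) {
  paths <- as.list(paths)
  req <- c("assertions", "biomarkers", "hotspots", "scores", "frequencies",
           "ontology_edges", "ontology_labels", "germline_panel")
  miss <- setdiff(req, names(paths))
  if (length(miss)) abort(paste0("missing resource path(s): ",
                                 paste(miss, collapse = ", ")))

  assertions <- read_fixture_tsv(paths$assertions, ASSERTION_COLS, "assertions")
  bad <- which(!assertions$effect %in% EFFECTS)
  if (length(bad)) {
    abort(paste0("assertions (", paths$assertions, ") line ", bad[1],
                 ": invalid effect '", assertions$effect[bad[1]], "'"))
  }
  assertions <- prepare_match_table(assertions, db, "assertions")
  assertions <- filter_by_rating(assertions, config)

  biomarkers <- read_fixture_tsv(paths$biomarkers, BIOMARKER_COLS, "biomarkers")
  bad <- which(!biomarkers$evidence_level %in% EVIDENCE_LEVELS)
  if (length(bad)) {
    abort(paste0("biomarkers (", paths$biomarkers, ") line ", bad[1],
                 ": invalid evidence_level '",
                 biomarkers$evidence_level[bad[1]], "'"))
  }
  biomarkers <- prepare_match_table(biomarkers, db, "biomarkers")

  hotspots <- read_fixture_tsv(
    paths$hotspots,
    c("gene_symbol", "aa_start", "aa_end", "variant_class", "p_value"),
    "hotspots")
  if (any(hotspots$p_value <= 0 | hotspots$p_value > 1)) {
    abort(paste0("hotspots (", paths$hotspots, "): p_value outside (0, 1]"))
  }

  scores_tbl <- read_fixture_tsv(paths$scores, c("variant_key", "phred_score"),
                                 "scores")
  if (any(scores_tbl$phred_score < 0)) {
    abort("scores: negative Phred score")
  }
  scores <- stats::setNames(scores_tbl$phred_score, scores_tbl$variant_key)

  freq_tbl <- read_fixture_tsv(paths$frequencies, c("variant_key", "max_af"),
                               "frequencies")
  frequencies <- stats::setNames(freq_tbl$max_af, freq_tbl$variant_key)

  ontology <- load_ontology(paths$ontology_edges, paths$ontology_labels)

  unresolved <- setdiff(unique(biomarkers$cancer_type), ontology$labels$term_id)
  if (length(unresolved)) {
    abort(paste0("biomarkers reference cancer type(s) missing from the ontology: ",
                 paste(unresolved, collapse = ", ")))
  }

  panel <- read_fixture_tsv(paths$germline_panel,
                            c("gene_symbol", "biallelic_only"),
                            "germline_panel")
  panel$biallelic_only <- as.logical(panel$biallelic_only)

  rules <- if (!is.null(paths$trial_rules)) read_trial_rules(paths$trial_rules)

  versions <- c(
    assertions = paste(sort(unique(assertions$source_version)), collapse = "+"),
    biomarkers = paste(sort(unique(biomarkers$source_version)), collapse = "+"),
    hotspots = "fixture-1", scores = "fixture-1", frequencies = "fixture-1",
    ontology = "fixture-1", germline_panel = "fixture-1"
  )
  counts <- c(nrow(assertions), nrow(biomarkers), nrow(hotspots),
              length(scores), length(frequencies), nrow(ontology$labels),
              nrow(panel))
  manifest <- tibble(
    resource = names(versions), version = unname(versions),
    n_records = counts,
    loaded_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  )

  structure(
    list(assertions = assertions, biomarkers = biomarkers, hotspots = hotspots,
         scores = scores, frequencies = frequencies, ontology = ontology,
         germline_panel = panel, trial_rules = rules, manifest = manifest),
    class = "knowledge_db"
  )
}

#' @export
print.knowledge_db <- function(x, ...) {
  cat("<knowledge_db>\n")
  print(x$manifest[, c("resource", "version", "n_records")])
  invisible(x)
}

#' Partition assertions by source-native evidence rating
#'
#' Records rated below their source's configured minimum are kept (for
#' reporting) but flagged `usable = FALSE` and never drive classification.
#'
#' @param assertions assertion tibble (a `rating` and `source` column).
#' @param config an [interpretation_config()] carrying `rating_minimums`.
#' @return the tibble with a logical `usable` column.
#' @export
filter_by_rating <- function(assertions, config = interpretation_config()) {
  mins <- config$rating_minimums
  missing_src <- setdiff(unique(assertions$source), names(mins))
  if (length(missing_src)) {
    abort(paste0("no rating minimum configured for source(s): ",
                 paste(missing_src, collapse = ", ")))
  }
  assertions$usable <- unname(assertions$rating >= mins[assertions$source])
  assertions
}

# ---- cancer-type ontology --------------------------------------------------

load_ontology <- function(edges_path, labels_path) {
  edges <- read_fixture_tsv(edges_path, c("child_id", "parent_id"),
                            "ontology edges")
  labels <- read_fixture_tsv(labels_path, c("term_id", "label"),
                             "ontology labels")
  terms <- labels$term_id
  unknown <- setdiff(unique(c(edges$child_id, edges$parent_id)), terms)
  if (length(unknown)) {
    abort(paste0("ontology edges reference unlabeled term(s): ",
                 paste(unknown, collapse = ", ")))
  }
  parents <- split(edges$parent_id, edges$child_id)
  ont <- list(labels = labels, parents = parents)
  if (ontology_has_cycle(ont)) abort("cancer-type ontology contains a cycle")
  ont
}

ontology_ancestors <- function(ontology, term) {
  seen <- character(0)
  frontier <- ontology$parents[[term]] %||% character(0)
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(lapply(new, function(t)
      ontology$parents[[t]] %||% character(0))))
  }
  seen
}

ontology_has_cycle <- function(ontology) {
  for (t in ontology$labels$term_id) {
    if (t %in% ontology_ancestors(ontology, t)) return(TRUE)
  }
  FALSE
}

#' Relate a patient's cancer type to a biomarker's cancer type
#'
#' @param patient_type,biomarker_type ontology term ids.
#' @param ontology the `ontology` element of a `knowledge_db` (or the handle).
#' @return `"same"`, `"patient_is_subtype"` (the biomarker type is an ancestor
#'   of the patient type in the disease hierarchy) or `"other"` — including
#'   the reverse direction, which does not count as a match.
#' @export
cancer_type_relation <- function(patient_type, biomarker_type, ontology) {
  if (inherits(ontology, "knowledge_db")) ontology <- ontology$ontology
  known <- ontology$labels$term_id
  for (t in c(patient_type, biomarker_type)) {
    if (!t %in% known) abort(paste0("unresolvable cancer-type term: ", t))
  }
  if (identical(patient_type, biomarker_type)) return("same")
  if (biomarker_type %in% ontology_ancestors(ontology, patient_type)) {
    return("patient_is_subtype")
  }
  "other"
}

# ---- per-variant queries ---------------------------------------------------

# Protein position span of a variant, parsed from its normalized protein
# change; used for category and hotspot matching.
variant_aa_span <- function(v) {
  pc <- v$protein_change
  if (is.na(pc) || !nzchar(pc)) return(NULL)
  m <- str_match(pc, "^p\\.[A-Z*](\\d+)(?:_[A-Z*](\\d+))?")
  if (is.na(m[1])) return(NULL)
  a <- as.integer(m[2]); b <- if (is.na(m[3])) a else as.integer(m[3])
  c(a, b)
}

match_category_row <- function(rec, v) {
  if (rec$gene_symbol != v$gene_symbol) return(FALSE)
  if (!is.na(rec$cat_consequence)) {
    allowed <- strsplit(rec$cat_consequence, "|", fixed = TRUE)[[1]]
    if (!v$consequence %in% allowed) return(FALSE)
  }
  if (!is.na(rec$cat_exon)) {
    if (is.na(v$exon_number) || v$exon_number != rec$cat_exon) return(FALSE)
  }
  if (!is.na(rec$cat_aa_start)) {
    span <- variant_aa_span(v)
    if (is.null(span)) return(FALSE)
    if (span[2] < rec$cat_aa_start || span[1] > rec$cat_aa_end) return(FALSE)
  }
  TRUE
}

# All assertion records (usable and weak) matching one normalized variant.
# Functional-entity assertions are excluded: entity membership is defined by
# the engine's own output and cannot feed back into evidence A.
match_assertions <- function(v, kb) {
  a <- kb$assertions
  if (nrow(a) == 0) return(a)
  hit <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (a$match_type[i] == "exact_change") {
      hit[i] <- if (a$match_level[i] == "protein") {
        nzchar(v$protein_change %||% "") &&
          identical(a$match_key[i], paste0(v$gene_symbol, ":", v$protein_change))
      } else {
        identical(a$match_key[i], v$variant_key)
      }
    } else if (a$match_type[i] == "category") {
      hit[i] <- match_category_row(a[i, ], v)
    }
  }
  a[hit, ]
}

assertion_axis <- function(rec) {
  # Map heterogeneous assertion scopes onto the allele-centric functional axis.
  gp <- rec$germline_pathogenicity
  if (rec$effect %in% c("loss_of_function", "gain_of_function",
                        "switch_of_function")) return("functional")
  if (rec$effect == "neutral") return("neutral")
  if (!is.na(gp) && gp %in% c("pathogenic", "likely_pathogenic")) return("functional")
  if (!is.na(gp) && gp %in% c("benign", "likely_benign")) return("neutral")
  "none"
}

#' Aggregate knowledge-base assertions for one variant
#'
#' @param v one-row tibble of a normalized variant.
#' @param kb a `knowledge_db`.
#' @return list with `verdict` (`functional`, `neutral`, `conflicting`,
#'   `none`), `direction` (strongest explicit effect among usable functional
#'   matches, `NA` when none), and `records` (all matched records, weak ones
#'   flagged).
#' @export
aggregate_assertions <- function(v, kb) {
  recs <- match_assertions(v, kb)
  if (nrow(recs) == 0) {
    return(list(verdict = "none", direction = NA_character_, records = recs))
  }
  usable <- recs[recs$usable, ]
  axes <- if (nrow(usable)) vapply(seq_len(nrow(usable)), function(i)
    assertion_axis(usable[i, ]), character(1)) else character(0)
  has_f <- any(axes == "functional")
  has_n <- any(axes == "neutral")
  verdict <- if (has_f && has_n) "conflicting"
    else if (has_f) "functional"
    else if (has_n) "neutral"
    else "none"
  direction <- NA_character_
  if (has_f) {
    eff <- usable$effect[axes == "functional"]
    explicit <- eff[eff %in% c("loss_of_function", "gain_of_function",
                               "switch_of_function")]
    direction <- if (length(explicit)) explicit[1] else "pathogenicity_only"
  }
  list(verdict = verdict, direction = direction, records = recs)
}

#' Is a variant a common polymorphism?
#'
#' @param v one-row normalized variant tibble.
#' @param kb a `knowledge_db`.
#' @param config an [interpretation_config()].
#' @return `TRUE` iff the maximum population allele frequency on record is at
#'   least `common_af_threshold`; absence from the table means `FALSE`.
#' @export
is_common_polymorphism <- function(v, kb, config = interpretation_config()) {
  af <- kb$frequencies[v$variant_key]
  !is.na(af) && af >= config$common_af_threshold
}

hotspot_hit <- function(v, kb, config) {
  span <- variant_aa_span(v)
  if (is.null(span)) return(FALSE)
  klass <- if (v$consequence == "missense") "missense"
    else if (v$consequence %in% c("inframe_insertion", "inframe_deletion"))
      "inframe_indel"
    else return(FALSE)
  h <- kb$hotspots
  any(h$gene_symbol == v$gene_symbol & h$variant_class == klass &
        h$p_value < config$hotspot_alpha &
        h$aa_start <= span[2] & h$aa_end >= span[1])
}

#' Infer critical protein regions for a tumor suppressor
#'
#' The curated loss-of-function truncating assertions for the gene delimit a
#' prefix interval: any premature stop at or before the most C-terminal
#' curated truncating position is deemed to disrupt a crucial region.
#'
#' @param gene gene symbol (mechanism must be tumor-suppressor or dual).
#' @param kb a `knowledge_db`.
#' @return a list of protein intervals (2-column matrices); empty when no
#'   usable curated truncating loss-of-function assertion exists.
#' @export
infer_critical_regions <- function(gene, kb) {
  a <- kb$assertions
  a <- a[a$gene_symbol == gene & a$usable &
           a$match_type == "exact_change", , drop = FALSE]
  if (nrow(a) == 0) return(list())
  lof <- vapply(seq_len(nrow(a)), function(i)
    assertion_axis(a[i, ]) == "functional" &&
      (a$effect[i] == "loss_of_function" ||
         (!is.na(a$germline_pathogenicity[i]) &&
            a$germline_pathogenicity[i] %in% c("pathogenic", "likely_pathogenic"))),
    logical(1))
  a <- a[lof, , drop = FALSE]
  if (nrow(a) == 0) return(list())
  trunc_pos <- integer(0)
  for (i in seq_len(nrow(a))) {
    pk <- a$norm_protein_key[i]
    m <- str_match(pk, ":p\\.[A-Z](\\d+)(\\*|fs)$")
    if (!is.na(m[1])) trunc_pos <- c(trunc_pos, as.integer(m[2]))
  }
  if (length(trunc_pos) == 0) return(list())
  landmark <- max(trunc_pos)
  list(matrix(c(1L, landmark), ncol = 2,
              dimnames = list(NULL, c("start", "end"))))
}
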