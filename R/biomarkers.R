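# Context-dependent layer, part 1: biomarker matching and ESCAT tiering.

entity_satisfied <- function(entity, call) {
  if (call$label != "functionally_relevant") return(FALSE)
  dir <- call$effect_direction
  switch(entity,
    loss_of_function = dir == "loss_of_function",
    gain_of_function = dir == "gain_of_function",
    switch_of_function = dir == "switch_of_function",
    oncogenic = dir %in% c("gain_of_function", "switch_of_function"),
    relevant = TRUE,
    FALSE
  )
}

#' Match classified variants against the biomarker catalog
#'
#' Exact-change biomarkers match by normalized key (protein- or
#' nucleotide-level, as authored); category biomarkers by predicate over
#' consequence/exon/protein interval; functional-entity biomarkers by the
#' engine's own functional call (e.g., "oncogenic mutations" requires a
#' relevant gain/switch-of-function call). Matches whose cancer type bears no
#' relation to the patient's are retained but flagged — they can only reach
#' the lower actionability tiers.
#'
#' @param calls an `oncoboard_calls` tibble from [classify_variants()].
#' @param cancer_type the patient's cancer-type ontology term.
#' @param kb a `knowledge_db`.
#' @return tibble, one row per (variant, biomarker) match.
#' @export
match_biomarkers <- function(calls, cancer_type, kb) {
  bm <- kb$biomarkers
  out <- list()
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    cand <- bm[bm$gene_symbol == v$gene_symbol, , drop = FALSE]
    if (nrow(cand) == 0) next
    for (j in seq_len(nrow(cand))) {
      b <- cand[j, ]
      hit <- switch(b$match_type,
        exact_change = if (b$match_level == "protein") {
          nzchar(v$protein_change %||% "") &&
            identical(b$match_key, paste0(v$gene_symbol, ":", v$protein_change))
        } else {
          identical(b$match_key, v$variant_key)
        },
        category = match_category_row(b, v),
        functional_entity = entity_satisfied(b$entity, v),
        FALSE
      )
      if (!hit) next
      rel <- cancer_type_relation(cancer_type, b$cancer_type, kb$ontology)
      out[[length(out) + 1]] <- tibble(
        variant_key = v$variant_key, gene_symbol = v$gene_symbol,
        protein_change = v$protein_change,
        match_kind = b$match_type, association = b$association,
        drug_or_context = b$drug_or_context,
        evidence_level = b$evidence_level,
        biomarker_cancer_type = b$cancer_type,
        type_relation = rel,
        off_tumor_type = rel == "other",
        source = b$source
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(variant_key = character(), gene_symbol = character(),
                  protein_change = character(), match_kind = character(),
                  association = character(), drug_or_context = character(),
                  evidence_level = character(),
                  biomarker_cancer_type = character(),
                  type_relation = character(), off_tumor_type = logical(),
                  source = character()))
  }
  bind_rows(out)
}

#' Assign ESCAT actionability tiers to biomarker matches
#'
#' The tier is a pure lookup in the configured
#' (evidence level x cancer-type relation) matrix; see
#' [default_escat_matrix()] for the defaults.
#'
#' @param matches tibble from [match_biomarkers()].
#' @param config an [interpretation_config()].
#' @return the matches with `escat_tier` and `escat_rationale` columns.
#' @export
assign_escat <- function(matches, config = interpretation_config()) {
  m <- config$escat_matrix
  tiers <- character(nrow(matches))
  for (i in seq_len(nrow(matches))) {
    lev <- matches$evidence_level[i]
    rel <- matches$type_relation[i]
    if (!lev %in% rownames(m)) {
      abort(paste0("evidence level absent from ESCAT matrix: ", lev))
    }
    if (!rel %in% colnames(m)) {
      abort(paste0("cancer-type relation absent from ESCAT matrix: ", rel))
    }
    tiers[i] <- m[lev, rel]
  }
  matches$escat_tier <- tiers
  matches$escat_rationale <- paste0(matches$evidence_level, "|",
                                    matches$type_relation)
  matches
}
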