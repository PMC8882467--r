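# Clinical-trial eligibility rules: boolean combinator trees (ALL/ANY/NONE)
# over gene-alteration and signature predicates, with per-rule priorities and
# per-gene evidence-floor overrides.

ALTERATION_CLASSES <- c("LoF_mutation", "GoF_mutation", "SoF_mutation",
                        "amplification", "deletion")

#' Read a structured trial-rule file
#'
#' The file is a JSON array of rules, each with `trial_id`, `arm_id`,
#' `priority` (lower = higher priority), optional `evidence_floor_overrides`
#' (gene -> accepted evidence tiers) and an `expression` combinator tree.
#' Nodes are either `{"op": "ALL"|"ANY"|"NONE", "children": [...]}` or leaves
#' `{"pred": "alteration", "genes": [...], "class": "LoF_mutation"}` /
#' `{"pred": "signature", "name": "TMB", "categories": [...]}` /
#' `{"pred": "signature", "name": ..., "min": x}`.
#'
#' @param path path to the JSON rule file.
#' @return list of validated rule objects (class `trial_rules`).
#' @export
read_trial_rules <- function(path) {
  if (!file.exists(path)) abort(paste0("trial rule file not found: ", path))
  rules <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (r in rules) {
    for (fld in c("trial_id", "arm_id", "priority", "expression")) {
      if (is.null(r[[fld]])) {
        abort(paste0("trial rule missing field '", fld, "'"))
      }
    }
    validate_rule_node(r$expression, paste0(r$trial_id, "/", r$arm_id))
  }
  structure(rules, class = "trial_rules")
}

validate_rule_node <- function(node, ctx) {
  if (!is.null(node$op)) {
    if (!node$op %in% c("ALL", "ANY", "NONE")) {
      abort(paste0(ctx, ": unknown combinator '", node$op, "'"))
    }
    if (is.null(node$children) || length(node$children) == 0) {
      abort(paste0(ctx, ": combinator ", node$op, " has no children"))
    }
    for (ch in node$children) validate_rule_node(ch, ctx)
    return(invisible(TRUE))
  }
  if (is.null(node$pred)) abort(paste0(ctx, ": node is neither combinator nor predicate"))
  if (node$pred == "alteration") {
    if (is.null(node$genes) || length(node$genes) == 0) {
      abort(paste0(ctx, ": alteration predicate with empty gene set"))
    }
    if (is.null(node$class) || !node$class %in% ALTERATION_CLASSES) {
      abort(paste0(ctx, ": invalid alteration class '",
                   node$class %||% "", "'"))
    }
  } else if (node$pred == "signature") {
    if (is.null(node$name)) abort(paste0(ctx, ": signature predicate without name"))
    if (is.null(node$categories) && is.null(node$min)) {
      abort(paste0(ctx, ": signature predicate needs 'categories' or 'min'"))
    }
  } else {
    abort(paste0(ctx, ": unknown predicate '", node$pred, "'"))
  }
  invisible(TRUE)
}

direction_for_class <- function(class) {
  switch(class,
    LoF_mutation = "loss_of_function",
    GoF_mutation = "gain_of_function",
    SoF_mutation = "switch_of_function",
    NULL
  )
}

eval_rule_node <- function(node, profile, rule, config) {
  if (!is.null(node$op)) {
    vals <- vapply(node$children, eval_rule_node, logical(1),
                   profile = profile, rule = rule, config = config)
    return(switch(node$op, ALL = all(vals), ANY = any(vals),
                  NONE = !any(vals)))
  }
  if (node$pred == "alteration") {
    genes <- unlist(node$genes)
    dir <- direction_for_class(node$class)
    if (is.null(dir)) {  # copy-number classes
      cn <- profile$copy_number
      type <- if (node$class == "amplification") "amplification" else "deletion"
      return(!is.null(cn) && nrow(cn) > 0 &&
               any(cn$gene_symbol %in% genes & cn$type == type))
    }
    calls <- profile$calls
    if (is.null(calls) || nrow(calls) == 0) return(FALSE)
    overrides <- rule$evidence_floor_overrides %||% list()
    ok <- vapply(seq_len(nrow(calls)), function(i) {
      v <- calls[i, ]
      if (!v$gene_symbol %in% genes) return(FALSE)
      if (v$label != "functionally_relevant") return(FALSE)
      if (v$effect_direction != dir) return(FALSE)
      floor <- unlist(overrides[[v$gene_symbol]]) %||% config$trial_evidence_floor
      v$evidence_tier %in% floor
    }, logical(1))
    return(any(ok))
  }
  # signature predicate
  val <- profile$signatures[[node$name]]
  if (is.null(val)) return(FALSE)
  if (!is.null(node$min)) return(as.numeric(val) >= node$min)
  cat <- if (identical(node$name, "TMB") && is.numeric(val)) {
    tmb_category(val, config)
  } else {
    as.character(val)
  }
  cat %in% unlist(node$categories)
}

#' Evaluate trial eligibility rules over a tumor profile
#'
#' A rule fires when its boolean expression evaluates true over the profile's
#' classified variants, copy-number events and signatures. Mutation predicates
#' require a functionally relevant call of the matching direction whose
#' evidence tier meets the rule's floor (default: tiers A and B only —
#' computational-only evidence does not match trials unless a rule carries an
#' explicit per-gene override). `NONE` evaluates absence over the whole
#' profile.
#'
#' @param profile a `tumor_profile` (see [tumor_profile()]).
#' @param rules a `trial_rules` object from [read_trial_rules()].
#' @param config an [interpretation_config()].
#' @return tibble of firing rules ordered by priority
#'   (`trial_id`, `arm_id`, `priority`).
#' @export
evaluate_trial_rules <- function(profile, rules,
                                 config = interpretation_config()) {
  fired <- keep(rules, function(r)
    isTRUE(eval_rule_node(r$expression, profile, r, config)))
  out <- tibble(
    trial_id = map_chr(fired, "trial_id"),
    arm_id = map_chr(fired, "arm_id"),
    priority = map_int(fired, ~ as.integer(.x$priority))
  )
  arrange(out, .data$priority, .data$arm_id)
}
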