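# The allele-centric classification cascade.
#
# Pre-filter: variants assumed neutral (common polymorphisms, silent changes
# away from splice sites) are labelled functionally_neutral up front. Then
# strict precedence over three evidence sources: A = curated knowledge-base
# assertions; B = bona fide biological assumptions for tumor-suppressor null
# variants (PVS1-style); C = computational metrics (mutation hotspots, then
# CADD Phred scores for missense changes in tumor suppressors). The first
# conclusive verdict wins; cancer type, VAF and somatic/germline origin play
# no role at this layer.

TRUNCATING <- c("nonsense", "frameshift")

#' Flat decision step of the classification cascade
#'
#' Operates on the extracted per-variant features so the rule logic is a pure
#' function that can be exercised over its full input grid. `classify_variants()`
#' computes these features from data and then calls this.
#'
#' @param features data frame with columns `assertion_verdict`
#'   (`functional`/`neutral`/`conflicting`/`none`), `assertion_direction`,
#'   `consequence`, `nmd_predicted` (logical, NA when no PTC),
#'   `in_critical_region` (logical), `truncated_fraction` (NA when not
#'   truncating), `hotspot_significant` (logical), `phred_score` (NA when
#'   unscored), `mechanism`, `is_common` (logical).
#' @param config an [interpretation_config()].
#' @return tibble with `label`, `effect_direction`, `evidence_tier`,
#'   `strength`, `criteria_codes` (';'-joined).
#' @export
functional_cascade <- function(features, config = interpretation_config()) {
  features <- as_tibble(features)
  if (nrow(features) == 0) {
    return(tibble(label = character(), effect_direction = character(),
                  evidence_tier = character(), strength = character(),
                  criteria_codes = character()))
  }
  out <- lapply(seq_len(nrow(features)), function(i)
    cascade_one(features[i, ], config))
  bind_rows(out)
}

cascade_one <- function(f, config) {
  codes <- character(0)
  result <- function(label, direction, tier, strength) {
    tibble(label = label, effect_direction = direction, evidence_tier = tier,
           strength = strength,
           criteria_codes = paste(codes, collapse = ";"))
  }
  unknown <- function() {
    tibble(label = "unknown", effect_direction = "none",
           evidence_tier = "none", strength = "none",
           criteria_codes = paste(codes, collapse = ";"))
  }
  tsg_like <- f$mechanism %in% c("tumor_suppressor", "dual")

  # pre-filter: assumed-neutral variants
  if (isTRUE(f$is_common)) {
    codes <- c(codes, "COMMON_POLYMORPHISM")
    return(result("functionally_neutral", "none", "A", "strong"))
  }
  if (f$consequence == "synonymous") {
    codes <- c(codes, "SILENT")
    return(result("functionally_neutral", "none", "B", "strong"))
  }

  # evidence A: curated assertions
  if (f$assertion_verdict == "functional") {
    codes <- c(codes, "KB_MATCH")
    dir <- f$assertion_direction
    if (is.na(dir) || dir == "pathogenicity_only") {
      dir <- if (f$mechanism == "oncogene") "gain_of_function" else "loss_of_function"
    }
    return(result("functionally_relevant", dir, "A", "very_strong"))
  }
  if (f$assertion_verdict == "neutral") {
    codes <- c(codes, "KB_MATCH")
    return(result("functionally_neutral", "none", "A", "very_strong"))
  }
  if (f$assertion_verdict == "conflicting") {
    codes <- c(codes, "CONFLICT")
  }

  # evidence B: bona fide biological assumptions (tumor suppressors only)
  if (tsg_like) {
    b_codes <- character(0)
    if (f$consequence == "splice_canonical") b_codes <- c(b_codes, "PVS1_SPLICE")
    if (f$consequence %in% TRUNCATING && isTRUE(f$nmd_predicted)) {
      b_codes <- c(b_codes, "PVS1_NMD")
    }
    if (length(b_codes) == 0 && f$consequence %in% TRUNCATING) {
      if (isTRUE(f$in_critical_region)) {
        b_codes <- c(b_codes, "PVS1S_CRITICAL_REGION")
      }
      if (!is.na(f$truncated_fraction) &&
          f$truncated_fraction > config$truncation_fraction_threshold) {
        b_codes <- c(b_codes, "PVS1S_TRUNC_GT10")
      }
    }
    if (length(b_codes)) {
      codes <- c(codes, b_codes)
      strength <- if (any(b_codes %in% c("PVS1_SPLICE", "PVS1_NMD")))
        "very_strong" else "strong"
      return(result("functionally_relevant", "loss_of_function", "B", strength))
    }
  }

  # evidence C: computational metrics (hotspot first, then CADD)
  if (isTRUE(f$hotspot_significant)) {
    codes <- c(codes, "HOTSPOT")
    dir <- switch(f$mechanism,
                  oncogene = "gain_of_function",
                  tumor_suppressor = "loss_of_function",
                  dual = "loss_of_function",
                  "none")
    return(result("functionally_relevant", dir, "C", "strong"))
  }
  if (f$consequence == "missense" && tsg_like && !is.na(f$phred_score)) {
    if (f$phred_score > config$cadd_high_threshold) {
      codes <- c(codes, "CADD_HIGH")
      return(result("functionally_relevant", "loss_of_function", "C", "strong"))
    }
    if (f$phred_score < config$cadd_low_threshold) {
      codes <- c(codes, "CADD_LOW")
      return(result("functionally_neutral", "none", "C", "strong"))
    }
  }
  unknown()
}

# ---- feature extraction ----------------------------------------------------

critical_regions_for <- function(gene, db, kb) {
  rec <- gene_record(db, gene)
  curated <- rec$critical_regions[[1]]
  regs <- list()
  if (!is.null(curated) && nrow(curated)) regs <- c(regs, list(curated))
  if (rec$mechanism %in% c("tumor_suppressor", "dual")) {
    regs <- c(regs, infer_critical_regions(gene, kb))
  }
  regs
}

in_region <- function(pos, regions) {
  if (is.na(pos) || length(regions) == 0) return(FALSE)
  any(vapply(regions, function(m)
    any(pos >= m[, 1] & pos <= m[, 2]), logical(1)))
}

extract_features_one <- function(v, db, kb, config, regions_cache) {
  gene <- v$gene_symbol
  st <- canonical_struct(db, gene)
  mech <- gene_record(db, gene)$mechanism
  agg <- aggregate_assertions(v, kb)
  truncating <- v$consequence %in% c(TRUNCATING, "splice_canonical")
  tf <- if (truncating) truncated_fraction_one(v, st, db) else NA_real_
  nmd <- if (!is.na(v$ptc_codon)) {
    predict_nmd_one(v$ptc_codon, v$ref, v$alt, v$pos, st, config)
  } else NA
  eff_codon <- if (!is.na(v$ptc_codon)) v$ptc_codon else v$fs_codon
  regions <- regions_cache[[gene]]
  s <- kb$scores[v$variant_key]
  phred <- if (length(s) == 1 && !is.na(s)) unname(s) else NA_real_
  feats <- tibble(
    assertion_verdict = agg$verdict,
    assertion_direction = agg$direction,
    consequence = v$consequence,
    nmd_predicted = nmd,
    in_critical_region = v$consequence %in% TRUNCATING &&
      in_region(eff_codon, regions),
    truncated_fraction = tf,
    hotspot_significant = hotspot_hit(v, kb, config),
    phred_score = phred,
    mechanism = mech,
    is_common = is_common_polymorphism(v, kb, config)
  )
  list(features = feats, records = agg$records)
}

#' Classify variants through the full evidence cascade
#'
#' @param variants tibble from [normalize_variants()].
#' @param db a [transcript_db()].
#' @param kb a `knowledge_db` from [load_resources()].
#' @param config an [interpretation_config()].
#' @return the input tibble with appended columns `label`, `effect_direction`,
#'   `evidence_tier`, `strength`, `criteria_codes`, `matched_sources`,
#'   `n_usable_assertions`, `assertion_conflict`.
#' @examples
#' \dontrun{
#' fx <- generate_fixture_bundle(n_patients = 2, seed = 1)
#' calls <- normalize_variants("BRCA1:c.5468-1G>A", fx$db) |>
#'   classify_variants(fx$db, fx$kb)
#' calls$label
#' }
#' @export
classify_variants <- function(variants, db, kb,
                              config = interpretation_config()) {
  genes <- unique(variants$gene_symbol)
  regions_cache <- stats::setNames(
    lapply(genes, critical_regions_for, db = db, kb = kb), genes)
  feats <- vector("list", nrow(variants))
  srcs <- character(nrow(variants))
  n_use <- integer(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    ex <- extract_features_one(variants[i, ], db, kb, config, regions_cache)
    feats[[i]] <- ex$features
    recs <- ex$records
    srcs[i] <- paste(unique(recs$source), collapse = ";")
    n_use[i] <- sum(recs$usable)
  }
  feats <- bind_rows(feats)
  res <- functional_cascade(feats, config)
  out <- bind_cols(variants, res)
  out$matched_sources <- srcs
  out$n_usable_assertions <- n_use
  out$assertion_conflict <- if (nrow(variants) > 0) {
    feats$assertion_verdict == "conflicting"
  } else logical(0)
  class(out) <- c("oncoboard_calls", class(out))
  out
}

#' Evidence-A classification for one variant
#'
#' @param v one-row normalized variant tibble.
#' @param db,kb,config see [classify_variants()].
#' @return one-row call tibble, or `NULL` when evidence A is inconclusive
#'   (no usable match, or conflicting usable matches).
#' @export
evidence_a <- function(v, db, kb, config = interpretation_config()) {
  agg <- aggregate_assertions(v, kb)
  if (!agg$verdict %in% c("functional", "neutral")) return(NULL)
  mech <- gene_record(db, v$gene_symbol)$mechanism
  f <- tibble(assertion_verdict = agg$verdict,
              assertion_direction = agg$direction,
              consequence = v$consequence, nmd_predicted = NA,
              in_critical_region = FALSE, truncated_fraction = NA_real_,
              hotspot_significant = FALSE, phred_score = NA_real_,
              mechanism = mech, is_common = FALSE)
  functional_cascade(f, config)
}

#' Evidence-B classification for one variant
#'
#' Applies the null-variant assumptions (canonical splice, NMD-triggering PTC,
#' critical-region truncation, >10% truncation) for tumor-suppressor genes.
#'
#' @param v one-row normalized variant tibble.
#' @param db a [transcript_db()].
#' @param regions list of protein-interval matrices (critical regions).
#' @param config an [interpretation_config()].
#' @return one-row call tibble or `NULL` when inconclusive.
#' @export
evidence_b <- function(v, db, regions = list(),
                       config = interpretation_config()) {
  st <- canonical_struct(db, v$gene_symbol)
  mech <- gene_record(db, v$gene_symbol)$mechanism
  if (!mech %in% c("tumor_suppressor", "dual")) return(NULL)
  truncating <- v$consequence %in% c(TRUNCATING, "splice_canonical")
  tf <- if (truncating) truncated_fraction_one(v, st, db) else NA_real_
  nmd <- if (!is.na(v$ptc_codon)) {
    predict_nmd_one(v$ptc_codon, v$ref, v$alt, v$pos, st, config)
  } else NA
  eff <- if (!is.na(v$ptc_codon)) v$ptc_codon else v$fs_codon
  f <- tibble(assertion_verdict = "none", assertion_direction = NA_character_,
              consequence = v$consequence, nmd_predicted = nmd,
              in_critical_region = v$consequence %in% TRUNCATING &&
                in_region(eff, regions),
              truncated_fraction = tf, hotspot_significant = FALSE,
              phred_score = NA_real_, mechanism = mech, is_common = FALSE)
  res <- functional_cascade(f, config)
  if (res$evidence_tier == "B") res else NULL
}

#' Evidence-C classification for one variant
#'
#' Hotspot membership first, then CADD Phred thresholds for missense variants
#' in tumor suppressors.
#'
#' @inheritParams evidence_b
#' @param kb a `knowledge_db`.
#' @return one-row call tibble or `NULL` when the variant stays unknown.
#' @export
evidence_c <- function(v, db, kb, config = interpretation_config()) {
  mech <- gene_record(db, v$gene_symbol)$mechanism
  s <- kb$scores[v$variant_key]
  f <- tibble(assertion_verdict = "none", assertion_direction = NA_character_,
              consequence = v$consequence, nmd_predicted = NA,
              in_critical_region = FALSE, truncated_fraction = NA_real_,
              hotspot_significant = hotspot_hit(v, kb, config),
              phred_score = if (length(s) && !is.na(s)) unname(s) else NA_real_,
              mechanism = mech, is_common = FALSE)
  res <- functional_cascade(f, config)
  if (res$evidence_tier == "C") res else NULL
}
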