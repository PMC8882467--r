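# Independent oracles shared by the unit and acceptance suites.

CONSEQUENCES <- c("missense", "nonsense", "frameshift", "inframe_insertion",
                  "inframe_deletion", "synonymous", "splice_canonical",
                  "splice_region", "other")

# Flat decision table for the classification cascade. Written as one literal
# rule list evaluated top to bottom, deliberately sharing no code with the
# implementation.
oracle_decide <- function(f) {
  tsg <- f$mechanism %in% c("tumor_suppressor", "dual")
  trunc <- f$consequence %in% c("nonsense", "frameshift")
  if (isTRUE(f$is_common)) {
    return(c("functionally_neutral", "A", "strong"))
  }
  if (f$consequence == "synonymous") {
    return(c("functionally_neutral", "B", "strong"))
  }
  if (f$assertion_verdict == "functional") {
    return(c("functionally_relevant", "A", "very_strong"))
  }
  if (f$assertion_verdict == "neutral") {
    return(c("functionally_neutral", "A", "very_strong"))
  }
  if (tsg && f$consequence == "splice_canonical") {
    return(c("functionally_relevant", "B", "very_strong"))
  }
  if (tsg && trunc && isTRUE(f$nmd_predicted)) {
    return(c("functionally_relevant", "B", "very_strong"))
  }
  if (tsg && trunc && isTRUE(f$in_critical_region)) {
    return(c("functionally_relevant", "B", "strong"))
  }
  if (tsg && trunc && !is.na(f$truncated_fraction) &&
      f$truncated_fraction > 0.10) {
    return(c("functionally_relevant", "B", "strong"))
  }
  if (isTRUE(f$hotspot_significant)) {
    return(c("functionally_relevant", "C", "strong"))
  }
  if (tsg && f$consequence == "missense" && !is.na(f$phred_score) &&
      f$phred_score > 30) {
    return(c("functionally_relevant", "C", "strong"))
  }
  if (tsg && f$consequence == "missense" && !is.na(f$phred_score) &&
      f$phred_score < 10) {
    return(c("functionally_neutral", "C", "strong"))
  }
  c("unknown", "none", "none")
}

# The full (filtered) feature grid for the cascade.
cascade_grid <- function() {
  g <- expand.grid(
    assertion_verdict = c("functional", "neutral", "conflicting", "none"),
    consequence = CONSEQUENCES,
    nmd_predicted = c(TRUE, FALSE, NA),
    in_critical_region = c(TRUE, FALSE),
    truncated_fraction = c(0.05, 0.5),
    hotspot_significant = c(TRUE, FALSE),
    phred_score = c(8, 20, 35, NA),
    mechanism = c("tumor_suppressor", "oncogene"),
    is_common = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  trunc <- g$consequence %in% c("nonsense", "frameshift")
  keep <- (trunc & !is.na(g$nmd_predicted)) | (!trunc & is.na(g$nmd_predicted))
  g <- g[keep, ]
  g$in_critical_region[!g$consequence %in% c("nonsense", "frameshift")] <- FALSE
  g$truncated_fraction[!g$consequence %in%
                         c("nonsense", "frameshift", "splice_canonical")] <- NA
  g <- unique(g)
  g$assertion_direction <- NA_character_
  g
}

# Brute-force NMD positional oracle, recomputed from the raw exon coordinate
# vectors of one transcripts-table row.
nmd_positional_oracle <- function(row, ptc) {
  es <- row$exon_starts[[1]]; ee <- row$exon_ends[[1]]
  widths <- ee - es + 1L
  if (row$strand == "-") { es <- rev(es); ee <- rev(ee); widths <- rev(widths) }
  if (length(widths) == 1) return(FALSE)
  last_jn <- sum(widths[-length(widths)])
  first_cds_g <- if (row$strand == "+") row$cds_start else row$cds_end
  k <- which(first_cds_g >= pmin(es, ee) & first_cds_g <= pmax(es, ee))[1]
  within <- if (row$strand == "+") first_cds_g - es[k] else ee[k] - first_cds_g
  cds_t_start <- sum(widths[seq_len(k - 1)]) + within + 1L
  ptc_first <- cds_t_start + (ptc - 1L) * 3L
  (last_jn - ptc_first) > 50
}
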