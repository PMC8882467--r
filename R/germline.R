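# Germline counseling alerts.
#
# Alerts are restricted to a configured gene panel and to loss-of-function
# calls supported by curated evidence or bona fide biological assumptions
# (tiers A/B) — computational-only calls (tier C) never alert. Genes marked
# biallelic_only (MUTYH) alert only for homozygous or compound-heterozygous
# carriers.

#' Issue germline genetic-counseling alerts
#'
#' @param profile a `tumor_profile`; its `calls` must carry `origin`,
#'   `zygosity` and `vaf` columns.
#' @param panel germline panel tibble (`gene_symbol`, `biallelic_only`), e.g.
#'   `kb$germline_panel`.
#' @param config an [interpretation_config()].
#' @return tibble of alerts with an `origin_basis` column:
#'   `"paired"` when germline origin was established by paired calling,
#'   `"inferred_vaf"` when inferred from the tumor-only VAF window,
#'   `"indeterminate"` when the VAF was missing in tumor-only mode.
#' @export
issue_germline_alerts <- function(profile, panel,
                                  config = interpretation_config()) {
  calls <- profile$calls
  empty <- tibble(patient_id = character(), gene_symbol = character(),
                  variant_key = character(), protein_change = character(),
                  zygosity = character(), evidence_tier = character(),
                  origin_basis = character())
  if (is.null(calls) || nrow(calls) == 0) return(empty)
  paired <- isTRUE(profile$paired)
  germ <- potential_germline_by_vaf(calls, paired, config)
  basis <- if (paired) {
    if_else(germ, "paired", NA_character_)
  } else {
    dplyr::case_when(is.na(germ) ~ "indeterminate",
                     germ ~ "inferred_vaf",
                     TRUE ~ NA_character_)
  }
  cand <- which(!is.na(basis))
  if (length(cand) == 0) return(empty)

  eligible <- vapply(cand, function(i) {
    v <- calls[i, ]
    v$gene_symbol %in% panel$gene_symbol &&
      v$label == "functionally_relevant" &&
      v$effect_direction == "loss_of_function" &&
      v$evidence_tier %in% c("A", "B")
  }, logical(1))
  cand <- cand[eligible]
  if (length(cand) == 0) return(empty)

  # compound heterozygosity: >= 2 distinct eligible germline variants in the
  # same gene upgrade each other's zygosity
  genes <- calls$gene_symbol[cand]
  zyg <- calls$zygosity[cand]
  per_gene <- table(genes)
  zyg <- vapply(seq_along(cand), function(k) {
    z <- zyg[k]
    if (z %in% c("heterozygous", "unknown") && per_gene[[genes[k]]] >= 2) {
      "compound_heterozygous"
    } else z
  }, character(1))

  keep_row <- vapply(seq_along(cand), function(k) {
    biall <- panel$biallelic_only[panel$gene_symbol == genes[k]][1]
    !isTRUE(biall) || zyg[k] %in% c("homozygous", "compound_heterozygous")
  }, logical(1))
  cand <- cand[keep_row]; zyg <- zyg[keep_row]
  if (length(cand) == 0) return(empty)

  tibble(
    patient_id = profile$patient_id %||% NA_character_,
    gene_symbol = calls$gene_symbol[cand],
    variant_key = calls$variant_key[cand],
    protein_change = calls$protein_change[cand],
    zygosity = zyg,
    evidence_tier = calls$evidence_tier[cand],
    origin_basis = basis[cand]
  )
}
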