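# broom-style tidiers and ggplot2 autoplot methods for the engine's results.

#' Tidy a set of functional calls
#'
#' @param x an `oncoboard_calls` tibble.
#' @param ... unused.
#' @return a plain tibble with the key interpretation columns.
#' @export
tidy.oncoboard_calls <- function(x, ...) {
  as_tibble(x)[, intersect(
    c("gene_symbol", "variant_key", "cdna_change", "protein_change",
      "consequence", "label", "effect_direction", "evidence_tier",
      "strength", "criteria_codes"), names(x))]
}

#' Summarize a set of functional calls
#'
#' @param x an `oncoboard_calls` tibble.
#' @param ... unused.
#' @return one-row tibble with label counts and the fraction of calls per
#'   evidence tier.
#' @export
glance.oncoboard_calls <- function(x, ...) {
  tibble(
    n_variants = nrow(x),
    n_relevant = sum(x$label == "functionally_relevant"),
    n_neutral = sum(x$label == "functionally_neutral"),
    n_unknown = sum(x$label == "unknown"),
    n_tier_a = sum(x$evidence_tier == "A"),
    n_tier_b = sum(x$evidence_tier == "B"),
    n_tier_c = sum(x$evidence_tier == "C"),
    n_conflicts = sum(x$assertion_conflict %||% FALSE)
  )
}

#' Tidy a patient report into one variant table
#'
#' @param x a `patient_report`.
#' @param ... unused.
#' @return tibble of all variants with their table membership.
#' @export
tidy.patient_report <- function(x, ...) {
  bind_rows(lapply(names(x$tables), function(nm) {
    t <- x$tables[[nm]]
    if (nrow(t) == 0) return(NULL)
    t$report_table <- nm
    t
  })) %||% tibble()
}

#' Summarize a patient report
#'
#' @param x a `patient_report`.
#' @param ... unused.
#' @return one-row tibble of headline counts.
#' @export
glance.patient_report <- function(x, ...) {
  tibble(
    patient_id = x$header$patient_id,
    cancer_type = x$header$cancer_type,
    n_variants = x$counts$n_variants,
    n_relevant = x$counts$n_relevant,
    n_unknown = x$counts$n_unknown,
    n_neutral = x$counts$n_neutral,
    n_biomarker_matches = nrow(x$biomarker_matches),
    n_trial_recommendations = nrow(x$trial_recommendations),
    n_germline_alerts = nrow(x$germline_alerts)
  )
}

#' Plot the functional classification of a call set
#'
#' Stacked bar of labels colored by the evidence tier that produced each call,
#' mirroring the usual cohort-level summary of a classification cascade.
#'
#' @param object an `oncoboard_calls` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.oncoboard_calls <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(label = factor(.data$label,
                          c("functionally_relevant", "unknown",
                            "functionally_neutral")),
           tier = factor(.data$evidence_tier, c("A", "B", "C", "none")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, fill = .data$tier)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "Evidence") +
    ggplot2::labs(x = NULL, y = "Variants",
                  title = "Functional classification by evidence tier") +
    ggplot2::theme_minimal()
}

#' Plot ESCAT tiers of a patient's biomarker matches
#'
#' @param object tibble from [assign_escat()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_escat <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(escat_tier = factor(.data$escat_tier, c("I", "II", "III", "IV")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$escat_tier,
                                  fill = .data$type_relation)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_brewer(palette = "Set1", name = "Cancer-type match") +
    ggplot2::labs(x = "ESCAT tier", y = "Biomarker matches") +
    ggplot2::theme_minimal()
}
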