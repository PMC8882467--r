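#' Interpretation configuration
#'
#' All tunable thresholds of the interpretation engine live in one list so that
#' every rule is driven by configuration rather than constants buried in code.
#'
#' Defaults follow the published operating points of the classification rules:
#' CADD Phred thresholds of 30 (functional) and 10 (neutral) applied with
#' strict inequalities, hotspot significance at p < 0.05 (strict), the
#' "more than 10%" truncated-protein rule (strict), a 1% maximum population
#' allele frequency for calling a common polymorphism, and source-native
#' evidence-rating minimums of 2 stars (ClinVar-style) and 3 stars
#' (CIViC-style).
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A list of class `oncoboard_config`.
#' @examples
#' cfg <- interpretation_config(hotspot_alpha = 0.01)
#' cfg$cadd_high_threshold
#' @export
interpretation_config <- function(...) {
  cfg <- list(
    cadd_high_threshold = 30,
    cadd_low_threshold = 10,
    hotspot_alpha = 0.05,
    truncation_fraction_threshold = 0.10,
    common_af_threshold = 0.01,
    nmd_distance_nt = 50,
    rating_minimums = c(ClinVar = 2, CIViC = 3, OncoKB = 1, CGI = 1,
                        BRCAExchange = 1),
    germline_vaf_windows = list(c(0.40, 0.60), c(0.90, 1.0)),
    tmb_cutoffs = c(intermediate = 6, high = 20),
    trial_evidence_floor = c("A", "B"),
    escat_matrix = default_escat_matrix(),
    vaf_field = "AF",
    forbidden_header_fields = c("patient_name", "name", "dob", "date_of_birth",
                                "ssn", "mrn")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    abort(paste0("unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "oncoboard_config")
}

validate_config <- function(cfg) {
  if (!(cfg$cadd_low_threshold < cfg$cadd_high_threshold)) {
    abort("cadd_low_threshold must be below cadd_high_threshold")
  }
  fr <- c(cfg$hotspot_alpha, cfg$truncation_fraction_threshold,
          cfg$common_af_threshold)
  if (any(fr <= 0 | fr > 1)) abort("fraction thresholds must lie in (0, 1]")
  for (w in cfg$germline_vaf_windows) {
    if (length(w) != 2 || w[1] > w[2] || any(w < 0) || any(w > 1)) {
      abort("each germline VAF window must be an ordered pair in [0, 1]")
    }
  }
  invisible(cfg)
}

#' Default ESCAT tier matrix
#'
#' Maps (clinical evidence level, cancer-type relation) to an ESCAT tier.
#' Tier I is reserved for approved/guideline biomarkers matching the patient's
#' tumor type or a subtype of it; investigational clinical evidence in the
#' matching disease gives tier II; clinical evidence observed in other tumor
#' types, retrospective series and case reports give tier III; preclinical
#' evidence gives tier IV regardless of disease match.
#'
#' @return matrix of tier labels, rows = evidence levels, columns = relations.
#' @export
default_escat_matrix <- function() {
  m <- rbind(
    approved_or_guideline = c("I", "I", "III"),
    clinical_trial = c("II", "II", "III"),
    retrospective_clinical = c("III", "III", "III"),
    case_report = c("III", "III", "III"),
    preclinical = c("IV", "IV", "IV")
  )
  colnames(m) <- c("same", "patient_is_subtype", "other")
  m
}

#' Read a run configuration file
#'
#' A run configuration is a YAML file with a `resources:` block of fixture
#' paths (relative paths resolved against the file's directory) and an
#' optional `thresholds:` block overriding [interpretation_config()] keys.
#'
#' @param path path to the YAML file.
#' @return list with elements `paths` (named character) and `config`
#'   (an `oncoboard_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$resources)) abort("run config lacks a 'resources:' block")
  base <- dirname(normalizePath(path))
  paths <- vapply(raw$resources, function(p) {
    if (startsWith(p, "/")) p else file.path(base, p)
  }, character(1))
  overrides <- raw$thresholds %||% list()
  if (!is.null(overrides$rating_minimums)) {
    overrides$rating_minimums <- unlist(overrides$rating_minimums)
  }
  if (!is.null(overrides$germline_vaf_windows)) {
    overrides$germline_vaf_windows <-
      lapply(overrides$germline_vaf_windows, as.numeric)
  }
  if (!is.null(overrides$tmb_cutoffs)) {
    overrides$tmb_cutoffs <- unlist(overrides$tmb_cutoffs)
  }
  if (!is.null(overrides$escat_matrix)) {
    em <- overrides$escat_matrix
    m <- do.call(rbind, lapply(em, unlist))
    overrides$escat_matrix <- m
  }
  cfg <- do.call(interpretation_config, overrides)
  list(paths = paths, config = cfg)
}

#' Categorize a tumor mutational burden value
#'
#' @param tmb numeric TMB in mutations per megabase.
#' @param config an [interpretation_config()].
#' @return character: `"low"`, `"intermediate"` or `"high"`.
#' @export
tmb_category <- function(tmb, config = interpretation_config()) {
  cut <- config$tmb_cutoffs
  dplyr::case_when(
    is.na(tmb) ~ NA_character_,
    tmb >= cut[["high"]] ~ "high",
    tmb >= cut[["intermediate"]] ~ "intermediate",
    TRUE ~ "low"
  )
}
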