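# Patient-level inputs: a VCF 4.2 of variants plus a YAML side file with the
# pseudonymous id, cancer type, assay metadata, copy-number events and
# signature values.

integrity_abort <- function(msg) abort(msg, class = "oncoboard_integrity")

validate_vcf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !startsWith(lines[1], "##fileformat=VCF")) {
    integrity_abort(paste0(path, ": not a VCF file (missing ##fileformat header)"))
  }
  header_i <- which(startsWith(lines, "#CHROM"))
  if (length(header_i) != 1) {
    integrity_abort(paste0(path, ": missing #CHROM header line"))
  }
  for (i in seq_along(lines)) {
    if (i <= header_i || !nzchar(lines[i])) next
    nfield <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nfield < 8) {
      integrity_abort(paste0(path, " line ", i,
                             ": malformed VCF record (", nfield, " fields)"))
    }
  }
  invisible(lines)
}

vcf_info_field <- function(info, key) {
  m <- str_match(info, paste0("(?:^|;)", key, "=([^;]+)"))
  m[, 2]
}

#' Read a patient VCF into a raw variant table
#'
#' Tumor-only and paired VCFs are supported; the VAF is taken from the INFO
#' field named by `config$vaf_field` (default `AF`), the somatic/germline
#' origin from an `ORIGIN` INFO key when present (paired calling), and
#' zygosity from the first sample's `GT`.
#'
#' @param path VCF file path.
#' @param db a [transcript_db()] (used for normalization downstream).
#' @param config an [interpretation_config()].
#' @return tibble with columns `chrom`, `pos`, `ref`, `alt`, `gene_symbol`,
#'   `vaf`, `origin`, `zygosity`.
#' @export
read_variants_vcf <- function(path, db, config = interpretation_config()) {
  validate_vcf_lines(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcf@fix
  if (is.null(fx) || nrow(fx) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), gene_symbol = character(),
                  vaf = double(), origin = character(),
                  zygosity = character()))
  }
  info <- fx[, "INFO"]
  vaf <- suppressWarnings(as.numeric(vcf_info_field(info, config$vaf_field)))
  origin <- vcf_info_field(info, "ORIGIN")
  origin[is.na(origin)] <- "unknown"
  gene <- vcf_info_field(info, "GENE")
  zyg <- rep("unknown", nrow(fx))
  if (ncol(vcf@gt) >= 2) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    g <- gt[, 1]
    zyg <- dplyr::case_when(
      g %in% c("1/1", "1|1") ~ "homozygous",
      g %in% c("0/1", "1/0", "0|1", "1|0") ~ "heterozygous",
      TRUE ~ "unknown"
    )
  }
  tibble(
    chrom = unname(fx[, "CHROM"]), pos = as.integer(fx[, "POS"]),
    ref = unname(fx[, "REF"]), alt = unname(fx[, "ALT"]),
    gene_symbol = unname(gene), vaf = unname(vaf),
    origin = unname(origin), zygosity = unname(zyg)
  )
}

#' Read a free-text variant list
#'
#' One `GENE:expression` per line; blank lines and `#` comments ignored.
#'
#' @param path text file path.
#' @return character vector of expressions (ready for [normalize_variants()]).
#' @export
read_variants_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a patient profile side file
#'
#' @param path YAML file with keys `patient_id`, `cancer_type`, `paired`,
#'   optional `assay`, `copy_number` (list of `{gene, type}`), `signatures`
#'   (name -> value map). Inputs containing identifier-like fields
#'   (configured in `forbidden_header_fields`) are refused: deidentification
#'   is the caller's responsibility.
#' @param config an [interpretation_config()].
#' @return list with the profile metadata.
#' @export
read_patient_profile <- function(path, config = interpretation_config()) {
  if (!file.exists(path)) abort(paste0("profile not found: ", path))
  y <- yaml::read_yaml(path)
  banned <- intersect(tolower(names(y)), config$forbidden_header_fields)
  if (length(banned)) {
    abort(paste0("profile ", path, " contains identifier-like field(s): ",
                 paste(banned, collapse = ", "),
                 " — inputs must be deidentified upstream"))
  }
  for (fld in c("patient_id", "cancer_type", "paired")) {
    if (is.null(y[[fld]])) {
      abort(paste0("profile ", path, " lacks required field '", fld, "'"))
    }
  }
  cn <- if (length(y$copy_number)) {
    bind_rows(lapply(y$copy_number, function(e)
      tibble(gene_symbol = e$gene, type = e$type)))
  } else {
    tibble(gene_symbol = character(), type = character())
  }
  list(patient_id = y$patient_id, cancer_type = y$cancer_type,
       paired = isTRUE(y$paired), assay = y$assay %||% list(),
       copy_number = cn, signatures = y$signatures %||% list())
}

#' Construct a tumor profile
#'
#' @param patient_id pseudonymous identifier.
#' @param cancer_type ontology term for the tumor type.
#' @param calls classified variants ([classify_variants()] output).
#' @param copy_number tibble (`gene_symbol`, `type`).
#' @param signatures named list of signature values (e.g. `TMB`).
#' @param paired logical: paired tumor/normal calling?
#' @return list of class `tumor_profile`.
#' @export
tumor_profile <- function(patient_id, cancer_type, calls,
                          copy_number = NULL, signatures = list(),
                          paired = FALSE) {
  structure(
    list(patient_id = patient_id, cancer_type = cancer_type, calls = calls,
         copy_number = copy_number %||%
           tibble(gene_symbol = character(), type = character()),
         signatures = signatures, paired = paired),
    class = "tumor_profile"
  )
}
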