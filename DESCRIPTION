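Package: oncoboard
Title: Rule-Based Clinical Interpretation of Cancer Gene Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale engine for molecular-tumor-board style interpretation
    of somatic and germline cancer gene variants. Variants from VCF or HGVS-style
    text are normalized against lightweight transcript models and classified on
    an allele-centric functional axis through a three-tier evidence cascade:
    curated knowledge-base assertions, bona fide biological assumptions for
    tumor-suppressor null variants (ACMG PVS1-style rules with nonsense-mediated
    decay prediction), and computational metrics (mutation hotspots and CADD
    Phred deleteriousness scores). Functionally relevant variants are then
    matched to cancer biomarkers with cancer-type ontology awareness and tiered
    on the ESMO/ESCAT actionability scale, evaluated against boolean clinical
    trial eligibility rules, and screened against a germline counseling panel.
    Deterministic synthetic fixture generators emulate every external resource
    so the full pipeline runs and is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
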