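# Variant normalization, consequence calling, truncation arithmetic, NMD.

test_that("HGVS text, genomic HGVS and VCF records converge to one representation", {
  fx <- fx_bundle()
  db <- fx$db
  # the same BRAF allele through three syntaxes
  a <- normalize_variants("BRAF:c.1799T>A", db)
  b <- normalize_variants(paste0("BRAF:", sub("^BRAF:", "", a$variant_key)), db)
  vcf_style <- tibble::tibble(chrom = a$chrom, pos = a$pos, ref = a$ref,
                              alt = a$alt, gene_symbol = "BRAF")
  c <- normalize_variants(vcf_style, db)
  cols <- c("chrom", "pos", "ref", "alt", "variant_key", "cdna_change",
            "protein_change", "consequence")
  expect_identical(a[cols], b[cols])
  expect_identical(a[cols], c[cols])
  # protein syntax resolves to the same allele
  d <- normalize_variants("BRAF:p.V600E", db)
  expect_identical(a$variant_key, d$variant_key)
})

test_that("normalization is idempotent and converges across syntaxes for random variants", {
  fx <- fx_bundle()
  db <- fx$db
  genes <- c("BRCA2", "EGFR", "MLH1", "ATM", "TP53")
  set.seed(42)
  n_checked <- 0
  for (rep in 1:60) {
    g <- sample(genes, 1)
    st <- oncoboard:::canonical_struct(db, g)
    k <- sample(seq_len(st$protein_length - 2), 1)
    for (target in c("missense", "stop")) {
      e <- oncoboard:::codon_sub_expr(db, g, k, target)
      if (is.na(e)) next
      v1 <- normalize_variants(paste0(g, ":", e), db)
      # re-feed its own canonical forms
      v2 <- normalize_variants(paste0(g, ":",
                                      sub(paste0("^", g, ":"), "", v1$variant_key)), db)
      v3 <- normalize_variants(paste0(g, ":", v1$cdna_change), db)
      v4 <- normalize_variants(
        tibble::tibble(chrom = v1$chrom, pos = v1$pos, ref = v1$ref,
                       alt = v1$alt, gene_symbol = g), db)
      cols <- c("pos", "ref", "alt", "variant_key", "cdna_change",
                "protein_change", "consequence")
      expect_identical(v1[cols], v2[cols])
      expect_identical(v1[cols], v3[cols])
      expect_identical(v1[cols], v4[cols])
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 60)
})

test_that("an insertion placed anywhere in a homopolymer normalizes identically", {
  db <- make_toy_db()
  # the toy 5' UTR is an 11-C homopolymer on the genome (exon 1 start);
  # inserting one C at every possible position must left-align identically
  st <- oncoboard:::canonical_struct(db, "TSG1")
  run_start <- st$exons$gstart[1]          # first of 11 consecutive C
  keys <- vapply(0:10, function(off) {
    v <- normalize_variants(
      tibble::tibble(chrom = "ctg_toy", pos = run_start + off,
                     ref = substr(db$sequences[["ctg_toy"]],
                                  run_start + off, run_start + off),
                     alt = paste0(substr(db$sequences[["ctg_toy"]],
                                         run_start + off, run_start + off), "C"),
                     gene_symbol = "TSG1"), db)
    v$variant_key
  }, character(1))
  expect_length(unique(keys), 1)
})

test_that("unparseable syntax and unknown genes are rejected with the offending token", {
  fx <- fx_bundle()
  expect_error(normalize_variants("BRAF:q.12X", fx$db), "q\\.12X")
  expect_error(normalize_variants("NOSUCHGENE:c.1A>T", fx$db), "NOSUCHGENE")
  expect_error(normalize_variants("BRAF:c.99999A>T", fx$db), "outside")
})

test_that("consequence calling covers nonsense, splice and in-frame deletion cases", {
  db <- make_toy_db()
  # immediate stop at codon 10 of the 100-aa toy protein
  v <- normalize_variants(toy_stop_expr(10), db)
  expect_equal(v$consequence, "nonsense")
  expect_equal(v$ptc_codon, 10L)
  expect_equal(v$protein_change, "p.E10*")
  # intronic -1 acceptor position
  st <- oncoboard:::canonical_struct(db, "TSG1")
  acc <- st$exons$gstart[2] - 1L
  ref <- substr(db$sequences[["ctg_toy"]], acc, acc)
  v2 <- normalize_variants(
    tibble::tibble(chrom = "ctg_toy", pos = acc, ref = ref,
                   alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                   gene_symbol = "TSG1"), db)
  expect_equal(v2$consequence, "splice_canonical")
  # EGFR-like in-frame deletion in exon 19 of the synthetic model
  fx <- fx_bundle()
  v3 <- normalize_variants("EGFR:c.2236_2250del", fx$db)
  expect_equal(v3$consequence, "inframe_deletion")
  expect_equal(v3$exon_number, 19L)
})

test_that("splice_region (intronic 3-8 nt) is distinguished from canonical sites", {
  db <- make_toy_db()
  st <- oncoboard:::canonical_struct(db, "TSG1")
  probe <- function(offset) {
    pos <- st$exons$gend[1] + offset
    ref <- substr(db$sequences[["ctg_toy"]], pos, pos)
    normalize_variants(
      tibble::tibble(chrom = "ctg_toy", pos = pos, ref = ref,
                     alt = setdiff(c("A", "C", "G", "T"), ref)[1],
                     gene_symbol = "TSG1"), db)$consequence
  }
  expect_equal(probe(1L), "splice_canonical")
  expect_equal(probe(2L), "splice_canonical")
  expect_equal(probe(3L), "splice_region")
  expect_equal(probe(8L), "splice_region")
  expect_equal(probe(20L), "other")
})

test_that("truncated_fraction matches hand-computed values and is monotone", {
  db <- make_toy_db()
  tf <- function(k) truncated_fraction(normalize_variants(toy_stop_expr(k), db), db)
  expect_equal(tf(1), 1.0)
  expect_equal(tf(91), 0.10)
  expect_equal(tf(51), 0.50)
  vals <- vapply(seq(1, 100, by = 7), tf, numeric(1))
  expect_true(all(diff(vals) <= 0))
  expect_true(all(vals >= 0 & vals <= 1))
  # non-truncating input is rejected
  miss <- normalize_variants("TSG1:c.2A>C", db)   # GAA -> GCA missense
  expect_equal(miss$consequence, "missense")
  expect_error(truncated_fraction(miss, db), "truncating")
})

test_that("NMD prediction follows the 50-nt last-junction rule", {
  db <- make_toy_db()
  nmd <- function(k) predict_nmd_trigger(normalize_variants(toy_stop_expr(k), db), db)
  expect_true(nmd(10))     # far upstream of the last junction
  expect_false(nmd(91))    # last-exon PTC escapes
  # PTC first base 60 nt upstream of the junction triggers; 30 nt does not
  expect_true(nmd(57))     # distance 60
  expect_false(nmd(67))    # distance 30
})

test_that("NMD agrees with a brute-force positional oracle on random synthetic pairs", {
  fx <- fx_bundle()
  db <- fx$db
  cfg <- interpretation_config()
  set.seed(7)
  tr <- db$transcripts
  n <- 0
  for (i in 1:1100) {
    row <- tr[sample(nrow(tr), 1), ]
    st <- oncoboard:::tx_struct(db, row$transcript_id)
    ptc <- sample(seq_len(row$protein_length), 1)
    got <- oncoboard:::predict_nmd_one(ptc, "A", "T",
                                       oncoboard:::t2g(st, st$cds_t_start),
                                       st, cfg)
    # oracle: recompute everything from the raw exon coordinate vectors
    es <- row$exon_starts[[1]]; ee <- row$exon_ends[[1]]
    widths <- ee - es + 1L
    if (row$strand == "-") { es <- rev(es); ee <- rev(ee); widths <- rev(widths) }
    want <- if (length(widths) == 1) FALSE else {
      last_jn <- sum(widths[-length(widths)])
      # transcript offset of the first CDS base, recomputed from scratch
      first_cds_g <- if (row$strand == "+") row$cds_start else row$cds_end
      k <- which(first_cds_g >= pmin(es, ee) & first_cds_g <= pmax(es, ee))[1]
      within <- if (row$strand == "+") first_cds_g - es[k] else ee[k] - first_cds_g
      cds_t_start <- sum(widths[seq_len(k - 1)]) + within + 1L
      ptc_first <- cds_t_start + (ptc - 1L) * 3L
      (last_jn - ptc_first) > 50
    }
    expect_identical(got, want)
    n <- n + 1
  }
  expect_gte(n, 1000)
})

test_that("tumor-only germline plausibility uses the configured VAF windows", {
  fx <- fx_bundle()
  v <- normalize_variants(c("BRCA1:c.5468-1G>A", "BRAF:p.V600E",
                            "KRAS:c.35G>A"), fx$db)
  v$vaf <- c(0.12, 0.48, NA)
  v$origin <- c("germline", "unknown", "unknown")
  expect_equal(potential_germline_by_vaf(v, paired = TRUE),
               c(TRUE, FALSE, FALSE))
  expect_equal(potential_germline_by_vaf(v, paired = FALSE),
               c(FALSE, TRUE, NA))
  expect_true(potential_germline_by_vaf(v[2, ], paired = FALSE,
    config = interpretation_config(germline_vaf_windows = list(c(0.1, 0.2)))) ==
      FALSE)
})
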