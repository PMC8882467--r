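# Deterministic synthetic gene-model generator.
#
# Sequences are arbitrary but codon-consistent: CDSs are built from non-stop
# codons with a single terminal stop, introns carry GT..AG dinucleotides, and
# a handful of anchor genes reproduce structural features needed by the
# classification rules (a junction at a known cDNA position, an exon spanning
# a known cDNA window, long NMD-escaping last exons, fixed codons at famous
# residues). Everything is a pure function of the seed.

NON_STOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

anchor_gene_specs <- function() {
  tibble::tribble(
    ~gene, ~mechanism, ~n_exons, ~protein_length, ~strand, ~special,
    "BRCA1",  "tumor_suppressor", 22, 1863, "-", "brca1_junction",
    "BRCA2",  "tumor_suppressor", 26, 3418, "+", NA,
    "EGFR",   "oncogene",         28, 1210, "+", "egfr_exon19",
    "FLT3",   "oncogene",         24,  993, "-", NA,
    "KIT",    "oncogene",         21,  976, "+", "kit_codon572",
    "BRAF",   "oncogene",         18,  766, "-", "braf_codon600",
    "KRAS",   "oncogene",          5,  189, "-", "kras_codon12",
    "TP53",   "tumor_suppressor", 11,  393, "-", NA,
    "PTEN",   "tumor_suppressor",  9,  403, "+", "long_last_exon",
    "MLH1",   "tumor_suppressor", 19,  756, "+", NA,
    "MSH2",   "tumor_suppressor", 16,  934, "+", NA,
    "MSH6",   "tumor_suppressor", 10, 1360, "+", NA,
    "PMS2",   "tumor_suppressor", 15,  862, "-", NA,
    "POLE",   "dual",             20, 2286, "-", NA,
    "POLD1",  "dual",             15, 1107, "+", NA,
    "MUTYH",  "tumor_suppressor", 16,  546, "-", NA,
    "PALB2",  "tumor_suppressor", 13, 1186, "-", NA,
    "ATM",    "tumor_suppressor", 20, 3056, "+", NA,
    "CHEK2",  "tumor_suppressor", 14,  543, "+", NA,
    "RAD51C", "tumor_suppressor",  9,  376, "+", NA,
    "BRIP1",  "tumor_suppressor", 19, 1249, "-", NA,
    "APC",    "tumor_suppressor", 15, 2843, "+", "long_last_exon",
    "CD274",  "oncogene",          7,  290, "+", NA,
    "ERBB2",  "oncogene",         20, 1255, "+", NA,
    "FGFR3",  "oncogene",         18,  806, "+", NA,
    "SSX1T",  "tumor_suppressor",  1,  450, "+", NA
  )
}

fixed_codons_for <- function(gene) {
  switch(gene,
    KIT = c("572" = "GAT"),    # p.D572
    BRAF = c("600" = "GTG"),   # p.V600
    KRAS = c("12" = "GGT"),    # p.G12
    NULL
  )
}

# interior transcript cut points (exon boundaries): cut after position x
make_cuts <- function(tx_len, n_exons, forced = integer(0),
                      last_cut = NA_integer_, window = NULL) {
  if (n_exons == 1) return(integer(0))
  n_cuts <- n_exons - 1L
  if (!is.null(window)) {
    # window = c(exon_index, t_start, t_end): that exon spans [t_start, t_end]
    k <- window[1]; t1 <- window[2]; t2 <- window[3]
    before <- round(seq(40, t1 - 40, length.out = k - 1))
    after_n <- n_cuts - (k - 1) - 1L
    after <- if (after_n > 0) round(seq(t2 + 40, tx_len - 40, length.out = after_n)) else integer(0)
    cuts <- sort(unique(c(before[-length(before)], t1 - 1L, t2, after)))
    # `before` had k-1 points ending near t1; replace its last with t1-1
    cuts <- sort(unique(c(round(seq(40, t1 - 80, length.out = k - 2)),
                          t1 - 1L, t2, after)))
    return(as.integer(cuts))
  }
  if (!is.na(last_cut)) {
    first <- round(seq(40, last_cut - 40, length.out = n_cuts - 1))
    return(as.integer(sort(unique(c(first, last_cut)))))
  }
  cuts <- round(seq(1, tx_len - 1, length.out = n_cuts + 2))[2:(n_cuts + 1)]
  for (f in forced) {
    i <- which.min(abs(cuts - f))
    cuts[i] <- f
  }
  as.integer(sort(unique(cuts)))
}

build_gene_model <- function(gene, mechanism, n_exons, plen, strand, special) {
  utr5 <- sample(80:200, 1)
  utr3 <- sample(150:500, 1)
  codons <- sample(NON_STOP_CODONS, plen, replace = TRUE)
  fixed <- fixed_codons_for(gene)
  if (!is.null(fixed)) codons[as.integer(names(fixed))] <- unname(fixed)
  cds <- paste0(paste(codons, collapse = ""), "TAA")
  tx <- paste0(random_dna(utr5), cds, random_dna(utr3))
  tx_len <- nchar(tx)

  forced <- integer(0); last_cut <- NA_integer_; window <- NULL
  if (identical(special, "brca1_junction")) forced <- utr5 + 5467L
  if (identical(special, "egfr_exon19")) window <- c(19L, utr5 + 2150L, utr5 + 2330L)
  if (identical(special, "long_last_exon")) {
    # last junction at ~25% of the CDS: a long NMD-escaping terminal exon
    last_cut <- utr5 + as.integer(round(0.25 * 3 * plen))
  }
  cuts <- make_cuts(tx_len, n_exons, forced = forced, last_cut = last_cut,
                    window = window)
  n_exons_eff <- length(cuts) + 1L

  starts_t <- c(1L, cuts + 1L)
  ends_t <- c(cuts, tx_len)
  exon_seqs <- substring(tx, starts_t, ends_t)
  intron_lens <- if (n_exons_eff > 1) sample(150:1200, n_exons_eff - 1, replace = TRUE) else integer(0)
  intron_seqs <- vapply(intron_lens, function(L)
    paste0("GT", random_dna(L - 4L), "AG"), character(1))

  pieces <- character(0)
  for (k in seq_len(n_exons_eff)) {
    pieces <- c(pieces, exon_seqs[k])
    if (k < n_exons_eff) pieces <- c(pieces, intron_seqs[k])
  }
  pre <- paste(pieces, collapse = "")
  genomic_sense <- if (strand == "+") pre else revcomp(pre)
  flank5 <- random_dna(500); flank3 <- random_dna(500)
  contig <- paste0(flank5, genomic_sense, flank3)
  off <- 500L

  # exon coordinates in pre-mRNA space
  pre_starts <- integer(n_exons_eff); pre_ends <- integer(n_exons_eff)
  cursor <- 0L
  for (k in seq_len(n_exons_eff)) {
    pre_starts[k] <- cursor + 1L
    pre_ends[k] <- cursor + nchar(exon_seqs[k])
    cursor <- pre_ends[k]
    if (k < n_exons_eff) cursor <- cursor + nchar(intron_seqs[k])
  }
  pre_len <- nchar(pre)
  if (strand == "+") {
    gstarts <- off + pre_starts; gends <- off + pre_ends
  } else {
    gstarts <- off + (pre_len - pre_ends + 1L)
    gends <- off + (pre_len - pre_starts + 1L)
    ord <- order(gstarts)
    gstarts <- gstarts[ord]; gends <- gends[ord]
  }
  # genomic CDS bounds: transcript positions utr5+1 and utr5+nchar(cds)
  t_cds <- c(utr5 + 1L, utr5 + nchar(cds))
  pre_of_t <- function(t) {
    for (k in seq_len(n_exons_eff)) {
      if (t >= starts_t[k] && t <= ends_t[k]) {
        return(pre_starts[k] + (t - starts_t[k]))
      }
    }
    stop("internal: transcript coordinate not in exons")
  }
  g_of_t <- function(t) {
    p <- pre_of_t(t)
    if (strand == "+") off + p else off + (pre_len - p + 1L)
  }
  cds_g <- sort(vapply(t_cds, g_of_t, numeric(1)))

  list(
    transcript = tibble(
      gene_symbol = gene,
      transcript_id = paste0("TX_", gene),
      chrom = paste0("ctg_", gene), strand = strand,
      exon_starts = list(as.integer(gstarts)),
      exon_ends = list(as.integer(gends)),
      cds_start = as.integer(cds_g[1]), cds_end = as.integer(cds_g[2]),
      protein_length = as.integer(plen)
    ),
    gene = tibble(
      gene_symbol = gene, mechanism = mechanism,
      canonical_transcript = paste0("TX_", gene),
      critical_regions = list(curated_region_for(gene, plen))
    ),
    sequence = stats::setNames(contig, paste0("ctg_", gene))
  )
}

curated_region_for <- function(gene, plen) {
  if (gene == "TP53") {
    return(matrix(c(94L, 312L), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

#' Generate synthetic gene and transcript models
#'
#' Produces a deterministic mixture of tumor suppressors, oncogenes and
#' dual-mechanism genes (1-28 exons), always including the anchor genes used
#' throughout the fixtures (BRCA1/2-, EGFR-, FLT3-, KRAS-, MUTYH-like, a
#' single-exon gene, long-last-exon tumor suppressors) plus random filler
#' genes.
#'
#' @param n_genes total number of genes (minimum 1; defaults to the anchor set
#'   plus four fillers).
#' @param seed integer seed; fixed seed gives byte-identical fixtures.
#' @return a [transcript_db()].
#' @export
generate_gene_models <- function(n_genes = NULL, seed = 1) {
  specs <- anchor_gene_specs()
  n_anchor <- nrow(specs)
  if (is.null(n_genes)) n_genes <- n_anchor + 4L
  if (n_genes < 1) abort("n_genes must be >= 1")
  withr::with_seed(seed, {
    models <- list()
    use <- specs[seq_len(min(n_genes, n_anchor)), ]
    for (i in seq_len(nrow(use))) {
      models[[i]] <- build_gene_model(use$gene[i], use$mechanism[i],
                                      use$n_exons[i], use$protein_length[i],
                                      use$strand[i], use$special[i])
    }
    n_fill <- n_genes - nrow(use)
    for (j in seq_len(n_fill)) {
      gene <- sprintf("GENE%02d", j)
      mech <- sample(c("tumor_suppressor", "oncogene", "dual", "unknown"), 1,
                     prob = c(0.4, 0.4, 0.1, 0.1))
      models[[nrow(use) + j]] <- build_gene_model(
        gene, mech, sample(2:20, 1), sample(300:800, 1),
        sample(c("+", "-"), 1), NA)
    }
    transcript_db(
      transcripts = bind_rows(map(models, "transcript")),
      genes = bind_rows(map(models, "gene")),
      sequences = unlist(map(models, "sequence"))
    )
  })
}
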