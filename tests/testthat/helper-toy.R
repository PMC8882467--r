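# Hand-built miniature transcript database with fully known arithmetic:
# gene TSG1 (+ strand): 100-aa protein of Glu codons (GAA) + TAA stop,
# 11-nt 5' UTR, 20-nt 3' UTR, five exons of transcript coordinates
# [1,60][61,120][121,180][181,240][241,334], introns of 100 nt.
# A G>T at the first base of codon k creates a stop (GAA -> TAA), so PTCs can
# be placed anywhere. Last exon-exon junction at transcript position 240
# (CDS position 229..240 region); codon k starts at transcript 11 + 3(k-1) + 1.
make_toy_db <- function() {
  utr5 <- 11L
  cds <- paste0(strrep("GAA", 100), "TAA")
  tx <- paste0(strrep("C", utr5), cds, strrep("C", 20L))
  stopifnot(nchar(tx) == 334L)
  starts_t <- c(1L, 61L, 121L, 181L, 241L)
  ends_t <- c(60L, 120L, 180L, 240L, 334L)
  intron <- function() paste0("GT", strrep("A", 96), "AG")
  pieces <- character(0)
  for (k in 1:5) {
    pieces <- c(pieces, substring(tx, starts_t[k], ends_t[k]))
    if (k < 5) pieces <- c(pieces, intron())
  }
  contig <- paste0(strrep("T", 50), paste(pieces, collapse = ""),
                   strrep("T", 50))
  off <- 50L
  gstarts <- integer(5); gends <- integer(5); cursor <- off
  for (k in 1:5) {
    gstarts[k] <- cursor + 1L
    gends[k] <- cursor + (ends_t[k] - starts_t[k] + 1L)
    cursor <- gends[k]
    if (k < 5) cursor <- cursor + 100L
  }
  transcripts <- tibble::tibble(
    gene_symbol = "TSG1", transcript_id = "TX_TSG1", chrom = "ctg_toy",
    strand = "+", exon_starts = list(gstarts), exon_ends = list(gends),
    cds_start = toy_g(utr5 + 1L, gstarts, starts_t, ends_t),
    cds_end = toy_g(utr5 + 303L, gstarts, starts_t, ends_t),
    protein_length = 100L
  )
  genes <- tibble::tibble(
    gene_symbol = "TSG1", mechanism = "tumor_suppressor",
    canonical_transcript = "TX_TSG1",
    critical_regions = list(matrix(integer(0), ncol = 2))
  )
  transcript_db(transcripts, genes,
                stats::setNames(contig, "ctg_toy"))
}

# transcript coordinate -> genomic, for the toy (+ strand) layout
toy_g <- function(t, gstarts, starts_t, ends_t) {
  k <- which(t >= starts_t & t <= ends_t)[1]
  as.integer(gstarts[k] + (t - starts_t[k]))
}

# expression creating a stop at codon k of TSG1 (GAA -> TAA)
toy_stop_expr <- function(k) paste0("TSG1:c.", 3L * (k - 1L) + 1L, "G>T")
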