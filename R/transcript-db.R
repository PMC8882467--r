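# Lightweight gene/transcript models.
#
# A transcript_db bundles three tables: transcript structures, gene records
# (mechanism of action, canonical transcript, curated critical regions) and the
# genomic sequences of the synthetic contigs the transcripts live on. All
# genomic coordinates are 1-based and closed (VCF convention); exon intervals
# are stored in ascending genomic order regardless of strand.

#' Build a transcript database
#'
#' @param transcripts tibble with columns `gene_symbol`, `transcript_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `exon_starts`, `exon_ends` (list columns
#'   of integer vectors, ascending genomic order), `cds_start`, `cds_end`
#'   (genomic bounds of the coding sequence including the stop codon) and
#'   `protein_length` (amino acids, excluding the stop).
#' @param genes tibble with columns `gene_symbol`, `mechanism`
#'   (`tumor_suppressor`, `oncogene`, `dual`, `unknown`), `canonical_transcript`
#'   and `critical_regions` (list column of 2-column matrices of protein
#'   intervals, possibly empty).
#' @param sequences named character vector: contig name -> DNA sequence.
#'
#' @return object of class `transcript_db`.
#' @export
transcript_db <- function(transcripts, genes, sequences) {
  transcripts <- as_tibble(transcripts)
  genes <- as_tibble(genes)
  db <- structure(
    list(transcripts = transcripts, genes = genes, sequences = sequences,
         cache = new.env(parent = emptyenv())),
    class = "transcript_db"
  )
  validate_transcript_db(db)
  db
}

validate_transcript_db <- function(db) {
  tr <- db$transcripts
  needed <- c("gene_symbol", "transcript_id", "chrom", "strand", "exon_starts",
              "exon_ends", "cds_start", "cds_end", "protein_length")
  miss <- setdiff(needed, names(tr))
  if (length(miss)) abort(paste0("transcripts table lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  for (i in seq_len(nrow(tr))) {
    s <- tr$exon_starts[[i]]
    e <- tr$exon_ends[[i]]
    id <- tr$transcript_id[i]
    if (length(s) != length(e) || any(e < s)) {
      abort(paste0("malformed exons in transcript ", id))
    }
    if (length(s) > 1 && any(s[-1] <= e[-length(e)])) {
      abort(paste0("overlapping/unordered exons in transcript ", id))
    }
    in_exon <- function(g) any(g >= s & g <= e)
    if (!in_exon(tr$cds_start[i]) || !in_exon(tr$cds_end[i])) {
      abort(paste0("CDS bounds outside exons in transcript ", id))
    }
    if (!tr$chrom[i] %in% names(db$sequences)) {
      abort(paste0("no sequence for contig ", tr$chrom[i]))
    }
    st <- tx_struct(db, id)
    if (st$cds_len != 3L * (tr$protein_length[i] + 1L)) {
      abort(paste0("protein_length inconsistent with CDS length in ", id))
    }
  }
  gn <- db$genes
  if (!all(gn$mechanism %in% c("tumor_suppressor", "oncogene", "dual", "unknown"))) {
    abort("unknown gene mechanism value")
  }
  if (!all(gn$canonical_transcript %in% tr$transcript_id)) {
    abort("canonical_transcript missing from transcripts table")
  }
  invisible(db)
}

#' @export
print.transcript_db <- function(x, ...) {
  cat("<transcript_db> ", nrow(x$transcripts), " transcripts, ",
      nrow(x$genes), " genes, ", length(x$sequences), " contigs\n", sep = "")
  invisible(x)
}

# Resolved per-transcript structure, cached on first use.
tx_struct <- function(db, transcript_id) {
  cached <- db$cache[[transcript_id]]
  if (!is.null(cached)) return(cached)
  row <- db$transcripts[db$transcripts$transcript_id == transcript_id, ]
  if (nrow(row) == 0) abort(paste0("unknown transcript: ", transcript_id))
  strand <- row$strand
  chrom <- row$chrom
  seq <- db$sequences[[chrom]]
  gs <- row$exon_starts[[1]]
  ge <- row$exon_ends[[1]]
  ord <- if (strand == "+") seq_along(gs) else rev(seq_along(gs))
  gs <- gs[ord]; ge <- ge[ord]
  w <- ge - gs + 1L
  tstart <- cumsum(c(1L, w[-length(w)]))
  tend <- cumsum(w)
  exon_seq <- vapply(seq_along(gs), function(k) {
    x <- substr(seq, gs[k], ge[k])
    if (strand == "-") revcomp(x) else x
  }, character(1))
  spliced <- paste(exon_seq, collapse = "")
  exons <- tibble(rank = seq_along(gs), gstart = gs, gend = ge,
                  width = w, tstart = tstart, tend = tend)
  first_cds_g <- if (strand == "+") row$cds_start else row$cds_end
  last_cds_g <- if (strand == "+") row$cds_end else row$cds_start
  st <- list(
    transcript_id = transcript_id, gene_symbol = row$gene_symbol,
    chrom = chrom, strand = strand, exons = exons,
    tx_len = sum(w), spliced = spliced,
    protein_length = row$protein_length
  )
  st$cds_t_start <- g2t(st, first_cds_g)
  st$cds_t_end <- g2t(st, last_cds_g)
  st$cds_len <- st$cds_t_end - st$cds_t_start + 1L
  # transcript coordinates of exon-exon junctions (last base of each
  # non-terminal exon)
  st$junctions_t <- if (nrow(exons) > 1) exons$tend[-nrow(exons)] else integer(0)
  st$cds_seq <- substr(spliced, st$cds_t_start, st$cds_t_end)
  st$ref_prot <- translate_cds(st$cds_seq)     # includes terminal '*'
  db$cache[[transcript_id]] <- st
  st
}

# genomic -> transcript coordinate (NA when intronic / outside)
g2t <- function(st, gpos) {
  ex <- st$exons
  hit <- which(gpos >= ex$gstart & gpos <= ex$gend)
  if (length(hit) == 0) return(NA_integer_)
  k <- hit[1]
  if (st$strand == "+") ex$tstart[k] + (gpos - ex$gstart[k])
  else ex$tstart[k] + (ex$gend[k] - gpos)
}

t2g <- function(st, tpos) {
  ex <- st$exons
  hit <- which(tpos >= ex$tstart & tpos <= ex$tend)
  if (length(hit) == 0) abort("transcript coordinate out of range")
  k <- hit[1]
  if (st$strand == "+") ex$gstart[k] + (tpos - ex$tstart[k])
  else ex$gend[k] - (tpos - ex$tstart[k])
}

# genomic -> CDS coordinate (1-based within coding sequence), NA if outside CDS
g2c <- function(st, gpos) {
  t <- g2t(st, gpos)
  if (is.na(t)) return(NA_integer_)
  c <- t - st$cds_t_start + 1L
  if (c < 1L || c > st$cds_len) return(NA_integer_)
  c
}

# CDS coordinate (with optional intronic offset) -> genomic
c2g <- function(st, cpos, offset = 0L) {
  t <- st$cds_t_start + cpos - 1L
  g <- t2g(st, t)
  if (offset == 0L) return(g)
  if (st$strand == "+") g + offset else g - offset
}

# For an intronic genomic position: which junction is nearest and how far.
# Returns NULL when the position is exonic or outside the transcript span.
intron_context <- function(st, gpos) {
  ex <- st$exons
  if (!is.na(g2t(st, gpos))) return(NULL)
  n <- nrow(ex)
  if (n < 2) return(NULL)
  for (k in seq_len(n - 1)) {
    # genomic interval of the intron between tx exons k and k+1
    if (st$strand == "+") {
      lo <- ex$gend[k] + 1L; hi <- ex$gstart[k + 1] - 1L
      if (gpos < lo || gpos > hi) next
      d_donor <- gpos - ex$gend[k]
      d_acceptor <- ex$gstart[k + 1] - gpos
    } else {
      lo <- ex$gend[k + 1] + 1L; hi <- ex$gstart[k] - 1L
      if (gpos < lo || gpos > hi) next
      d_donor <- ex$gstart[k] - gpos
      d_acceptor <- gpos - ex$gend[k + 1]
    }
    if (d_donor <= d_acceptor) {
      return(list(junction = k, side = "donor", dist = d_donor,
                  exon_number = k))
    }
    return(list(junction = k, side = "acceptor", dist = d_acceptor,
                exon_number = k + 1L))
  }
  NULL
}

exon_number_of <- function(st, gpos) {
  ex <- st$exons
  hit <- which(gpos >= ex$gstart & gpos <= ex$gend)
  if (length(hit)) return(ex$rank[hit[1]])
  ic <- intron_context(st, gpos)
  if (is.null(ic)) NA_integer_ else ic$exon_number
}

# protein sequence (without stop) of the wild-type transcript
tx_protein <- function(st) {
  sub("\\*$", "", st$ref_prot)
}

canonical_struct <- function(db, gene_symbol) {
  g <- db$genes[db$genes$gene_symbol == gene_symbol, ]
  if (nrow(g) == 0) abort(paste0("unknown gene: ", gene_symbol))
  tx_struct(db, g$canonical_transcript[1])
}

gene_record <- function(db, gene_symbol) {
  g <- db$genes[db$genes$gene_symbol == gene_symbol, ]
  if (nrow(g) == 0) abort(paste0("unknown gene: ", gene_symbol))
  g
}

#' Write / read transcript model fixtures
#'
#' Transcript and gene models are exchanged as two tab-separated files plus a
#' FASTA of contig sequences. Exon coordinate vectors and critical regions are
#' comma/semicolon packed (`"12-80;95-120"`).
#'
#' @param db a [transcript_db()].
#' @param dir directory to write `transcripts.tsv`, `genes.tsv`, `genome.fa`.
#' @return `write_transcript_db()` returns `dir` invisibly;
#'   `read_transcript_db()` returns a `transcript_db`.
#' @export
write_transcript_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tr <- db$transcripts |>
    mutate(
      exon_starts = map_chr(.data$exon_starts, ~ paste(.x, collapse = ",")),
      exon_ends = map_chr(.data$exon_ends, ~ paste(.x, collapse = ","))
    )
  readr::write_tsv(tr, file.path(dir, "transcripts.tsv"))
  gn <- db$genes |>
    mutate(critical_regions = map_chr(.data$critical_regions, pack_regions))
  readr::write_tsv(gn, file.path(dir, "genes.tsv"))
  seqs <- Biostrings::DNAStringSet(db$sequences)
  Biostrings::writeXStringSet(seqs, file.path(dir, "genome.fa"))
  invisible(dir)
}

#' @rdname write_transcript_db
#' @export
read_transcript_db <- function(dir) {
  tr <- readr::read_tsv(file.path(dir, "transcripts.tsv"),
                        show_col_types = FALSE,
                        col_types = readr::cols(
                          exon_starts = readr::col_character(),
                          exon_ends = readr::col_character())) |>
    mutate(
      exon_starts = map(str_split(.data$exon_starts, ","), as.integer),
      exon_ends = map(str_split(.data$exon_ends, ","), as.integer),
      across(c("cds_start", "cds_end", "protein_length"), as.integer)
    )
  gn <- readr::read_tsv(file.path(dir, "genes.tsv"), show_col_types = FALSE,
                        col_types = readr::cols(
                          critical_regions = readr::col_character())) |>
    mutate(critical_regions = map(.data$critical_regions, unpack_regions))
  fa <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  seqs <- as.character(fa)
  names(seqs) <- sub("\\s.*$", "", names(fa))
  transcript_db(tr, gn, seqs)
}

pack_regions <- function(m) {
  if (is.null(m) || length(m) == 0 || nrow(m) == 0) return("")
  paste(paste0(m[, 1], "-", m[, 2]), collapse = ";")
}

unpack_regions <- function(x) {
  if (is.na(x) || !nzchar(x)) return(matrix(integer(0), ncol = 2))
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(strsplit(parts, "-", fixed = TRUE), as.integer))
  colnames(m) <- c("start", "end")
  m
}
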