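# Variant normalization.
#
# Every accepted syntax (VCF record, genomic HGVS, cDNA HGVS with intronic
# offsets, protein HGVS) is reduced to one canonical representation: plus-strand
# genomic alleles, trimmed of shared context and left-aligned on the genome.
# Indels are re-shifted 3' along the transcript strand for the cDNA/protein
# names only, so the naming matches HGVS convention while the genomic key stays
# VCF-like. Empty `ref` marks a pure insertion (pos = base 5' of the inserted
# sequence); empty `alt` a pure deletion (pos = first deleted base).

chrom_seq <- function(db, chrom) {
  s <- db$sequences[[chrom]]
  if (is.null(s)) abort(paste0("no sequence for contig ", chrom))
  s
}

# ---- canonical genomic form ------------------------------------------------

canonicalize_genomic <- function(db, chrom, pos, ref, alt) {
  seq <- chrom_seq(db, chrom)
  pos <- as.integer(pos)
  ref <- toupper(ref %||% ""); alt <- toupper(alt %||% "")
  if (nzchar(ref)) {
    obs <- seq_slice(seq, pos, pos + nchar(ref) - 1L)
    if (!identical(obs, ref)) {
      abort(paste0("reference mismatch at ", chrom, ":", pos,
                   " (expected ", ref, ", genome has ", obs, ")"))
    }
  }
  tr <- trim_allele_pair(ref, alt, pos)
  ref <- tr$ref; alt <- tr$alt; pos <- tr$pos
  if (!nzchar(ref) && !nzchar(alt)) {
    abort("alleles identical after trimming (no variant)")
  }
  if (!nzchar(alt)) {                                  # deletion
    sh <- shift_indel_left(seq, pos, ref, is_del = TRUE)
    pos <- sh$pos; ref <- sh$allele
  } else if (!nzchar(ref)) {                           # insertion
    pos <- pos - 1L                                    # base 5' of insertion
    sh <- shift_indel_left(seq, pos, alt, is_del = FALSE)
    pos <- sh$pos; alt <- sh$allele
  }
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

genomic_desc <- function(v) {
  if (nzchar(v$ref) && nzchar(v$alt)) {
    if (nchar(v$ref) == 1 && nchar(v$alt) == 1) {
      paste0("g.", v$pos, v$ref, ">", v$alt)
    } else {
      paste0("g.", v$pos, "_", v$pos + nchar(v$ref) - 1L, "delins", v$alt)
    }
  } else if (nzchar(v$ref)) {
    if (nchar(v$ref) == 1) paste0("g.", v$pos, "del")
    else paste0("g.", v$pos, "_", v$pos + nchar(v$ref) - 1L, "del")
  } else {
    paste0("g.", v$pos, "_", v$pos + 1L, "ins", v$alt)
  }
}

# Convert the canonical (possibly empty-allele) form to VCF-style anchored
# alleles; used when emitting VCF fixtures.
canonical_to_vcf <- function(db, chrom, pos, ref, alt) {
  seq <- chrom_seq(db, chrom)
  if (nzchar(ref) && nzchar(alt)) {
    return(list(pos = pos, ref = ref, alt = alt))
  }
  if (!nzchar(alt)) {                                  # deletion: anchor 5'
    a <- substr(seq, pos - 1L, pos - 1L)
    list(pos = pos - 1L, ref = paste0(a, ref), alt = a)
  } else {                                             # insertion after pos
    a <- substr(seq, pos, pos)
    list(pos = pos, ref = a, alt = paste0(a, alt))
  }
}

# ---- HGVS-lite parsing -----------------------------------------------------

parse_hgvs_expression <- function(db, gene, expr) {
  st <- canonical_struct(db, gene)
  expr <- gsub("\\s", "", expr)
  if (str_detect(expr, "^g\\.")) {
    parse_hgvs_g(db, st, expr)
  } else if (str_detect(expr, "^c\\.")) {
    parse_hgvs_c(db, st, expr)
  } else if (str_detect(expr, "^p\\.")) {
    parse_hgvs_p(db, st, expr)
  } else {
    abort(paste0("unparseable variant expression: '", expr,
                 "' (expected g./c./p. prefix)"))
  }
}

parse_hgvs_g <- function(db, st, expr) {
  seq <- chrom_seq(db, st$chrom)
  m <- str_match(expr, "^g\\.(\\d+)([ACGT])>([ACGT])$")
  if (!is.na(m[1])) {
    return(list(chrom = st$chrom, pos = as.integer(m[2]), ref = m[3], alt = m[4]))
  }
  m <- str_match(expr, "^g\\.(\\d+)(?:_(\\d+))?(del|dup|ins|delins)([ACGT]*)$")
  if (is.na(m[1])) abort(paste0("unparseable genomic expression: '", expr, "'"))
  s <- as.integer(m[2]); e <- if (is.na(m[3])) s else as.integer(m[3])
  op <- m[4]; seg <- m[5]
  span <- substr(seq, s, e)
  switch(op,
    del = list(chrom = st$chrom, pos = s, ref = span, alt = ""),
    dup = list(chrom = st$chrom, pos = e + 1L, ref = "", alt = span),
    delins = list(chrom = st$chrom, pos = s, ref = span, alt = seg),
    ins = {
      if (e != s + 1L) abort(paste0("ins positions must be adjacent: '", expr, "'"))
      if (!nzchar(seg)) abort(paste0("ins without sequence: '", expr, "'"))
      list(chrom = st$chrom, pos = s + 1L, ref = "", alt = seg)
    }
  )
}

c_point_to_g <- function(st, cpos, offset) {
  if (cpos < 1L || cpos > st$cds_len) {
    abort(paste0("cDNA position ", cpos, " outside CDS of ", st$transcript_id))
  }
  c2g(st, cpos, offset)
}

parse_hgvs_c <- function(db, st, expr) {
  seq <- chrom_seq(db, st$chrom)
  m <- str_match(expr, "^c\\.(\\d+)([+-]\\d+)?([ACGT])>([ACGT])$")
  if (!is.na(m[1])) {
    off <- if (is.na(m[3])) 0L else as.integer(m[3])
    g <- c_point_to_g(st, as.integer(m[2]), off)
    ref <- m[4]; alt <- m[5]
    if (st$strand == "-") { ref <- revcomp(ref); alt <- revcomp(alt) }
    obs <- substr(seq, g, g)
    if (obs != ref) {
      abort(paste0("reference mismatch for '", expr, "' (genome has ",
                   if (st$strand == "-") revcomp(obs) else obs,
                   " on the transcript strand)"))
    }
    return(list(chrom = st$chrom, pos = g, ref = ref, alt = alt))
  }
  m <- str_match(expr,
    "^c\\.(\\d+)([+-]\\d+)?(?:_(\\d+)([+-]\\d+)?)?(del|dup|ins|delins)([ACGT]*)$")
  if (is.na(m[1])) abort(paste0("unparseable cDNA expression: '", expr, "'"))
  o1 <- if (is.na(m[3])) 0L else as.integer(m[3])
  g1 <- c_point_to_g(st, as.integer(m[2]), o1)
  g2 <- if (is.na(m[4])) g1 else {
    o2 <- if (is.na(m[5])) 0L else as.integer(m[5])
    c_point_to_g(st, as.integer(m[4]), o2)
  }
  op <- m[6]; seg <- m[7]
  lo <- min(g1, g2); hi <- max(g1, g2)
  span <- substr(seq, lo, hi)
  if (st$strand == "-" && nzchar(seg)) seg <- revcomp(seg)
  switch(op,
    del = list(chrom = st$chrom, pos = lo, ref = span, alt = ""),
    dup = list(chrom = st$chrom, pos = hi + 1L, ref = "", alt = span),
    delins = list(chrom = st$chrom, pos = lo, ref = span, alt = seg),
    ins = {
      if (hi != lo + 1L) abort(paste0("ins positions must be adjacent: '", expr, "'"))
      if (!nzchar(seg)) abort(paste0("ins without sequence: '", expr, "'"))
      list(chrom = st$chrom, pos = lo + 1L, ref = "", alt = seg)
    }
  )
}

parse_hgvs_p <- function(db, st, expr) {
  m <- str_match(expr, "^p\\.([A-Z])(\\d+)([A-Z*])$")
  if (!is.na(m[1])) {
    return(protein_sub_to_genomic(db, st, m[2], as.integer(m[3]), m[4]))
  }
  m <- str_match(expr, "^p\\.([A-Z])(\\d+)(?:_([A-Z])(\\d+))?del$")
  if (!is.na(m[1])) {
    a <- as.integer(m[3]); b <- if (is.na(m[5])) a else as.integer(m[5])
    return(protein_del_to_genomic(db, st, m[2], a, if (is.na(m[4])) m[2] else m[4], b))
  }
  abort(paste0("unparseable protein expression: '", expr, "'"))
}

codon_genomic_positions <- function(st, aa_pos) {
  t0 <- st$cds_t_start + (aa_pos - 1L) * 3L
  vapply(0:2, function(k) t2g(st, t0 + k), integer(1))
}

protein_sub_to_genomic <- function(db, st, ref_aa, aa_pos, alt_aa) {
  if (aa_pos < 1L || aa_pos > st$protein_length) {
    abort(paste0("protein position ", aa_pos, " outside ", st$gene_symbol))
  }
  codon <- substr(st$cds_seq, (aa_pos - 1L) * 3L + 1L, aa_pos * 3L)
  if (translate_cds(codon) != ref_aa) {
    abort(paste0("reference amino acid mismatch at p.", ref_aa, aa_pos,
                 " in ", st$gene_symbol))
  }
  bases <- c("A", "C", "G", "T")
  for (j in 1:3) {
    for (b in bases) {
      if (substr(codon, j, j) == b) next
      mut <- codon
      substr(mut, j, j) <- b
      if (translate_cds(mut) == alt_aa) {
        g <- codon_genomic_positions(st, aa_pos)[j]
        ref_nt <- substr(codon, j, j); alt_nt <- b
        if (st$strand == "-") { ref_nt <- revcomp(ref_nt); alt_nt <- revcomp(alt_nt) }
        return(list(chrom = st$chrom, pos = g, ref = ref_nt, alt = alt_nt))
      }
    }
  }
  abort(paste0("no single-nucleotide change yields p.", ref_aa, aa_pos, alt_aa,
               " on ", st$gene_symbol, "; supply a nucleotide-level expression"))
}

protein_del_to_genomic <- function(db, st, aa1, a, aa2, b) {
  if (b < a) abort("protein deletion range reversed")
  gs <- unlist(lapply(a:b, function(i) codon_genomic_positions(st, i)))
  if (max(gs) - min(gs) + 1L != length(gs)) {
    abort("protein deletion spans an intron; supply a cDNA expression")
  }
  seq <- chrom_seq(db, st$chrom)
  prot <- tx_protein(st)
  if (substr(prot, a, a) != aa1 || substr(prot, b, b) != aa2) {
    abort(paste0("reference amino acid mismatch in p.", aa1, a, "_", aa2, b, "del"))
  }
  list(chrom = st$chrom, pos = min(gs), ref = substr(seq, min(gs), max(gs)),
       alt = "")
}

# ---- public API ------------------------------------------------------------

#' Normalize variants to a canonical representation
#'
#' Accepts either a data frame of VCF-style records (columns `chrom`, `pos`,
#' `ref`, `alt`, optionally `gene_symbol`, `vaf`, `origin`, `zygosity`) or a
#' character vector of `"GENE:expression"` strings where the expression is a
#' genomic (`g.`), cDNA (`c.`, intronic offsets supported) or protein (`p.`)
#' HGVS-style change. The same underlying allele always normalizes to the same
#' output row: genomic alleles are trimmed and left-aligned, while the reported
#' cDNA/protein names are 3'-shifted on the transcript strand.
#'
#' @param x data frame or character vector (see above).
#' @param db a [transcript_db()].
#' @return tibble with one row per input variant: canonical genomic
#'   coordinates, `variant_key`, `cdna_change`, `protein_change`, consequence
#'   annotation (see [call_consequence()]) and observation metadata.
#' @examples
#' db <- generate_gene_models(seed = 1)
#' normalize_variants("BRCA1:c.5468-1G>A", db)$consequence
#' @export
normalize_variants <- function(x, db) {
  if (is.character(x)) {
    rows <- lapply(x, function(line) {
      m <- str_match(line, "^([A-Za-z0-9_.-]+):(.+)$")
      if (is.na(m[1])) {
        abort(paste0("unparseable variant line: '", line,
                     "' (expected GENE:expression)"))
      }
      gene <- m[2]
      if (!gene %in% db$genes$gene_symbol) {
        abort(paste0("gene not in reference models: ", gene))
      }
      g <- parse_hgvs_expression(db, gene, m[3])
      tibble(chrom = g$chrom, pos = g$pos, ref = g$ref, alt = g$alt,
             gene_symbol = gene, vaf = NA_real_, origin = "unknown",
             zygosity = "unknown")
    })
    x <- bind_rows(rows)
  } else {
    x <- as_tibble(x)
    if (!all(c("chrom", "pos", "ref", "alt") %in% names(x))) {
      abort("variant table needs columns chrom, pos, ref, alt")
    }
    if (!"gene_symbol" %in% names(x)) x$gene_symbol <- NA_character_
    if (!"vaf" %in% names(x)) x$vaf <- NA_real_
    if (!"origin" %in% names(x)) x$origin <- "unknown"
    if (!"zygosity" %in% names(x)) x$zygosity <- "unknown"
  }
  if (nrow(x) == 0) return(empty_variant_tibble())
  out <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    out[[i]] <- normalize_one(db, x$chrom[i], x$pos[i], x$ref[i], x$alt[i],
                              x$gene_symbol[i], x$vaf[i], x$origin[i],
                              x$zygosity[i])
  }
  bind_rows(out)
}

empty_variant_tibble <- function() {
  tibble(gene_symbol = character(), transcript_id = character(),
         chrom = character(), pos = integer(), ref = character(),
         alt = character(), variant_key = character(),
         cdna_change = character(), protein_change = character(),
         consequence = character(), exon_number = integer(),
         ptc_codon = integer(), fs_codon = integer(),
         vaf = double(), origin = character(), zygosity = character())
}

normalize_one <- function(db, chrom, pos, ref, alt, gene = NA, vaf = NA,
                          origin = "unknown", zygosity = "unknown") {
  if (is.na(gene) || !nzchar(gene)) {
    gene <- locate_gene(db, chrom, pos)
  }
  if (!gene %in% db$genes$gene_symbol) {
    abort(paste0("gene not in reference models: ", gene))
  }
  v <- canonicalize_genomic(db, chrom, pos, ref, alt)
  st <- canonical_struct(db, gene)
  if (!identical(st$chrom, v$chrom)) {
    abort(paste0("variant contig ", v$chrom, " does not match ",
                 gene, " model (", st$chrom, ")"))
  }
  cc <- call_consequence_canonical(db, v, st)
  tibble(
    gene_symbol = gene, transcript_id = st$transcript_id,
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    variant_key = paste0(gene, ":", genomic_desc(v)),
    cdna_change = cc$cdna_change, protein_change = cc$protein_change,
    consequence = cc$consequence, exon_number = cc$exon_number,
    ptc_codon = cc$ptc_codon, fs_codon = cc$fs_codon,
    vaf = as.numeric(vaf), origin = origin %||% "unknown",
    zygosity = zygosity %||% "unknown"
  )
}

locate_gene <- function(db, chrom, pos) {
  tr <- db$transcripts
  hit <- which(tr$chrom == chrom &
                 map_dbl(tr$exon_starts, min) - 5000 <= pos &
                 map_dbl(tr$exon_ends, max) + 5000 >= pos)
  if (length(hit) == 0) {
    abort(paste0("no transcript model overlaps ", chrom, ":", pos))
  }
  tr$gene_symbol[hit[1]]
}
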