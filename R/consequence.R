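# Consequence calling against a single (canonical) transcript model.
#
# Coding effects are computed by editing the spliced transcript sequence and
# re-translating from the CDS start through the 3' UTR, so premature stop
# codons introduced by frameshifts are found by conceptual translation rather
# than by heuristics. Splice classification uses intronic distance to the
# nearest exon boundary: 1-2 nt = canonical site, 3-8 nt = splice region.

call_consequence_canonical <- function(db, v, st) {
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  is_ins <- !nzchar(ref)
  # genomic footprint
  if (is_ins) {
    gpos_all <- c(pos, pos + 1L)
  } else {
    gpos_all <- pos:(pos + nchar(ref) - 1L)
  }
  t_all <- vapply(gpos_all, function(g) g2t(st, g), integer(1))
  exonic <- !is.na(t_all)

  if (!any(exonic)) {
    ics <- lapply(gpos_all, function(g) intron_context(st, g))
    ics <- ics[!vapply(ics, is.null, logical(1))]
    if (length(ics) == 0) {
      abort(paste0("variant at ", v$chrom, ":", pos,
                   " lies outside transcript ", st$transcript_id))
    }
    d <- min(vapply(ics, function(x) x$dist, integer(1)))
    best <- ics[[which.min(vapply(ics, function(x) x$dist, integer(1)))]]
    cons <- if (d <= 2) "splice_canonical" else if (d <= 8) "splice_region" else "other"
    return(consequence_record(
      consequence = cons, exon_number = best$exon_number,
      cdna_change = intronic_cdna_name(st, v, best),
      protein_change = "", ptc_codon = NA_integer_, fs_codon = NA_integer_,
      splice_junction = if (cons == "splice_canonical") best$junction else NA_integer_
    ))
  }

  if (is_ins && sum(exonic) == 1) {
    # insertion at an exon/intron boundary disrupts the splice site
    ic <- intron_context(st, gpos_all[!exonic][1])
    jn <- if (!is.null(ic)) ic$junction else NA_integer_
    exn <- exon_number_of(st, gpos_all[exonic][1])
    return(consequence_record(
      consequence = "splice_canonical", exon_number = exn,
      cdna_change = "", protein_change = "",
      ptc_codon = NA_integer_, fs_codon = NA_integer_, splice_junction = jn
    ))
  }
  if (!is_ins && !all(exonic)) {
    # deletion straddling an exon/intron boundary
    first_ex <- exon_number_of(st, gpos_all[exonic][1])
    ic <- intron_context(st, gpos_all[!exonic][1])
    jn <- if (!is.null(ic)) ic$junction else NA_integer_
    return(consequence_record(
      consequence = "splice_canonical", exon_number = first_ex,
      cdna_change = "", protein_change = "",
      ptc_codon = NA_integer_, fs_codon = NA_integer_, splice_junction = jn
    ))
  }

  # fully exonic: transcript-space edit
  exn <- exon_number_of(st, gpos_all[1])
  if (is_ins) {
    anchor_t <- if (st$strand == "+") g2t(st, pos) else g2t(st, pos + 1L)
    t1 <- anchor_t + 1L; t2 <- anchor_t      # insertion between anchor_t, anchor_t+1
    ref_t <- ""
    alt_t <- if (st$strand == "-") revcomp(alt) else alt
  } else {
    ts <- range(t_all)
    t1 <- ts[1]; t2 <- ts[2]
    ref_t <- if (st$strand == "-") revcomp(ref) else ref
    alt_t <- if (nzchar(alt)) { if (st$strand == "-") revcomp(alt) else alt } else ""
  }

  cds_t1 <- st$cds_t_start; cds_t2 <- st$cds_t_end
  if (t2 < cds_t1 || t1 > cds_t2 - 2L) {
    # untranslated region (stop codon disruptions also land here)
    return(consequence_record(
      consequence = "other", exon_number = exn,
      cdna_change = "", protein_change = "",
      ptc_codon = NA_integer_, fs_codon = NA_integer_,
      splice_junction = NA_integer_
    ))
  }

  mutant <- if (is_ins) {
    apply_edit(st$spliced, t2 + 1L, t2, alt_t)
  } else {
    apply_edit(st$spliced, t1, t2, alt_t)
  }
  mut_cds_plus <- substr(mutant, cds_t1, nchar(mutant))
  mut_cds_plus <- substr(mut_cds_plus, 1L,
                         3L * (nchar(mut_cds_plus) %/% 3L))
  mut_prot <- translate_cds(mut_cds_plus)
  ref_prot_full <- st$ref_prot

  c1 <- t1 - cds_t1 + 1L
  dlen <- nchar(alt_t) - nchar(ref_t)
  edit_codon <- max(1L, ((if (is_ins) c1 else c1) - 1L) %/% 3L + 1L)

  if (dlen %% 3L == 0L) {
    if (nchar(ref_t) == 1L && nchar(alt_t) == 1L) {
      aa_ref <- substr(ref_prot_full, edit_codon, edit_codon)
      aa_alt <- substr(mut_prot, edit_codon, edit_codon)
      cdna <- snv_cdna_name(st, c1, ref_t, alt_t)
      if (aa_alt == aa_ref) {
        cons <- "synonymous"
        pchg <- paste0("p.", aa_ref, edit_codon, "=")
        ptc <- NA_integer_
      } else if (aa_alt == "*") {
        cons <- "nonsense"
        pchg <- paste0("p.", aa_ref, edit_codon, "*")
        ptc <- edit_codon
      } else if (aa_ref == "*") {
        cons <- "other"   # stop-loss
        pchg <- ""
        ptc <- NA_integer_
      } else {
        cons <- "missense"
        pchg <- paste0("p.", aa_ref, edit_codon, aa_alt)
        ptc <- NA_integer_
      }
      return(consequence_record(cons, exn, cdna, pchg, ptc, NA_integer_,
                                NA_integer_))
    }
    # in-frame indel or multi-nucleotide substitution
    if (dlen == 0L) {
      # MNV: classify by first differing amino acid
      n_cod <- (c1 + nchar(ref_t) - 2L) %/% 3L + 1L
      cods <- edit_codon:n_cod
      ref_aas <- substr(ref_prot_full, edit_codon, n_cod)
      alt_aas <- substr(mut_prot, edit_codon, n_cod)
      cdna <- indel_cdna_name(st, c1, ref_t, alt_t)
      if (identical(ref_aas, alt_aas)) {
        return(consequence_record("synonymous", exn, cdna,
                                  paste0("p.", substr(ref_aas, 1, 1), edit_codon, "="),
                                  NA_integer_, NA_integer_, NA_integer_))
      }
      diff_i <- which(strsplit(ref_aas, "")[[1]] != strsplit(alt_aas, "")[[1]])[1]
      cod <- cods[diff_i]
      a_r <- substr(ref_aas, diff_i, diff_i); a_a <- substr(alt_aas, diff_i, diff_i)
      if (a_a == "*") {
        return(consequence_record("nonsense", exn, cdna,
                                  paste0("p.", a_r, cod, "*"), cod, NA_integer_,
                                  NA_integer_))
      }
      return(consequence_record("missense", exn, cdna,
                                paste0("p.", a_r, cod, a_a), NA_integer_,
                                NA_integer_, NA_integer_))
    }
    cdna <- indel_cdna_name(st, c1, ref_t, alt_t)
    if (dlen < 0L) {
      a <- (c1 - 1L) %/% 3L + 1L
      b <- (c1 + nchar(ref_t) - 2L) %/% 3L + 1L
      prot <- tx_protein(st)
      pchg <- if (a == b) {
        paste0("p.", substr(prot, a, a), a, "del")
      } else {
        paste0("p.", substr(prot, a, a), a, "_", substr(prot, b, b), b, "del")
      }
      return(consequence_record("inframe_deletion", exn, cdna, pchg,
                                NA_integer_, NA_integer_, NA_integer_))
    }
    pchg <- paste0("p.", edit_codon, "_", edit_codon + 1L, "ins")
    return(consequence_record("inframe_insertion", exn, cdna, pchg,
                              NA_integer_, NA_integer_, NA_integer_))
  }

  # frameshift: conceptual translation to the first downstream stop
  cdna <- indel_cdna_name(st, c1, ref_t, alt_t)
  fs_codon <- edit_codon
  stops <- gregexpr("*", mut_prot, fixed = TRUE)[[1]]
  stops <- stops[stops >= fs_codon]
  ptc <- if (length(stops) && stops[1] > 0) as.integer(stops[1]) else NA_integer_
  prot <- tx_protein(st)
  fs_aa <- substr(prot, fs_codon, fs_codon)
  pchg <- paste0("p.", fs_aa, fs_codon, "fs")
  consequence_record("frameshift", exn, cdna, pchg, ptc, fs_codon, NA_integer_)
}

consequence_record <- function(consequence, exon_number, cdna_change,
                               protein_change, ptc_codon, fs_codon,
                               splice_junction) {
  list(consequence = consequence, exon_number = as.integer(exon_number),
       cdna_change = cdna_change, protein_change = protein_change,
       ptc_codon = ptc_codon, fs_codon = fs_codon,
       splice_junction = splice_junction)
}

snv_cdna_name <- function(st, c1, ref_t, alt_t) {
  paste0("c.", c1, ref_t, ">", alt_t)
}

# 3'-shift an exonic CDS indel along the spliced transcript before naming.
indel_cdna_name <- function(st, c1, ref_t, alt_t) {
  tx_from_cds <- substr(st$spliced, st$cds_t_start, nchar(st$spliced))
  if (!nzchar(alt_t) || !nzchar(ref_t)) {
    is_del <- !nzchar(alt_t)
    allele <- if (is_del) ref_t else alt_t
    p <- if (is_del) c1 else c1 - 1L   # insertion anchored 5'
    sh <- shift_indel_right(tx_from_cds, p, allele, is_del = is_del)
    if (is_del) {
      s <- sh$pos; e <- sh$pos + nchar(sh$allele) - 1L
      if (s == e) return(paste0("c.", s, "del"))
      return(paste0("c.", s, "_", e, "del"))
    }
    return(paste0("c.", sh$pos, "_", sh$pos + 1L, "ins", sh$allele))
  }
  paste0("c.", c1, "_", c1 + nchar(ref_t) - 1L, "delins", alt_t)
}

intronic_cdna_name <- function(st, v, ic) {
  if (!(nchar(v$ref) == 1 && nchar(v$alt) == 1)) return("")
  ex <- st$exons
  if (ic$side == "donor") {
    ct <- ex$tend[ic$junction] - st$cds_t_start + 1L
    off <- paste0("+", ic$dist)
  } else {
    ct <- ex$tstart[ic$junction + 1L] - st$cds_t_start + 1L
    off <- paste0("-", ic$dist)
  }
  ref_t <- v$ref; alt_t <- v$alt
  if (st$strand == "-") { ref_t <- revcomp(ref_t); alt_t <- revcomp(alt_t) }
  paste0("c.", ct, off, ref_t, ">", alt_t)
}

#' Call the molecular consequence of a normalized variant
#'
#' Wrapper used on already-normalized variant rows; recomputes the consequence
#' annotation on a chosen transcript (by default the gene's canonical one).
#'
#' @param variants tibble from [normalize_variants()].
#' @param db a [transcript_db()].
#' @return the input tibble with refreshed consequence columns.
#' @export
call_consequence <- function(variants, db) {
  stopifnot(is.data.frame(variants))
  out <- variants
  for (i in seq_len(nrow(variants))) {
    st <- canonical_struct(db, variants$gene_symbol[i])
    cc <- call_consequence_canonical(
      db, list(chrom = variants$chrom[i], pos = variants$pos[i],
               ref = variants$ref[i], alt = variants$alt[i]), st)
    out$consequence[i] <- cc$consequence
    out$exon_number[i] <- cc$exon_number
    out$cdna_change[i] <- cc$cdna_change
    out$protein_change[i] <- cc$protein_change
    out$ptc_codon[i] <- cc$ptc_codon
    out$fs_codon[i] <- cc$fs_codon
  }
  out
}

#' Fraction of the wild-type protein lost to a truncating variant
#'
#' For premature-termination variants the fraction is
#' `(protein_length - ptc_codon + 1) / protein_length`; for frameshifts that
#' never reach a downstream stop the frameshift start stands in for the stop;
#' for canonical splice disruptions it is the fraction of the coding sequence
#' downstream of the affected junction.
#'
#' @param variants tibble of normalized variants (truncating rows only).
#' @param db a [transcript_db()].
#' @return numeric vector in `[0, 1]`, one value per row.
#' @export
truncated_fraction <- function(variants, db) {
  vapply(seq_len(nrow(variants)), function(i) {
    st <- canonical_struct(db, variants$gene_symbol[i])
    truncated_fraction_one(variants[i, ], st, db)
  }, numeric(1))
}

truncated_fraction_one <- function(v, st, db) {
  L <- st$protein_length
  if (v$consequence %in% c("nonsense", "frameshift")) {
    eff <- if (!is.na(v$ptc_codon)) v$ptc_codon else v$fs_codon
    if (is.na(eff)) abort("truncating variant without a stop or frameshift codon")
    return(max(0, min(1, (L - eff + 1) / L)))
  }
  if (v$consequence == "splice_canonical") {
    cc <- call_consequence_canonical(
      db, list(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt), st)
    jn <- cc$splice_junction
    if (is.na(jn)) abort("cannot resolve affected junction")
    coding_len <- 3L * L
    junction_t <- st$junctions_t[jn]
    nt_up <- max(0L, min(junction_t - st$cds_t_start + 1L, coding_len))
    return((coding_len - nt_up) / coding_len)
  }
  abort(paste0("truncated_fraction is defined for truncating variants only (got ",
               v$consequence, ")"))
}

#' Predict nonsense-mediated decay for a premature termination codon
#'
#' Implements the 50-nt last-junction rule: a PTC is predicted to trigger NMD
#' when the first base of the stop codon lies strictly more than 50 nt upstream
#' of the last exon-exon junction of a multi-exon transcript. Single-exon
#' transcripts and last-exon PTCs escape.
#'
#' @param variants tibble of normalized variants with `ptc_codon` set.
#' @param db a [transcript_db()].
#' @param config an [interpretation_config()] (for the distance cut-off).
#' @return logical vector, one value per row.
#' @export
predict_nmd_trigger <- function(variants, db, config = interpretation_config()) {
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (is.na(v$ptc_codon)) abort("predict_nmd_trigger requires ptc_codon")
    st <- canonical_struct(db, v$gene_symbol)
    predict_nmd_one(v$ptc_codon, v$ref, v$alt, v$pos, st, config)
  }, logical(1))
}

predict_nmd_one <- function(ptc_codon, ref, alt, pos, st, config) {
  if (length(st$junctions_t) == 0) return(FALSE)
  dlen <- nchar(alt) - nchar(ref)
  t_edit <- if (!nzchar(ref)) {
    if (st$strand == "+") g2t(st, pos) else g2t(st, pos + 1L)
  } else {
    min(g2t(st, pos), g2t(st, pos + nchar(ref) - 1L), na.rm = TRUE)
  }
  ptc_first_t <- st$cds_t_start + (ptc_codon - 1L) * 3L
  last_jn <- max(st$junctions_t)
  if (!is.na(t_edit) && last_jn > t_edit) last_jn <- last_jn + dlen
  (last_jn - ptc_first_t) > config$nmd_distance_nt
}

#' Flag variants of potential germline origin
#'
#' With paired tumor/normal calling the recorded origin is authoritative. In
#' tumor-only mode a variant is a germline candidate when its VAF falls inside
#' one of the configured germline-plausible windows (default
#' `[0.40, 0.60]` and `[0.90, 1.00]`). A missing VAF in tumor-only mode yields
#' `NA` (indeterminate), never silent suppression.
#'
#' @param variants tibble of normalized variants (`vaf`, `origin` columns).
#' @param paired logical: was paired calling performed?
#' @param config an [interpretation_config()].
#' @return logical vector (NA = indeterminate).
#' @export
potential_germline_by_vaf <- function(variants, paired,
                                      config = interpretation_config()) {
  if (paired) return(variants$origin == "germline")
  vapply(variants$vaf, function(v) {
    if (is.na(v)) return(NA)
    any(vapply(config$germline_vaf_windows,
               function(w) v >= w[1] && v <= w[2], logical(1)))
  }, logical(1))
}
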