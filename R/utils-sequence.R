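# Small nucleotide-sequence helpers. Sequences are plain upper-case character
# strings; Biostrings supplies the genetic code and complementation so no codon
# table is duplicated here.

revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Translate a coding sequence
#'
#' @param x character vector of DNA strings; lengths must be multiples of 3.
#' @return character vector of amino-acid strings (`*` marks stop codons).
#' @keywords internal
translate_cds <- function(x) {
  stopifnot(all(nchar(x) %% 3 == 0))
  out <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x),
    genetic.code = Biostrings::GENETIC_CODE,
    no.init.codon = TRUE
  ))
  unname(out)
}

# Substring that tolerates out-of-range requests by clipping.
seq_slice <- function(seq, start, end) {
  start <- max(1L, start)
  end <- min(nchar(seq), end)
  if (end < start) return("")
  substr(seq, start, end)
}

# Apply an edit (replace [start,end] by `alt`; insertion when end < start)
# to a sequence string.
apply_edit <- function(seq, start, end, alt) {
  left <- if (start > 1) substr(seq, 1L, start - 1L) else ""
  right <- if (end < nchar(seq)) substr(seq, end + 1L, nchar(seq)) else ""
  paste0(left, alt, right)
}

trim_allele_pair <- function(ref, alt, pos) {
  # Remove shared suffix then shared prefix, moving pos past trimmed prefix.
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) > 0 && nchar(alt) > 0 &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(ref = ref, alt = alt, pos = pos)
}

# Left-align a pure insertion/deletion against a reference sequence string.
# Deletions: pos = first deleted base. Insertions: pos = base immediately 5'
# of the inserted sequence (0 allowed when the insertion lands before base 1).
shift_indel_left <- function(seq, pos, allele, is_del) {
  k <- nchar(allele)
  if (k == 0L) return(list(pos = pos, allele = allele))
  if (is_del) {
    while (pos > 1L && substr(seq, pos - 1L, pos - 1L) ==
           substr(allele, k, k)) {
      allele <- paste0(substr(seq, pos - 1L, pos - 1L),
                       substr(allele, 1L, k - 1L))
      pos <- pos - 1L
    }
  } else {
    while (pos >= 1L && substr(seq, pos, pos) == substr(allele, k, k)) {
      allele <- paste0(substr(seq, pos, pos), substr(allele, 1L, k - 1L))
      pos <- pos - 1L
    }
  }
  list(pos = pos, allele = allele)
}

# Right-shift (3'-shift) the same representation; used for HGVS-style naming
# on the transcript strand.
shift_indel_right <- function(seq, pos, allele, is_del) {
  k <- nchar(allele)
  if (k == 0L) return(list(pos = pos, allele = allele))
  n <- nchar(seq)
  if (is_del) {
    while (pos + k <= n && substr(seq, pos + k, pos + k) ==
           substr(allele, 1L, 1L)) {
      allele <- paste0(substr(allele, 2L, k), substr(seq, pos + k, pos + k))
      pos <- pos + 1L
    }
  } else {
    while (pos + 1L <= n && substr(seq, pos + 1L, pos + 1L) ==
           substr(allele, 1L, 1L)) {
      allele <- paste0(substr(allele, 2L, k), substr(seq, pos + 1L, pos + 1L))
      pos <- pos + 1L
    }
  }
  list(pos = pos, allele = allele)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

AA1 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q", Glu = "E",
  Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K", Met = "M", Phe = "F",
  Pro = "P", Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V", Ter = "*"
)
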