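#' Translate CDR3 nucleotide sequences
#'
#' Codon-wise translation under the standard genetic code. Stop codons are
#' rendered as `"*"`; a trailing partial codon (sequence length not a
#' multiple of 3, i.e. an out-of-frame junction) is rendered as a trailing
#' `"_"`. These are the marker conventions used by common V(D)J aligners,
#' and [filter_functional()] removes clonotypes carrying either marker.
#'
#' @param cdr3_nt Character vector of uppercase nucleotide sequences
#'   (`A`/`C`/`G`/`T` only).
#' @return Character vector of amino-acid sequences, same length as the
#'   input.
#' @examples
#' translate_cdr3(c("TGTGCC", "TGA", "TGTGC"))
#' @export
translate_cdr3 <- function(cdr3_nt) {
  if (!is.character(cdr3_nt)) {
    abort_tcr("`cdr3_nt` must be a character vector.", "tcrcomp_parse_error")
  }
  if (length(cdr3_nt) == 0) return(character(0))
  bad <- grepl("[^ACGT]", cdr3_nt)
  if (any(bad)) {
    abort_tcr(
      sprintf("Invalid nucleotide characters in sequence %d ('%s'); only A/C/G/T allowed.",
              which(bad)[1], cdr3_nt[which(bad)[1]]),
      "tcrcomp_parse_error"
    )
  }
  n <- nchar(cdr3_nt)
  k <- n %/% 3L
  rem <- n %% 3L
  out <- character(length(cdr3_nt))
  has_codons <- k > 0L
  if (any(has_codons)) {
    full <- substr(cdr3_nt[has_codons], 1L, 3L * k[has_codons])
    out[has_codons] <- as.character(
      Biostrings::translate(Biostrings::DNAStringSet(full),
                            no.init.codon = TRUE)
    )
  }
  out[rem > 0L] <- paste0(out[rem > 0L], "_")
  out
}

#' Normalize IMGT gene-segment names
#'
#' Strips allele suffixes (`*01`, `*00(score)` and similar) and surrounding
#' whitespace so that clonotype identity and segment-usage statistics work
#' at the gene level: `"TRBV20-1*01"` and `"TRBV20-1"` are the same gene.
#' Missing-value tokens (`"."`, `""`, `"NA"`, `NA`) map onto the canonical
#' [MISSING_SEGMENT] token.
#'
#' @param name Character vector of segment names.
#' @return Character vector of gene-level names.
#' @examples
#' normalize_segment_name(c("TRBV20-1*01", "TRAV26-1", "."))
#' @export
normalize_segment_name <- function(name) {
  x <- trimws(as.character(name))
  x <- sub("\\*.*$", "", x)
  missing <- is.na(x) | x == "" | x == "." | toupper(x) == "NA"
  x[missing] <- MISSING_SEGMENT
  x
}
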