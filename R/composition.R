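# Repertoire descriptors: amino-acid composition, positional occurrence,
# gene-segment usage, CDR3 length spectratype.
#
# All descriptors support two weightings:
#   diversity — each unique clonotype contributes weight 1 (the default,
#               matching clonotype/"diversity" percentages),
#   counts    — each clonotype contributes its UMI-derived molecule count.

check_nonempty <- function(x, what) {
  if (nrow(x$clonotypes) == 0) {
    abort_tcr(sprintf("Cannot compute %s on an empty repertoire.", what),
              "tcrcomp_empty_error")
  }
}

# Letters present in a CDR3 set that fall outside the 20 standard codes.
nonstandard_present <- function(cdr3_aa) {
  residues <- unique(strsplit(paste(cdr3_aa, collapse = ""), "")[[1]])
  setdiff(residues, AA_STANDARD)
}

#' Per-amino-acid CDR3 occurrence
#'
#' For each of the 20 standard amino acids, the percentage of clonotype
#' weight whose full CDR3 amino-acid sequence — conserved first C and last
#' F anchors included — contains at least one copy of that residue. This
#' containment metric does not sum to 100 across residues: a clonotype
#' containing both K and W contributes to both.
#'
#' Non-standard letters, should any survive functional filtering, are
#' tallied under a reserved `"other"` feature and reported via `message()`,
#' never silently dropped.
#'
#' @param x A functional-filtered, merged `tcr_repertoire`.
#' @param weighting `"diversity"` (default) or `"counts"`.
#' @return A tibble with the sample key plus `amino_acid` and `occurrence`
#'   (percent) columns.
#' @examples
#' r <- repertoire(tibble::tibble(
#'   cdr3_nt = c("TGTGCCAGCAGCTTC", "TGTGCCAAGAAGTTC"),
#'   cdr3_aa = c("CASSF", "CAKKF"),
#'   v_segment = "TRBV2", d_segment = ".", j_segment = "TRBJ2-1",
#'   count = c(1L, 1L), frequency = c(0.5, 0.5)))
#' aa_occurrence(r)
#' @export
aa_occurrence <- function(x, weighting = c("diversity", "counts")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(x, "tcr_repertoire"))
  check_nonempty(x, "amino-acid occurrence")
  w <- clonotype_weights(x, weighting)
  total <- sum(w)
  aa <- x$clonotypes$cdr3_aa
  letters_out <- AA_STANDARD
  occ <- vapply(AA_STANDARD, function(ltr) {
    100 * sum(w[grepl(ltr, aa, fixed = TRUE)]) / total
  }, numeric(1))
  extra <- nonstandard_present(aa)
  if (length(extra) > 0) {
    message(sprintf("Non-standard residue(s) %s counted under 'other'.",
                    paste(extra, collapse = ", ")))
    pat <- paste0("[", paste(gsub("([][\\^-])", "\\\\\\1", extra), collapse = ""), "]")
    occ <- c(occ, other = 100 * sum(w[grepl(pat, aa)]) / total)
    letters_out <- c(letters_out, "other")
  }
  dplyr::bind_cols(
    sample_key(x),
    tibble::tibble(weighting = weighting, amino_acid = letters_out,
                   occurrence = unname(occ))
  )
}

#' Percent change between group means
#'
#' Relative change of the case mean with respect to the control mean,
#' `100 * (case - control) / control`. A zero control mean with a positive
#' case mean has no defined relative change and yields `NA` (the explicit
#' undefined flag), never infinity or an error; both means zero yields 0.
#'
#' @param case_mean,control_mean Non-negative percentages (vectorized).
#' @return Signed percent change, `NA` where undefined.
#' @examples
#' percent_change(13, 8)  # +62.5
#' @export
percent_change <- function(case_mean, control_mean) {
  if (any(case_mean < 0, na.rm = TRUE) || any(control_mean < 0, na.rm = TRUE)) {
    abort_tcr("Means must be non-negative percentages.", "tcrcomp_domain_error")
  }
  out <- 100 * (case_mean - control_mean) / control_mean
  zero_ctrl <- !is.na(control_mean) & control_mean == 0
  out[zero_ctrl & case_mean > 0] <- NA_real_
  out[zero_ctrl & case_mean == 0] <- 0
  out
}

#' Positional CDR3 amino-acid occurrence
#'
#' Occurrence of each amino acid at each CDR3 position, numbered 1-based
#' from the conserved N-terminal cysteine in the N-to-C (5'-to-3')
#' direction, anchors included — so position 1 reports C at 100 percent for
#' anchor-conserved repertoires.
#'
#' By default the denominator is the whole repertoire weight: clonotypes
#' shorter than position `p` count as non-occurrence, which keeps profiles
#' comparable across repertoires with different length distributions and
#' makes the per-position sum over amino acids equal the percentage of
#' clonotype weight with CDR3 length at least `p`. With
#' `conditional = TRUE` the denominator is restricted to clonotypes of
#' length at least `p`.
#'
#' @param x A functional-filtered, merged `tcr_repertoire`.
#' @param weighting `"diversity"` or `"counts"`.
#' @param max_position Highest CDR3 position profiled.
#' @param conditional Use the length-conditional denominator.
#' @return A tibble with the sample key plus `position`, `amino_acid`,
#'   `occurrence` columns.
#' @export
positional_occurrence <- function(x, weighting = c("diversity", "counts"),
                                  max_position = 18, conditional = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(x, "tcr_repertoire"))
  if (!is.numeric(max_position) || max_position < 1) {
    abort_tcr("`max_position` must be >= 1.", "tcrcomp_domain_error")
  }
  max_position <- as.integer(max_position)
  check_nonempty(x, "positional occurrence")
  w <- clonotype_weights(x, weighting)
  total <- sum(w)
  aa <- x$clonotypes$cdr3_aa
  len <- nchar(aa)
  extra <- nonstandard_present(aa)
  letters_out <- c(AA_STANDARD, if (length(extra) > 0) "other")
  if (length(extra) > 0) {
    message(sprintf("Non-standard residue(s) %s counted under 'other'.",
                    paste(extra, collapse = ", ")))
  }
  rows <- purrr::map(seq_len(max_position), function(p) {
    ch <- substr(aa, p, p)
    denom <- if (conditional) sum(w[len >= p]) else total
    occ <- vapply(AA_STANDARD, function(ltr) {
      if (denom == 0) 0 else 100 * sum(w[ch == ltr]) / denom
    }, numeric(1))
    if (length(extra) > 0) {
      occ <- c(occ, other = if (denom == 0) 0 else
        100 * sum(w[ch %in% extra]) / denom)
    }
    tibble::tibble(position = p, amino_acid = letters_out,
                   occurrence = unname(occ))
  })
  dplyr::bind_cols(
    sample_key(x)[rep(1, max_position * length(letters_out)), ],
    tibble::tibble(weighting = weighting),
    dplyr::bind_rows(rows)
  )
}

#' Gene-segment usage
#'
#' Percentage of clonotype weight assigned to each V (or J) gene segment,
#' at gene level (allele suffixes pooled). Usage values sum to 100.
#'
#' @param x A functional-filtered, merged `tcr_repertoire`.
#' @param segment_class `"V"` or `"J"`.
#' @param weighting `"diversity"` or `"counts"`.
#' @return A tibble with the sample key plus `segment_class`, `segment`,
#'   `usage` columns, sorted by descending usage.
#' @export
segment_usage <- function(x, segment_class = c("V", "J"),
                          weighting = c("diversity", "counts")) {
  segment_class <- match.arg(segment_class)
  weighting <- match.arg(weighting)
  stopifnot(inherits(x, "tcr_repertoire"))
  check_nonempty(x, "segment usage")
  w <- clonotype_weights(x, weighting)
  seg <- normalize_segment_name(
    if (segment_class == "V") x$clonotypes$v_segment else x$clonotypes$j_segment
  )
  usage <- tapply(w, seg, sum) / sum(w) * 100
  out <- tibble::tibble(segment = names(usage), usage = as.numeric(usage))
  out <- dplyr::arrange(out, dplyr::desc(.data$usage), .data$segment)
  dplyr::bind_cols(
    sample_key(x)[rep(1, nrow(out)), ],
    tibble::tibble(weighting = weighting, segment_class = segment_class),
    out
  )
}

#' CDR3 length distribution (spectratype)
#'
#' Percentage of clonotype weight at each CDR3 amino-acid length; sums
#' to 100.
#'
#' @inheritParams segment_usage
#' @return A tibble with the sample key plus `length`, `percentage`
#'   columns.
#' @export
cdr3_length_distribution <- function(x, weighting = c("diversity", "counts")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(x, "tcr_repertoire"))
  check_nonempty(x, "CDR3 length distribution")
  w <- clonotype_weights(x, weighting)
  len <- nchar(x$clonotypes$cdr3_aa)
  pct <- tapply(w, len, sum) / sum(w) * 100
  dplyr::bind_cols(
    sample_key(x)[rep(1, length(pct)), ],
    tibble::tibble(weighting = weighting,
                   length = as.integer(names(pct)),
                   percentage = as.numeric(pct))
  )
}
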