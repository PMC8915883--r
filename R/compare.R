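#' Compare a repertoire descriptor between case and control donors
#'
#' End-to-end group contrast: computes the chosen descriptor for every
#' donor repertoire in one (subset, chain) stratum, then compares the case
#' and control arms feature-by-feature with [multiple_t_tests()] under
#' Holm-Sidak correction. The correction family is fixed by the
#' descriptor: all 20 standard amino acids for `"aa_occurrence"`, all
#' profiled positions of the queried amino acid for `"positional"`, and
#' all segments observed in the cohort for `"segment_usage"`.
#'
#' @param cohort List of merged, functional-filtered `tcr_repertoire`
#'   objects, all from one subset and chain, with at least two case and
#'   two control donors.
#' @param descriptor `"aa_occurrence"`, `"positional"` or
#'   `"segment_usage"`.
#' @param weighting `"diversity"` (default) or `"counts"`.
#' @param positional_aa Single amino-acid letter whose positional profile
#'   is compared (required for `descriptor = "positional"`).
#' @param max_position Number of CDR3 positions profiled in positional
#'   mode.
#' @param conditional Use the length-conditional positional denominator.
#' @param segment_class `"V"` or `"J"` for segment usage.
#' @param var_equal Pooled-variance t-tests if `TRUE` (default).
#' @param min_clonotypes Repertoires with fewer unique clonotypes are
#'   excluded from the comparison (reported via `message()`).
#' @return A tibble of per-feature comparisons ordered by adjusted
#'   p-value then feature, with attributes `subset`, `chain`,
#'   `descriptor`, `weighting`.
#' @export
compare_composition <- function(cohort,
                                descriptor = c("aa_occurrence", "positional",
                                               "segment_usage"),
                                weighting = c("diversity", "counts"),
                                positional_aa = NULL,
                                max_position = 18,
                                conditional = FALSE,
                                segment_class = "V",
                                var_equal = TRUE,
                                min_clonotypes = 50) {
  descriptor <- match.arg(descriptor)
  weighting <- match.arg(weighting)
  stopifnot(is.list(cohort),
            all(vapply(cohort, inherits, logical(1), "tcr_repertoire")))

  small <- vapply(cohort, diversity, integer(1)) < min_clonotypes
  if (any(small)) {
    message(sprintf(
      "Excluding %d repertoire(s) below the minimum of %d clonotypes: %s",
      sum(small), min_clonotypes,
      paste(vapply(cohort[small], function(r) r$donor_id, character(1)),
            collapse = ", ")))
    cohort <- cohort[!small]
  }
  strata <- unique(t(vapply(cohort, function(r) c(r$subset, r$chain),
                            character(2))))
  if (nrow(strata) > 1) {
    abort_tcr("Cohort mixes subsets or chains; compare one stratum at a time.",
              "tcrcomp_stratification_error")
  }
  conditions <- vapply(cohort, function(r) r$condition, character(1))
  if (sum(conditions == "case") < 2 || sum(conditions == "control") < 2) {
    abort_tcr("Need at least 2 case and 2 control repertoires.",
              "tcrcomp_replication_error")
  }

  donor_features <- function(r) {
    switch(descriptor,
      aa_occurrence = {
        prof <- aa_occurrence(r, weighting)
        prof <- prof[prof$amino_acid %in% AA_STANDARD, ]
        stats::setNames(prof$occurrence, prof$amino_acid)[AA_STANDARD]
      },
      positional = {
        if (is.null(positional_aa) || !positional_aa %in% AA_STANDARD) {
          abort_tcr("`positional_aa` must be a standard amino-acid letter.",
                    "tcrcomp_config_error")
        }
        prof <- positional_occurrence(r, weighting, max_position = max_position,
                                      conditional = conditional)
        prof <- prof[prof$amino_acid == positional_aa, ]
        stats::setNames(prof$occurrence,
                        sprintf("pos%02d:%s", prof$position, positional_aa))
      },
      segment_usage = {
        prof <- segment_usage(r, segment_class = segment_class,
                              weighting = weighting)
        stats::setNames(prof$usage, prof$segment)
      }
    )
  }

  values <- purrr::map(cohort, donor_features)
  features <- sort(unique(unlist(purrr::map(values, names))))
  mat <- do.call(rbind, purrr::map(values, function(v) {
    out <- stats::setNames(rep(0, length(features)), features)
    out[names(v)] <- v
    out
  }))
  case_values <- mat[conditions == "case", , drop = FALSE]
  control_values <- mat[conditions == "control", , drop = FALSE]

  out <- multiple_t_tests(case_values, control_values, var_equal = var_equal)
  out <- dplyr::arrange(out, .data$p_adj, .data$feature)
  attr(out, "subset") <- strata[1, 1]
  attr(out, "chain") <- strata[1, 2]
  attr(out, "descriptor") <- descriptor
  attr(out, "weighting") <- weighting
  out
}

#' Significance stars for a comparison report
#'
#' Stars mirror the usual figure-legend convention: `*` for adjusted
#' p below 0.05, `**` below 0.01.
#'
#' @param p_adj Numeric vector of adjusted p-values.
#' @param alpha Significance threshold for a single star.
#' @return Character vector of star annotations.
#' @export
significance_stars <- function(p_adj, alpha = 0.05) {
  dplyr::case_when(
    p_adj < alpha / 5 ~ "**",
    p_adj < alpha ~ "*",
    TRUE ~ ""
  )
}
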