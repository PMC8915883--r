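#' Construct a TCR repertoire
#'
#' A repertoire bundles a clonotype table with its sample metadata: donor,
#' T cell subset (CD4/CD8), receptor chain (TRA/TRB) and condition
#' (`"case"` = antigen-specific sorted cells, `"control"` = randomly sorted
#' cells from the same donor pool).
#'
#' @param clonotypes A data frame with columns `cdr3_nt`, `cdr3_aa`,
#'   `v_segment`, `d_segment`, `j_segment`, `count`, `frequency`.
#' @param donor_id Donor label.
#' @param subset `"CD4"` or `"CD8"` (or `NA`).
#' @param chain `"TRA"` or `"TRB"` (or `NA`).
#' @param condition `"case"` or `"control"` (or `NA`).
#' @return An object of class `tcr_repertoire`.
#' @seealso [diversity()], [total_count()], [merge_clonotypes()],
#'   [filter_functional()]
#' @export
repertoire <- function(clonotypes,
                       donor_id = NA_character_,
                       subset = NA_character_,
                       chain = NA_character_,
                       condition = NA_character_) {
  required <- c("cdr3_nt", "cdr3_aa", "v_segment", "d_segment", "j_segment",
                "count", "frequency")
  missing_cols <- setdiff(required, names(clonotypes))
  if (length(missing_cols) > 0) {
    abort_tcr(
      paste0("Clonotype table is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      "tcrcomp_format_error"
    )
  }
  clonotypes <- tibble::as_tibble(clonotypes)[required]
  if (nrow(clonotypes) > 0) {
    if (any(!is.finite(clonotypes$count) | clonotypes$count < 1 |
            clonotypes$count != round(clonotypes$count))) {
      abort_tcr("Clonotype counts must be positive integers.",
                "tcrcomp_parse_error")
    }
  }
  check_level <- function(value, levels, what) {
    if (!is.na(value) && !value %in% levels) {
      abort_tcr(sprintf("`%s` must be one of %s (got '%s').",
                        what, paste(levels, collapse = "/"), value),
                "tcrcomp_format_error")
    }
    as.character(value)
  }
  structure(
    list(
      donor_id = as.character(donor_id),
      subset = check_level(subset, c("CD4", "CD8"), "subset"),
      chain = check_level(chain, c("TRA", "TRB"), "chain"),
      condition = check_level(condition, c("case", "control"), "condition"),
      clonotypes = clonotypes
    ),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf(
    "<tcr_repertoire> donor=%s subset=%s chain=%s condition=%s\n",
    x$donor_id, x$subset, x$chain, x$condition
  ))
  cat(sprintf("  clonotypes (diversity): %d   molecules (counts): %s\n",
              diversity(x),
              format(total_count(x), big.mark = ",")))
  print(utils::head(x$clonotypes, 5), ...)
  if (nrow(x$clonotypes) > 5) {
    cat(sprintf("  ... and %d more clonotypes\n", nrow(x$clonotypes) - 5))
  }
  invisible(x)
}

#' Repertoire diversity (number of unique clonotypes)
#'
#' In repertoire sequencing the number of unique clonotypes is conventionally
#' called "diversity", as opposed to "counts" (total UMI-derived molecule
#' number, see [total_count()]). Analyses in this package default to
#' diversity weighting.
#'
#' @param x A `tcr_repertoire`.
#' @return Integer scalar.
#' @export
diversity <- function(x) {
  stopifnot(inherits(x, "tcr_repertoire"))
  nrow(x$clonotypes)
}

#' Total molecule count of a repertoire
#'
#' @param x A `tcr_repertoire`.
#' @return Numeric scalar: sum of clonotype counts.
#' @export
total_count <- function(x) {
  stopifnot(inherits(x, "tcr_repertoire"))
  sum(x$clonotypes$count)
}

# Coerce repertoire-or-tibble input to a clonotype tibble; returns list of
# (records, meta) so operations can round-trip metadata.
as_clonotype_records <- function(x) {
  if (inherits(x, "tcr_repertoire")) {
    list(records = x$clonotypes,
         meta = x[c("donor_id", "subset", "chain", "condition")])
  } else if (is.data.frame(x)) {
    list(records = tibble::as_tibble(x),
         meta = list(donor_id = NA_character_, subset = NA_character_,
                     chain = NA_character_, condition = NA_character_))
  } else {
    abort_tcr("Expected a `tcr_repertoire` or a clonotype data frame.",
              "tcrcomp_format_error")
  }
}

rebuild_repertoire <- function(records, meta) {
  repertoire(records, donor_id = meta$donor_id, subset = meta$subset,
             chain = meta$chain, condition = meta$condition)
}

# Sample weights under the chosen weighting scheme.
clonotype_weights <- function(x, weighting = c("diversity", "counts")) {
  weighting <- match.arg(weighting)
  if (weighting == "diversity") rep(1, nrow(x$clonotypes))
  else as.numeric(x$clonotypes$count)
}

sample_key <- function(x) {
  tibble::tibble(donor_id = x$donor_id, subset = x$subset,
                 chain = x$chain, condition = x$condition)
}
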