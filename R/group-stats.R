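# Group statistics: per-feature t-tests with step-down Holm-Sidak
# correction, and classical two-way ANOVA.

#' Holm-Sidak step-down multiple-testing adjustment
#'
#' Family-wise error control by the step-down procedure built on the Sidak
#' inequality: with the p-values sorted ascending, the i-th (of m) is
#' adjusted to `1 - (1 - p_(i))^(m - i + 1)`, then a cumulative maximum
#' enforces monotonicity. Values are returned in the input order.
#'
#' This is the "Holm-Sidak" correction of common biostatistics software; it
#' is uniformly no larger than the Holm(-Bonferroni) adjustment and no
#' smaller than the raw p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' holm_sidak_adjust(c(0.01, 0.04))
#' @export
holm_sidak_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_tcr("p-values must lie in [0, 1] and contain no NA.",
              "tcrcomp_domain_error")
  }
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- cummax(pmin(1, 1 - (1 - ps)^(m - seq_len(m) + 1)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Two-sample t-test p-value with the degenerate-variance conventions used
# for descriptor families: both arms constant and equal -> p = 1 (feature
# kept in the family rather than dropped as NaN); both arms constant and
# different -> p = 0.
two_sample_p <- function(x, y, var_equal = TRUE) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    message(sprintf("Zero variance in both arms; p set to %d by convention.",
                    if (equal) 1L else 0L))
    return(if (equal) 1 else 0)
  }
  stats::t.test(x, y, var.equal = var_equal)$p.value
}

percent_change_safe <- function(case_mean, control_mean) {
  if (is.na(case_mean) || is.na(control_mean) ||
      case_mean < 0 || control_mean < 0) return(NA_real_)
  percent_change(case_mean, control_mean)
}

#' Per-feature two-sample t-tests with Holm-Sidak correction
#'
#' Runs one two-sample t-test per feature (column) between the case and
#' control donor arms, then adjusts the whole family of p-values with
#' [holm_sidak_adjust()]. The family is exactly the feature set passed in
#' (for CDR3 composition, the 20 standard amino acids), so correction
#' boundaries are explicit.
#'
#' @param case_values,control_values Numeric matrices or data frames, one
#'   row per donor and one named column per feature. The two feature sets
#'   must be identical.
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch if
#'   `FALSE`.
#' @return A tibble with one row per feature: `feature`, `case_mean`,
#'   `control_mean`, `case_n`, `control_n`, `difference` (percentage
#'   points), `percent_change` (`NA` when undefined), `p_raw`, `p_adj`.
#' @export
multiple_t_tests <- function(case_values, control_values, var_equal = TRUE) {
  cv <- as.matrix(case_values)
  kv <- as.matrix(control_values)
  if (is.null(colnames(cv)) || is.null(colnames(kv))) {
    abort_tcr("Feature columns must be named.", "tcrcomp_format_error")
  }
  if (!setequal(colnames(cv), colnames(kv))) {
    abort_tcr("Case and control feature sets differ.",
              "tcrcomp_format_error")
  }
  kv <- kv[, colnames(cv), drop = FALSE]
  features <- colnames(cv)
  res <- purrr::map(features, function(f) {
    x <- cv[, f][!is.na(cv[, f])]
    y <- kv[, f][!is.na(kv[, f])]
    if (length(x) < 2 || length(y) < 2) {
      abort_tcr(
        sprintf("Feature '%s' has fewer than 2 donors in one arm.", f),
        "tcrcomp_replication_error"
      )
    }
    tibble::tibble(
      feature = f,
      case_mean = mean(x), control_mean = mean(y),
      case_n = length(x), control_n = length(y),
      difference = mean(x) - mean(y),
      percent_change = percent_change_safe(mean(x), mean(y)),
      p_raw = two_sample_p(x, y, var_equal)
    )
  })
  out <- dplyr::bind_rows(res)
  out$p_adj <- holm_sidak_adjust(out$p_raw)
  out
}

#' Two-way analysis of variance
#'
#' Classical two-factor ANOVA with interaction, decomposing the response
#' sum of squares into the two main effects, their interaction and a
#' residual, with F tests against the residual mean square. For balanced
#' complete layouts this is the textbook decomposition (factor, interaction
#' and residual sums of squares add up to the total). With a single
#' replicate per cell the interaction is not estimable and an additive
#' model is fitted with a warning; an empty cell is a design error.
#'
#' @param data A data frame.
#' @param response,factor_a,factor_b Column names (strings) of the numeric
#'   response and the two crossed factors.
#' @return A tibble with one row per term (`factor_a`, `factor_b`,
#'   interaction where estimable, `Residuals`): `term`, `df`, `sum_sq`,
#'   `mean_sq`, `statistic`, `p_value`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b) {
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) {
      abort_tcr(sprintf("Column '%s' not found in `data`.", col),
                "tcrcomp_format_error")
    }
  }
  df <- data.frame(
    y = as.numeric(data[[response]]),
    a = factor(data[[factor_a]]),
    b = factor(data[[factor_b]])
  )
  df <- df[stats::complete.cases(df), ]
  cells <- table(df$a, df$b)
  if (any(cells == 0)) {
    abort_tcr("Every factor-level combination needs at least one observation.",
              "tcrcomp_design_error")
  }
  with_interaction <- any(cells >= 2)
  if (!with_interaction) {
    rlang::warn("One replicate per cell: interaction not estimable, fitting additive model.")
  }
  form <- if (with_interaction) y ~ a * b else y ~ a + b
  tab <- stats::anova(stats::lm(form, data = df))
  term_names <- rownames(tab)
  term_names[term_names == "a"] <- factor_a
  term_names[term_names == "b"] <- factor_b
  term_names[term_names == "a:b"] <- paste0(factor_a, ":", factor_b)
  tibble::tibble(
    term = term_names,
    df = tab$Df,
    sum_sq = tab$`Sum Sq`,
    mean_sq = tab$`Mean Sq`,
    statistic = tab$`F value`,
    p_value = tab$`Pr(>F)`
  )
}
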