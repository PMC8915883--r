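# Brute-force oracles and ad-hoc data generators used across the suite.
# Oracles are written as literal loops, independent of the package's
# vectorized implementations.

# --- ad-hoc random clonotype records (independent of the simulator) -------

SENSE_CODONS <- {
  code <- Biostrings::GENETIC_CODE
  names(code[code != "*"])
}

random_records <- function(n, n_segments = 4, with_nonfunctional = TRUE) {
  v <- paste0("TRBV", seq_len(n_segments))
  j <- paste0("TRBJ", seq_len(n_segments))
  rows <- lapply(seq_len(n), function(i) {
    k <- sample(2:6, 1)
    nt <- paste(sample(SENSE_CODONS, k, replace = TRUE), collapse = "")
    if (with_nonfunctional && runif(1) < 0.15) {
      nt <- paste0(nt, sample(c("TAA", "TG"), 1))  # stop or frameshift tail
    }
    data.frame(
      cdr3_nt = nt,
      cdr3_aa = tcrcomp::translate_cdr3(nt),
      v_segment = sample(v, 1),
      d_segment = ".",
      j_segment = sample(j, 1),
      count = sample(1:20, 1),
      frequency = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tibble::as_tibble(do.call(rbind, rows))
}

random_repertoire <- function(n, ...) {
  recs <- random_records(n, ...)
  tcrcomp::repertoire(recs, donor_id = "oracle", subset = "CD4",
                      chain = "TRB", condition = "control")
}

# --- clonotype collapsing / filtering oracles -----------------------------

oracle_merge <- function(records) {
  groups <- list()
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    placed <- FALSE
    for (g in seq_along(groups)) {
      ref <- groups[[g]]
      if (ref$v_segment == row$v_segment && ref$d_segment == row$d_segment &&
          ref$j_segment == row$j_segment && ref$cdr3_nt == row$cdr3_nt) {
        stopifnot(ref$cdr3_aa == row$cdr3_aa)
        groups[[g]]$count <- ref$count + row$count
        placed <- TRUE
        break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- as.list(row)
  }
  out <- do.call(rbind, lapply(groups, as.data.frame))
  out$frequency <- out$count / sum(out$count)
  out[order(-out$count, out$cdr3_nt, out$v_segment, method = "radix"), ]
}

oracle_filter <- function(records, markers = c("*", "_")) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    chars <- strsplit(records$cdr3_aa[i], "")[[1]]
    keep[i] <- !any(chars %in% markers)
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) > 0) out$frequency <- out$count / sum(out$count)
  out
}

# --- descriptor oracles (literal loops over clonotypes and characters) ----

oracle_weights <- function(records, weighting) {
  if (weighting == "diversity") rep(1, nrow(records)) else records$count
}

oracle_aa_occurrence <- function(records, weighting) {
  w <- oracle_weights(records, weighting)
  sapply(tcrcomp::AA_STANDARD, function(letter) {
    num <- 0
    for (i in seq_len(nrow(records))) {
      chars <- strsplit(records$cdr3_aa[i], "")[[1]]
      if (letter %in% chars) num <- num + w[i]
    }
    100 * num / sum(w)
  })
}

oracle_positional <- function(records, weighting, max_position,
                              conditional = FALSE) {
  w <- oracle_weights(records, weighting)
  out <- matrix(0, nrow = max_position, ncol = length(tcrcomp::AA_STANDARD),
                dimnames = list(NULL, tcrcomp::AA_STANDARD))
  for (p in seq_len(max_position)) {
    denom <- if (conditional) {
      d <- 0
      for (i in seq_len(nrow(records))) {
        if (nchar(records$cdr3_aa[i]) >= p) d <- d + w[i]
      }
      d
    } else sum(w)
    for (letter in tcrcomp::AA_STANDARD) {
      num <- 0
      for (i in seq_len(nrow(records))) {
        chars <- strsplit(records$cdr3_aa[i], "")[[1]]
        if (length(chars) >= p && chars[p] == letter) num <- num + w[i]
      }
      out[p, letter] <- if (denom == 0) 0 else 100 * num / denom
    }
  }
  out
}

oracle_segment_usage <- function(records, segment_class, weighting) {
  w <- oracle_weights(records, weighting)
  seg <- if (segment_class == "V") records$v_segment else records$j_segment
  out <- list()
  for (i in seq_along(seg)) {
    s <- seg[i]
    out[[s]] <- (out[[s]] %||% 0) + w[i]
  }
  vapply(out, function(v) 100 * v / sum(w), numeric(1))
}

oracle_length_distribution <- function(records, weighting) {
  w <- oracle_weights(records, weighting)
  out <- list()
  for (i in seq_len(nrow(records))) {
    l <- as.character(nchar(records$cdr3_aa[i]))
    out[[l]] <- (out[[l]] %||% 0) + w[i]
  }
  vapply(out, function(v) 100 * v / sum(w), numeric(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- statistics oracles ---------------------------------------------------

# Step-down Sidak by the explicit formula, loop form.
oracle_holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running_max <- 0
  for (i in seq_len(m)) {
    step <- min(1, 1 - (1 - p[o[i]])^(m - i + 1))
    running_max <- max(running_max, step)
    adj[o[i]] <- running_max
  }
  adj
}

# Pooled two-sample t-test p-value from the closed-form statistic.
oracle_pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# Literal sums-of-squares decomposition for a balanced two-factor layout
# with replication.
oracle_anova2 <- function(y, a, b) {
  a <- as.character(a); b <- as.character(b)
  grand <- mean(y)
  ss_a <- 0
  for (lv in unique(a)) ss_a <- ss_a + sum(a == lv) * (mean(y[a == lv]) - grand)^2
  ss_b <- 0
  for (lv in unique(b)) ss_b <- ss_b + sum(b == lv) * (mean(y[b == lv]) - grand)^2
  ss_ab <- 0
  ss_res <- 0
  for (la in unique(a)) {
    for (lb in unique(b)) {
      cell <- y[a == la & b == lb]
      cm <- mean(cell)
      ss_ab <- ss_ab + length(cell) *
        (cm - mean(y[a == la]) - mean(y[b == lb]) + grand)^2
      ss_res <- ss_res + sum((cell - cm)^2)
    }
  }
  list(ss_a = ss_a, ss_b = ss_b, ss_ab = ss_ab, ss_res = ss_res,
       ss_total = sum((y - grand)^2))
}

# --- misc -----------------------------------------------------------------

# Reverse the genetic code for round-trip checks: any codon choice per
# residue.
backtranslate_random <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  paste(vapply(strsplit(aa, "")[[1]],
               function(ch) sample(by_aa[[ch]], 1), character(1)),
        collapse = "")
}
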