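# Internal helpers: typed conditions, stable hashing, scoped RNG.

abort_tcr <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "tcrcomp_error"), ...)
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-donor random streams from (root seed, donor, condition) and to digest
# configurations for provenance headers. Stable across platforms and R
# sessions; not cryptographic.
stable_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "\r")
  h <- 0
  for (i in utf8ToInt(s)) h <- (h * 131 + i) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x
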