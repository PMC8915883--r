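# Synthetic V(D)J repertoire generator.
#
# Clonotypes are assembled at the nucleotide level as
#   germline V flank + random junctional insertion + germline J flank,
# so the conserved CDR3 anchors (N-terminal C from the V segment,
# C-terminal F from the J segment) and the nucleotide/protein consistency
# invariant hold by construction. Insertions are drawn codon-wise from the
# 61 sense codons, keeping intended-functional rearrangements free of
# incidental stops; a configurable fraction is then deliberately disrupted
# (stop-codon substitution or single-nucleotide frameshift).

codon_tables <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) {
      code <- Biostrings::GENETIC_CODE
      sense <- code[code != "*"]
      gc <<- list(
        sense_codons = names(sense),
        sense_aa = unname(sense),
        stop_codons = names(code[code == "*"]),
        by_aa = split(names(sense), unname(sense))
      )
    }
    gc
  }
})

paste_codon_groups <- function(pieces, group, n) {
  f <- factor(group, levels = seq_len(n))
  vapply(split(pieces, f), paste, character(1), collapse = "")
}

#' Default germline segment pools for the simulator
#'
#' Small synthetic pools of V and J segments with Zipf-like sampling
#' weights. Each V flank begins with a cysteine codon and each J flank ends
#' with a phenylalanine codon, emulating the conserved CDR3 anchors.
#' Segment names follow IMGT style so downstream gene-level normalization
#' and usage statistics behave as with real data; the germline flank
#' sequences themselves are synthetic, not IMGT reference sequences.
#'
#' @param chain `"TRB"` or `"TRA"`.
#' @return A tibble with columns `segment`, `weight`, `flank_nt`,
#'   `flank_aa`.
#' @name segment_pools
NULL

#' @rdname segment_pools
#' @export
default_v_pool <- function(chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  if (chain == "TRB") {
    segment <- c("TRBV2", "TRBV4-1", "TRBV5-1", "TRBV6-2", "TRBV7-9",
                 "TRBV9", "TRBV11-2", "TRBV12-3", "TRBV15", "TRBV19",
                 "TRBV20-1", "TRBV27", "TRBV28", "TRBV29-1", "TRBV30")
    flank_nt <- c("TGTGCCAGCAGT", "TGTGCCAGCAGC", "TGCGCCAGCAGC",
                  "TGTGCCAGCAGA", "TGTGCCAGCAGG", "TGTGCCAGC",
                  "TGTGCCACCAGC", "TGCAGTGCTAGA", "TGTGCCACCTCC",
                  "TGTGCCAGTACC", "TGCAGTGCC", "TGTGCCAGCTCC",
                  "TGTGCCAGCGGC", "TGCAGCGTC", "TGTGCCTCC")
  } else {
    segment <- c("TRAV1-2", "TRAV8-4", "TRAV12-2", "TRAV13-1", "TRAV17",
                 "TRAV19", "TRAV21", "TRAV26-1", "TRAV29", "TRAV35",
                 "TRAV38-1", "TRAV8-6", "TRAV9-2", "TRAV12-1", "TRAV41")
    flank_nt <- c("TGTGCTGTG", "TGTGCCGTGAGC", "TGTGCCGTG", "TGTGCAGCA",
                  "TGTGCTACG", "TGTGCCCTG", "TGTGCAGTC", "TGCATCGTC",
                  "TGTGCAGCAAGC", "TGTGCAGGG", "TGTGCTTTCATG",
                  "TGTGCCGTC", "TGTGCTCTG", "TGTGTGGTG", "TGTGCTGTC")
  }
  tibble::tibble(
    segment = segment,
    weight = 1 / seq_along(segment),
    flank_nt = flank_nt,
    flank_aa = translate_cdr3(flank_nt)
  )
}

#' @rdname segment_pools
#' @export
default_j_pool <- function(chain = c("TRB", "TRA")) {
  chain <- match.arg(chain)
  if (chain == "TRB") {
    segment <- c("TRBJ1-1", "TRBJ1-2", "TRBJ1-4", "TRBJ1-5", "TRBJ1-6",
                 "TRBJ2-1", "TRBJ2-2", "TRBJ2-3", "TRBJ2-5", "TRBJ2-7")
    flank_nt <- c("ACCGAGGCCTTC", "TACACCTTT", "AACGAGCAGTTC",
                  "CAGCCCCAGTTT", "AGCCCTCTGTTC", "GAGCAGTTC",
                  "GGCGAGCTGTTT", "ACCCAGTACTTC", "GAGACCCAGTTC",
                  "TACGAGCAGTTC")
  } else {
    segment <- c("TRAJ4", "TRAJ9", "TRAJ16", "TRAJ23", "TRAJ29",
                 "TRAJ33", "TRAJ39", "TRAJ45", "TRAJ49", "TRAJ53")
    flank_nt <- c("AGCGGCTTC", "GGCAACACCTTT", "AGCGATGGCTTC",
                  "TACAACCAGTTC", "AACACCCCTTTC", "GATAGCAACTTT",
                  "AACAACGCCTTC", "GGAGGAGCTTTT", "ACCGGGAACTTC",
                  "AGCAGCAACTTT")
  }
  tibble::tibble(
    segment = segment,
    weight = 1 / seq_along(segment),
    flank_nt = flank_nt,
    flank_aa = translate_cdr3(flank_nt)
  )
}

#' Specify a case-versus-control enrichment effect
#'
#' Describes a feature whose occurrence is to be raised by `effect`
#' percentage points in case repertoires relative to the control-generative
#' baseline, emulating antigen-driven repertoire skews such as an
#' overrepresented amino acid, a position-specific residue preference, or a
#' favored gene segment.
#'
#' @param mode `"containment"` (raise the fraction of clonotypes whose CDR3
#'   contains the target amino acid anywhere), `"positional"` (raise the
#'   fraction with the target residue at a fixed CDR3 position), or
#'   `"segment_usage"` (raise the usage of a target gene segment).
#' @param target Amino-acid letter (containment/positional) or segment name
#'   (segment_usage).
#' @param position 1-based CDR3 position, counted from the conserved
#'   N-terminal cysteine; positional mode only. Anchor positions cannot be
#'   targeted (position must be >= 2 and the substitution never touches the
#'   terminal residue).
#' @param effect Occurrence increase in percentage points (0 < effect <=
#'   100).
#' @return An object of class `tcr_enrichment`.
#' @export
enrichment <- function(mode = c("containment", "positional", "segment_usage"),
                       target, position = NULL, effect) {
  mode <- match.arg(mode)
  if (!is.numeric(effect) || length(effect) != 1 || effect <= 0 ||
      effect > 100) {
    abort_tcr("`effect` must be a single value in (0, 100].",
              "tcrcomp_config_error")
  }
  if (mode %in% c("containment", "positional") &&
      !(is.character(target) && nchar(target) == 1 && target %in% AA_STANDARD)) {
    abort_tcr("`target` must be a single standard amino-acid letter.",
              "tcrcomp_config_error")
  }
  if (mode == "positional") {
    if (is.null(position) || !is.numeric(position) || position < 1) {
      abort_tcr("Positional enrichment needs `position` >= 1.",
                "tcrcomp_config_error")
    }
    if (position < 2) {
      abort_tcr("Positional enrichment cannot target the conserved anchor at position 1.",
                "tcrcomp_config_error")
    }
  }
  structure(list(mode = mode, target = target,
                 position = if (is.null(position)) NA_integer_ else as.integer(position),
                 effect = effect),
            class = "tcr_enrichment")
}

#' Configure a synthetic repertoire simulation
#'
#' Defines the generative law of a donor cohort: segment pools with
#' Zipf-like weights, geometric junctional insertion lengths (in whole
#' codons, mean `insertion_mean_nt` nucleotides), a discrete power-law
#' clone-size distribution, a fixed rate of non-functional rearrangements,
#' Dirichlet-style per-donor jitter of segment-usage weights, and optional
#' case-arm [enrichment()] effects.
#'
#' @param n_donors_case,n_donors_control Donors per arm.
#' @param clonotypes_per_repertoire Number of rearrangements drawn per
#'   donor (unique clonotypes can be slightly fewer if independent draws
#'   collide and are merged).
#' @param chain `"TRB"` or `"TRA"`.
#' @param subset `"CD4"` or `"CD8"`; metadata carried into the generated
#'   repertoires.
#' @param v_pool,j_pool Segment pools (see [default_v_pool()]).
#' @param insertion_mean_nt Mean junctional insertion length in
#'   nucleotides; insertions are drawn as whole codons with a geometric
#'   codon count.
#' @param nonfunctional_rate Fraction of rearrangements disrupted by a stop
#'   codon or frameshift, in `[0, 1]`.
#' @param clone_size_exponent,clone_size_max Discrete power law
#'   `P(k) ~ k^-exponent` on `1..clone_size_max` for clone sizes.
#' @param donor_usage_noise Dirichlet concentration for per-donor segment
#'   weight jitter; larger values mean less donor-to-donor variability.
#' @param enrichments List of [enrichment()] specs applied to case donors.
#' @param seed Root seed; per-donor streams are derived by stable hashing
#'   of (seed, donor, condition), so adding a donor never perturbs other
#'   donors' draws.
#' @return An object of class `tcr_simulation_config`.
#' @export
simulation_config <- function(n_donors_case = 5,
                              n_donors_control = 5,
                              clonotypes_per_repertoire = 2000,
                              chain = c("TRB", "TRA"),
                              subset = c("CD4", "CD8"),
                              v_pool = NULL,
                              j_pool = NULL,
                              insertion_mean_nt = 6,
                              nonfunctional_rate = 0.1,
                              clone_size_exponent = 2.5,
                              clone_size_max = 10000,
                              donor_usage_noise = 50,
                              enrichments = list(),
                              seed = 1L) {
  chain <- match.arg(chain)
  subset <- match.arg(subset)
  v_pool <- v_pool %||% default_v_pool(chain)
  j_pool <- j_pool %||% default_j_pool(chain)
  check_pool <- function(pool, what, anchor) {
    if (any(pool$weight < 0) || all(pool$weight == 0)) {
      abort_tcr(sprintf("%s pool weights must be non-negative with at least one positive.", what),
                "tcrcomp_config_error")
    }
    aa <- translate_cdr3(pool$flank_nt)
    ok <- if (anchor == "C") startsWith(aa, "C") else endsWith(aa, "F")
    if (!all(ok)) {
      abort_tcr(sprintf("Every %s flank must translate to a peptide %s.", what,
                        if (anchor == "C") "starting with C" else "ending with F"),
                "tcrcomp_config_error")
    }
  }
  check_pool(v_pool, "V", "C")
  check_pool(j_pool, "J", "F")
  if (nonfunctional_rate < 0 || nonfunctional_rate > 1) {
    abort_tcr("`nonfunctional_rate` must lie in [0, 1].", "tcrcomp_config_error")
  }
  if (!all(vapply(enrichments, inherits, logical(1), "tcr_enrichment"))) {
    abort_tcr("`enrichments` must be a list of enrichment() specs.",
              "tcrcomp_config_error")
  }
  structure(
    list(
      n_donors_case = as.integer(n_donors_case),
      n_donors_control = as.integer(n_donors_control),
      clonotypes_per_repertoire = as.integer(clonotypes_per_repertoire),
      chain = chain, subset = subset,
      v_pool = v_pool, j_pool = j_pool,
      insertion_mean_nt = insertion_mean_nt,
      nonfunctional_rate = nonfunctional_rate,
      clone_size_exponent = clone_size_exponent,
      clone_size_max = as.integer(clone_size_max),
      donor_usage_noise = donor_usage_noise,
      enrichments = enrichments,
      seed = as.integer(seed)
    ),
    class = "tcr_simulation_config"
  )
}

jitter_weights <- function(weights, concentration) {
  base <- weights / sum(weights)
  if (!is.finite(concentration) || concentration <= 0) return(base)
  shape <- concentration * base
  draw <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(draw) == 0) base else draw / sum(draw)
}

#' Simulate one donor repertoire
#'
#' Draws `clonotypes_per_repertoire` V(D)J rearrangements under the
#' configured generative law, applies the configured fraction of
#' non-functional disruptions, applies case-arm enrichment effects, draws
#' clone sizes, and collapses the result with [merge_clonotypes()].
#'
#' Enrichment effects are realized on the merged (unique-clonotype) table:
#' an exactly-sized random subset of functional clonotypes that do not yet
#' show the target feature is substituted, so the realized
#' diversity-weighted case occurrence exceeds the control-generative
#' occurrence by approximately `effect` percentage points in expectation.
#' The substitution rewrites the codon in `cdr3_nt` as well, preserving
#' nucleotide/protein consistency, and never duplicates an existing
#' clonotype key.
#'
#' @param config A [simulation_config()].
#' @param donor_id Donor label.
#' @param condition `"case"` or `"control"`; enrichments apply to case
#'   only.
#' @param seed Optional stream seed; by default derived by stable hashing
#'   of (config seed, donor, condition).
#' @return A `tcr_repertoire`.
#' @export
simulate_repertoire <- function(config, donor_id, condition = c("control", "case"),
                                seed = NULL) {
  stopifnot(inherits(config, "tcr_simulation_config"))
  condition <- match.arg(condition)
  stream_seed <- seed %||% stable_hash(config$seed, donor_id, condition)
  ct <- codon_tables()
  n <- config$clonotypes_per_repertoire
  with_seed(stream_seed, {
    vw <- jitter_weights(config$v_pool$weight, config$donor_usage_noise)
    jw <- jitter_weights(config$j_pool$weight, config$donor_usage_noise)
    v_idx <- sample.int(nrow(config$v_pool), n, replace = TRUE, prob = vw)
    j_idx <- sample.int(nrow(config$j_pool), n, replace = TRUE, prob = jw)
    mean_codons <- config$insertion_mean_nt / 3
    ins_k <- stats::rgeom(n, prob = 1 / (1 + mean_codons))
    draws <- sample.int(length(ct$sense_codons), sum(ins_k), replace = TRUE)
    grp <- rep.int(seq_len(n), ins_k)
    ins_nt <- paste_codon_groups(ct$sense_codons[draws], grp, n)
    ins_aa <- paste_codon_groups(ct$sense_aa[draws], grp, n)
    nf <- stats::runif(n) < config$nonfunctional_rate

    cdr3_nt <- paste0(config$v_pool$flank_nt[v_idx], ins_nt,
                      config$j_pool$flank_nt[j_idx])
    cdr3_aa <- paste0(config$v_pool$flank_aa[v_idx], ins_aa,
                      config$j_pool$flank_aa[j_idx])

    # non-functional disruptions: half stop-codon substitutions, half
    # single-nucleotide frameshifts
    nf_idx <- which(nf)
    if (length(nf_idx) > 0) {
      is_stop <- stats::runif(length(nf_idx)) < 0.5
      si <- nf_idx[is_stop]
      if (length(si) > 0) {
        L <- nchar(cdr3_aa[si])
        q <- 2L + floor(stats::runif(length(si)) * (L - 2L))
        stop_codon <- sample(ct$stop_codons, length(si), replace = TRUE)
        substr(cdr3_nt[si], 3L * q - 2L, 3L * q) <- stop_codon
        substr(cdr3_aa[si], q, q) <- "*"
      }
      fi <- nf_idx[!is_stop]
      if (length(fi) > 0) {
        L <- nchar(cdr3_aa[fi])
        cdr3_nt[fi] <- substr(cdr3_nt[fi], 1L, nchar(cdr3_nt[fi]) - 1L)
        cdr3_aa[fi] <- paste0(substr(cdr3_aa[fi], 1L, L - 1L), "_")
      }
    }

    sizes <- sample.int(config$clone_size_max, n, replace = TRUE,
                        prob = seq_len(config$clone_size_max)^(-config$clone_size_exponent))
    records <- tibble::tibble(
      cdr3_nt = cdr3_nt,
      cdr3_aa = cdr3_aa,
      v_segment = config$v_pool$segment[v_idx],
      d_segment = MISSING_SEGMENT,
      j_segment = config$j_pool$segment[j_idx],
      count = sizes,
      frequency = NA_real_
    )
    rep <- merge_clonotypes(repertoire(records, donor_id = donor_id,
                                       subset = config$subset,
                                       chain = config$chain,
                                       condition = condition))
    # enrichments act on the merged (unique-clonotype) table, since the
    # realized effect is defined on diversity-weighted occurrence
    if (condition == "case" && length(config$enrichments) > 0) {
      cl <- rep$clonotypes
      for (spec in config$enrichments) {
        cl <- apply_enrichment(cl, spec, config, ct)
      }
      rep <- merge_clonotypes(repertoire(cl, donor_id = donor_id,
                                         subset = config$subset,
                                         chain = config$chain,
                                         condition = condition))
    }
    attr(rep, "stream_seed") <- stream_seed
    rep
  })
}

# Apply one enrichment spec to a merged clonotype table (case arm only).
# An exactly-sized random subset of functional clonotypes lacking the
# target feature is modified; cdr3_nt is rewritten along with cdr3_aa so
# the translation invariant holds. A proposed substitution that would
# duplicate an existing clonotype key is rejected and replaced by a fresh
# candidate, so the realized unique-clonotype occurrence tracks the
# requested effect instead of being eroded by merge collisions.
apply_enrichment <- function(cl, spec, config, ct) {
  func <- !grepl("*", cl$cdr3_aa, fixed = TRUE) &
    !grepl("_", cl$cdr3_aa, fixed = TRUE)
  n_func <- sum(func)
  k <- round(spec$effect / 100 * n_func)

  if (spec$mode == "segment_usage") {
    in_v <- spec$target %in% config$v_pool$segment
    if (!in_v && !spec$target %in% config$j_pool$segment) {
      abort_tcr(sprintf("Enrichment target segment '%s' is not in the configured pools.",
                        spec$target), "tcrcomp_config_error")
    }
    pool <- if (in_v) config$v_pool else config$j_pool
    seg <- if (in_v) cl$v_segment else cl$j_segment
    cand <- which(func & seg != spec$target)
    new_nt <- pool$flank_nt[match(spec$target, pool$segment)]
    new_aa <- pool$flank_aa[match(spec$target, pool$segment)]
    propose <- function(idx) {
      old_nt_len <- nchar(pool$flank_nt[match(seg[idx], pool$segment)])
      old_aa_len <- old_nt_len %/% 3L
      ntl <- nchar(cl$cdr3_nt[idx])
      aal <- nchar(cl$cdr3_aa[idx])
      if (in_v) {
        list(nt = paste0(new_nt, substr(cl$cdr3_nt[idx], old_nt_len + 1L, ntl)),
             aa = paste0(new_aa, substr(cl$cdr3_aa[idx], old_aa_len + 1L, aal)),
             v = rep.int(spec$target, length(idx)), j = cl$j_segment[idx])
      } else {
        list(nt = paste0(substr(cl$cdr3_nt[idx], 1L, ntl - old_nt_len), new_nt),
             aa = paste0(substr(cl$cdr3_aa[idx], 1L, aal - old_aa_len), new_aa),
             v = cl$v_segment[idx], j = rep.int(spec$target, length(idx)))
      }
    }
    err <- sprintf("Requested segment enrichment of %+g points for '%s' is infeasible.",
                   spec$effect, spec$target)
  } else {
    if (spec$mode == "containment") {
      cand <- which(func & !grepl(spec$target, cl$cdr3_aa, fixed = TRUE) &
                      nchar(cl$cdr3_aa) >= 4)
    } else {
      cand <- which(func & nchar(cl$cdr3_aa) > spec$position &
                      substr(cl$cdr3_aa, spec$position, spec$position) !=
                        spec$target)
    }
    propose <- function(idx) {
      if (spec$mode == "containment") {
        L <- nchar(cl$cdr3_aa[idx])
        q <- 2L + floor(stats::runif(length(idx)) * (L - 2L))
      } else {
        q <- rep.int(spec$position, length(idx))
      }
      codon <- sample(ct$by_aa[[spec$target]], length(idx), replace = TRUE)
      nt <- cl$cdr3_nt[idx]
      aa <- cl$cdr3_aa[idx]
      substr(nt, 3L * q - 2L, 3L * q) <- codon
      substr(aa, q, q) <- spec$target
      list(nt = nt, aa = aa, v = cl$v_segment[idx], j = cl$j_segment[idx])
    }
    err <- sprintf("Requested %s enrichment of %+g points for '%s' is infeasible at this repertoire size.",
                   spec$mode, spec$effect, spec$target)
  }

  if (k > length(cand)) abort_tcr(err, "tcrcomp_config_error")
  queue <- cand[sample.int(length(cand), length(cand))]
  applied <- 0L
  pos <- 1L
  while (applied < k && pos <= length(queue)) {
    batch <- queue[pos:min(length(queue), pos + (k - applied) - 1L)]
    pos <- pos + length(batch)
    prop <- propose(batch)
    key <- paste(cl$v_segment, cl$d_segment, cl$j_segment, cl$cdr3_nt,
                 sep = "\r")
    key[batch] <- paste(prop$v, cl$d_segment[batch], prop$j, prop$nt,
                        sep = "\r")
    dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
    ok <- which(!dup[batch])
    if (length(ok) > 0) {
      acc <- batch[ok]
      cl$cdr3_nt[acc] <- prop$nt[ok]
      cl$cdr3_aa[acc] <- prop$aa[ok]
      cl$v_segment[acc] <- prop$v[ok]
      cl$j_segment[acc] <- prop$j[ok]
      applied <- applied + length(ok)
    }
  }
  if (applied < k) abort_tcr(err, "tcrcomp_config_error")
  cl
}

#' Simulate a donor cohort
#'
#' Generates `n_donors_case + n_donors_control` repertoires with distinct
#' donor labels. Each donor draws from its own random stream derived from
#' the root seed, so the cohort is reproducible and donors are independent.
#'
#' @param config A [simulation_config()].
#' @return A list of `tcr_repertoire` objects (class `tcr_cohort`), case
#'   donors first.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "tcr_simulation_config"))
  if (config$n_donors_case < 1 || config$n_donors_control < 1) {
    abort_tcr("Both arms need at least one donor.", "tcrcomp_config_error")
  }
  ids_case <- sprintf("donor%02d", seq_len(config$n_donors_case))
  ids_ctrl <- sprintf("donor%02d",
                      config$n_donors_case + seq_len(config$n_donors_control))
  reps <- c(
    purrr::map(ids_case, simulate_repertoire, config = config, condition = "case"),
    purrr::map(ids_ctrl, simulate_repertoire, config = config, condition = "control")
  )
  structure(reps, class = "tcr_cohort", config = config)
}

#' Write a simulated cohort to disk
#'
#' Writes one VDJtools-style TSV per repertoire plus a YAML sample manifest
#' consumable by [read_cohort()]. Every table carries a provenance comment
#' header (package version, root seed, configuration digest).
#'
#' @param cohort A `tcr_cohort` (or plain list of repertoires).
#' @param dir Output directory, created if needed.
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  config <- attr(cohort, "config")
  provenance <- c(
    paste0("tcrcomp ", as.character(utils::packageVersion("tcrcomp"))),
    if (!is.null(config)) paste0("seed: ", config$seed),
    if (!is.null(config)) paste0("config_digest: ", stable_hash(format(config)))
  )
  samples <- purrr::map(cohort, function(rep) {
    fname <- sprintf("%s_%s_%s_%s.tsv", rep$donor_id, rep$subset, rep$chain,
                     rep$condition)
    write_clonotype_table(rep, file.path(dir, fname), provenance = provenance)
    list(path = fname, donor_id = rep$donor_id, subset = rep$subset,
         chain = rep$chain, condition = rep$condition)
  })
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(samples = samples), manifest_path)
  invisible(manifest_path)
}
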