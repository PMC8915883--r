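# File-based orchestration: simulate cohorts to disk, run the full
# read -> merge -> filter -> descriptors -> statistics chain from a sample
# manifest, and write reproducible report tables.

provenance_lines <- function(settings, seed = NULL) {
  c(
    paste0("tcrcomp ", as.character(utils::packageVersion("tcrcomp"))),
    if (!is.null(seed)) paste0("seed: ", seed),
    paste0("config_digest: ", stable_hash(format(settings)))
  )
}

write_report_tsv <- function(x, path, provenance) {
  writeLines(paste0("# ", provenance), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  path
}

sample_id <- function(r) {
  sprintf("%s_%s_%s_%s", r$donor_id, r$subset, r$chain, r$condition)
}

#' Simulate a cohort and write it to disk
#'
#' Generates a donor cohort under `config`, writes one VDJtools-style TSV
#' per repertoire plus a YAML manifest, and logs the realized occurrence of
#' every requested enrichment (case vs control arm) so requested and
#' realized effects can be compared.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with `manifest` (path) and
#'   `realized_enrichments` (tibble, possibly empty).
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "tcr_simulation_config"))
  cohort <- simulate_cohort(config)
  manifest <- write_cohort(cohort, out_dir)
  realized <- realized_enrichments(cohort, config)
  if (nrow(realized) > 0) {
    for (i in seq_len(nrow(realized))) {
      message(sprintf(
        "Enrichment %s '%s': requested %+g points, realized case-control difference %+0.2f points.",
        realized$mode[i], realized$target[i], realized$requested[i],
        realized$realized[i]))
    }
  }
  message(sprintf("Wrote %d sample table(s) and manifest to '%s'.",
                  length(cohort), out_dir))
  invisible(list(manifest = manifest, realized_enrichments = realized))
}

# Realized case-minus-control occurrence for each enrichment spec, measured
# on the functional-filtered cohort under diversity weighting.
realized_enrichments <- function(cohort, config) {
  specs <- config$enrichments
  if (length(specs) == 0) {
    return(tibble::tibble(mode = character(0), target = character(0),
                          requested = numeric(0), realized = numeric(0)))
  }
  prepared <- purrr::map(cohort, function(r) {
    suppressMessages(filter_functional(r))
  })
  measure <- function(r, spec) {
    switch(spec$mode,
      containment = {
        prof <- aa_occurrence(r, "diversity")
        prof$occurrence[prof$amino_acid == spec$target]
      },
      positional = {
        prof <- positional_occurrence(r, "diversity",
                                      max_position = spec$position)
        prof$occurrence[prof$position == spec$position &
                          prof$amino_acid == spec$target]
      },
      segment_usage = {
        cls <- if (grepl("V", spec$target)) "V" else "J"
        prof <- segment_usage(r, segment_class = cls, weighting = "diversity")
        val <- prof$usage[prof$segment == spec$target]
        if (length(val) == 0) 0 else val
      }
    )
  }
  conditions <- vapply(prepared, function(r) r$condition, character(1))
  dplyr::bind_rows(purrr::map(specs, function(spec) {
    vals <- vapply(prepared, measure, numeric(1), spec = spec)
    tibble::tibble(
      mode = spec$mode, target = spec$target, requested = spec$effect,
      realized = mean(vals[conditions == "case"]) -
        mean(vals[conditions == "control"])
    )
  }))
}

#' Run the full comparison pipeline from a sample manifest
#'
#' Reads every sample table listed in the manifest, collapses records into
#' clonotypes and removes non-functional ones, writes per-sample descriptor
#' tables, and for every (subset, chain) stratum with at least two donors
#' per condition writes a case-versus-control comparison report per
#' descriptor. All outputs are plain TSV with a provenance comment header;
#' identical inputs and settings produce byte-identical outputs.
#'
#' @param manifest Path to a YAML/JSON sample manifest (see
#'   [read_sample_manifest()]).
#' @param out_dir Output directory.
#' @param descriptors Subset of `c("aa_occurrence", "positional",
#'   "segment_usage", "cdr3_length")` to compute.
#' @param weighting `"diversity"` or `"counts"`.
#' @param dialect Input table dialect.
#' @param alpha Significance threshold used for star annotations.
#' @param positional_aa Amino acids whose positional profiles are compared
#'   (one report per letter).
#' @param max_position,conditional Positional profile settings.
#' @param var_equal Pooled-variance t-tests if `TRUE`.
#' @param min_clonotypes Minimum unique clonotypes for a repertoire to
#'   enter comparisons.
#' @return Invisibly, a list with the written `sample_tables`,
#'   `comparison_reports` and the `run_log` path.
#' @export
run_compare <- function(manifest, out_dir,
                        descriptors = c("aa_occurrence", "positional",
                                        "segment_usage", "cdr3_length"),
                        weighting = c("diversity", "counts"),
                        dialect = "vdjtools",
                        alpha = 0.05,
                        positional_aa = c("K", "W"),
                        max_position = 18,
                        conditional = FALSE,
                        var_equal = TRUE,
                        min_clonotypes = 50) {
  weighting <- match.arg(weighting)
  descriptors <- match.arg(descriptors, several.ok = TRUE)
  manifest_tbl <- read_sample_manifest(manifest)
  base_dir <- dirname(manifest)
  settings <- list(descriptors = descriptors, weighting = weighting,
                   dialect = dialect, alpha = alpha,
                   positional_aa = positional_aa,
                   max_position = max_position, conditional = conditional,
                   var_equal = var_equal, min_clonotypes = min_clonotypes)
  prov <- provenance_lines(settings)

  # read everything (validating all paths) before writing anything
  cohort <- read_cohort(manifest_tbl, dialect = dialect, base_dir = base_dir,
                        prepare = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sample_tables <- character(0)
  for (r in cohort) {
    tabs <- list()
    if ("aa_occurrence" %in% descriptors) {
      tabs$aa_occurrence <- aa_occurrence(r, weighting)
    }
    if ("positional" %in% descriptors) {
      tabs$positional <- positional_occurrence(r, weighting,
                                               max_position = max_position,
                                               conditional = conditional)
    }
    if ("segment_usage" %in% descriptors) {
      tabs$segment_usage <- dplyr::bind_rows(
        segment_usage(r, "V", weighting),
        segment_usage(r, "J", weighting)
      )
    }
    if ("cdr3_length" %in% descriptors) {
      tabs$cdr3_length <- cdr3_length_distribution(r, weighting)
    }
    for (nm in names(tabs)) {
      path <- file.path(out_dir, sprintf("%s.%s.tsv", sample_id(r), nm))
      write_report_tsv(tabs[[nm]], path, prov)
      sample_tables <- c(sample_tables, path)
    }
  }

  strata <- unique(manifest_tbl[, c("subset", "chain")])
  comparison_reports <- character(0)
  for (i in seq_len(nrow(strata))) {
    sub <- strata$subset[i]
    ch <- strata$chain[i]
    members <- purrr::keep(cohort, function(r) {
      identical(r$subset, sub) && identical(r$chain, ch)
    })
    run_one <- function(descriptor, suffix, ...) {
      cmp <- tryCatch(
        compare_composition(members, descriptor = descriptor,
                            weighting = weighting, var_equal = var_equal,
                            min_clonotypes = min_clonotypes, ...),
        tcrcomp_replication_error = function(e) {
          rlang::warn(sprintf(
            "Stratum %s/%s skipped for %s: %s", sub, ch, suffix,
            conditionMessage(e)))
          NULL
        }
      )
      if (is.null(cmp)) return(invisible(NULL))
      cmp$stars <- significance_stars(cmp$p_adj, alpha)
      path <- file.path(out_dir,
                        sprintf("comparison_%s_%s_%s.tsv", sub, ch, suffix))
      write_report_tsv(cmp, path, prov)
      comparison_reports <<- c(comparison_reports, path)
    }
    if ("aa_occurrence" %in% descriptors) {
      run_one("aa_occurrence", "aa_occurrence")
    }
    if ("positional" %in% descriptors) {
      for (aa in positional_aa) {
        run_one("positional", paste0("positional_", aa), positional_aa = aa,
                max_position = max_position, conditional = conditional)
      }
    }
    if ("segment_usage" %in% descriptors) {
      run_one("segment_usage", "segment_usage_V", segment_class = "V")
      run_one("segment_usage", "segment_usage_J", segment_class = "J")
    }
  }

  input_paths <- ifelse(grepl("^/", manifest_tbl$path), manifest_tbl$path,
                        file.path(base_dir, manifest_tbl$path))
  checksums <- tools::md5sum(input_paths)
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(c(
    prov,
    "",
    "input checksums (md5):",
    sprintf("  %s  %s", unname(checksums), basename(input_paths)),
    "",
    sprintf("samples read: %d", length(cohort)),
    sprintf("sample descriptor tables written: %d", length(sample_tables)),
    sprintf("comparison reports written: %d", length(comparison_reports))
  ), log_path)

  invisible(list(sample_tables = sample_tables,
                 comparison_reports = comparison_reports,
                 run_log = log_path))
}
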