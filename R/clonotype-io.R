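# Reading, writing, collapsing and filtering clonotype tables.

# Column maps for the supported tab-separated dialects. Keys are the
# internal field names, values the column headers expected in the file.
CLONOTYPE_DIALECTS <- list(
  vdjtools = c(count = "count", frequency = "freq", cdr3_nt = "cdr3nt",
               cdr3_aa = "cdr3aa", v_segment = "v", d_segment = "d",
               j_segment = "j"),
  mixcr = c(count = "cloneCount", frequency = "cloneFraction",
            cdr3_nt = "nSeqCDR3", cdr3_aa = "aaSeqCDR3",
            v_segment = "bestVHit", d_segment = "bestDHit",
            j_segment = "bestJHit")
)

#' Read a clonotype table
#'
#' Reads one sample's clonotype table in a VDJtools-style or MIXCR-export
#' tab-separated dialect. Rows are returned as-is (segment names are
#' normalized to gene level, but records are neither collapsed nor
#' filtered); follow with [merge_clonotypes()] and [filter_functional()].
#'
#' @param path Path to a tab-separated clonotype table. Lines starting with
#'   `#` are treated as comments; a leading `#` on the header line is
#'   tolerated.
#' @param dialect `"vdjtools"` (columns `count freq cdr3nt cdr3aa v d j`) or
#'   `"mixcr"` (columns `cloneCount cloneFraction nSeqCDR3 aaSeqCDR3
#'   bestVHit bestDHit bestJHit`).
#' @param donor_id,subset,chain,condition Sample metadata, typically taken
#'   from a sample manifest (see [read_sample_manifest()]).
#' @return A [repertoire()] holding one record per data row.
#' @examples
#' path <- system.file("extdata", "example_clonotypes_synthetic.tsv",
#'                     package = "tcrcomp")
#' rep <- read_clonotype_table(path, donor_id = "demo", subset = "CD4",
#'                             chain = "TRB", condition = "case")
#' filter_functional(merge_clonotypes(rep))
#' @export
read_clonotype_table <- function(path, dialect = c("vdjtools", "mixcr"),
                                 donor_id = NA, subset = NA, chain = NA,
                                 condition = NA) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_tcr(sprintf("Clonotype table '%s' does not exist.", path),
              "tcrcomp_format_error")
  }
  map <- CLONOTYPE_DIALECTS[[dialect]]
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE,
                         name_repair = "minimal")
  names(raw) <- sub("^#", "", names(raw))
  missing_cols <- setdiff(unname(map), names(raw))
  if (length(missing_cols) > 0) {
    abort_tcr(
      sprintf("File '%s' lacks required %s column(s): %s", path, dialect,
              paste(missing_cols, collapse = ", ")),
      "tcrcomp_format_error"
    )
  }
  if (nrow(raw) == 0) {
    abort_tcr(sprintf("File '%s' has a header but no data rows.", path),
              "tcrcomp_empty_error")
  }
  counts <- suppressWarnings(as.numeric(raw[[map[["count"]]]]))
  bad <- !is.finite(counts) | counts != round(counts) | counts < 1
  if (any(bad)) {
    abort_tcr(
      sprintf("Row %d of '%s': count '%s' is not a positive integer.",
              which(bad)[1], path, raw[[map[["count"]]]][which(bad)[1]]),
      "tcrcomp_parse_error"
    )
  }
  records <- tibble::tibble(
    cdr3_nt = toupper(raw[[map[["cdr3_nt"]]]]),
    cdr3_aa = raw[[map[["cdr3_aa"]]]],
    v_segment = normalize_segment_name(raw[[map[["v_segment"]]]]),
    d_segment = normalize_segment_name(raw[[map[["d_segment"]]]]),
    j_segment = normalize_segment_name(raw[[map[["j_segment"]]]]),
    count = as.integer(counts),
    frequency = suppressWarnings(as.numeric(raw[[map[["frequency"]]]]))
  )
  message(sprintf("Read %d clonotype records from '%s' (%s dialect).",
                  nrow(records), basename(path), dialect))
  repertoire(records, donor_id = donor_id, subset = subset, chain = chain,
             condition = condition)
}

#' Write a clonotype table
#'
#' Writes a repertoire as a VDJtools-style TSV (columns
#' `count freq cdr3nt cdr3aa v d j`). Optional provenance lines are
#' prepended as `#` comments.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output file path.
#' @param provenance Optional character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path, provenance = NULL) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  out <- tibble::tibble(
    count = rep$clonotypes$count,
    freq = rep$clonotypes$frequency,
    cdr3nt = rep$clonotypes$cdr3_nt,
    cdr3aa = rep$clonotypes$cdr3_aa,
    v = rep$clonotypes$v_segment,
    d = rep$clonotypes$d_segment,
    j = rep$clonotypes$j_segment
  )
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest maps sample files to their metadata. YAML (`.yaml`/`.yml`)
#' and JSON (`.json`) are supported; the top level is a list `samples`,
#' each entry with fields `path`, `donor_id`, `subset`, `chain`,
#' `condition`.
#'
#' @param path Manifest file path.
#' @return A tibble with one row per sample.
#' @export
read_sample_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_tcr(sprintf("Manifest '%s' does not exist.", path),
              "tcrcomp_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  parsed <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    abort_tcr("Manifest must be a .yaml/.yml or .json file.",
              "tcrcomp_format_error")
  }
  samples <- parsed$samples %||% parsed
  if (length(samples) == 0) {
    abort_tcr("Manifest lists no samples.", "tcrcomp_empty_error")
  }
  rows <- purrr::map(samples, function(s) {
    need <- c("path", "donor_id", "subset", "chain", "condition")
    missing_f <- setdiff(need, names(s))
    if (length(missing_f) > 0) {
      abort_tcr(paste0("Manifest entry lacks field(s): ",
                       paste(missing_f, collapse = ", ")),
                "tcrcomp_format_error")
    }
    tibble::as_tibble(s[need])
  })
  dplyr::bind_rows(rows)
}

#' Read a cohort of clonotype tables via a manifest
#'
#' @param manifest Path to a manifest file, or a tibble as returned by
#'   [read_sample_manifest()].
#' @param dialect Table dialect passed to [read_clonotype_table()].
#' @param base_dir Directory against which relative sample paths are
#'   resolved. Defaults to the manifest's directory when `manifest` is a
#'   path, else the working directory.
#' @param prepare If `TRUE` (default), each repertoire is collapsed with
#'   [merge_clonotypes()] and cleaned with [filter_functional()].
#' @return List of `tcr_repertoire` objects.
#' @export
read_cohort <- function(manifest, dialect = "vdjtools", base_dir = NULL,
                        prepare = TRUE) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- read_sample_manifest(manifest)
  }
  base_dir <- base_dir %||% "."
  paths <- ifelse(grepl("^/", manifest$path), manifest$path,
                  file.path(base_dir, manifest$path))
  absent <- !file.exists(paths)
  if (any(absent)) {
    abort_tcr(
      paste0("Manifest references missing file(s): ",
             paste(paths[absent], collapse = ", ")),
      "tcrcomp_format_error"
    )
  }
  purrr::map(seq_len(nrow(manifest)), function(i) {
    rep <- read_clonotype_table(paths[i], dialect = dialect,
                                donor_id = manifest$donor_id[i],
                                subset = manifest$subset[i],
                                chain = manifest$chain[i],
                                condition = manifest$condition[i])
    if (prepare) rep <- filter_functional(merge_clonotypes(rep))
    rep
  })
}

#' Collapse records into clonotypes
#'
#' Records sharing an identical V, D and J gene segment and CDR3 nucleotide
#' sequence are considered one clonotype; member counts are summed and
#' frequencies recomputed as `count / total`. Output order is deterministic:
#' descending count, ties broken lexicographically by CDR3 nucleotide
#' sequence, then V segment.
#'
#' @param x A `tcr_repertoire` or a clonotype data frame.
#' @return An object of the same kind as `x`, collapsed.
#' @export
merge_clonotypes <- function(x) {
  inp <- as_clonotype_records(x)
  records <- inp$records
  if (nrow(records) == 0) {
    out <- records
  } else {
    key <- paste(records$v_segment, records$d_segment, records$j_segment,
                 records$cdr3_nt, sep = "\r")
    pair <- paste(key, records$cdr3_aa, sep = "\r")
    uniq_pairs <- !duplicated(pair)
    conflict_key <- key[uniq_pairs][duplicated(key[uniq_pairs])]
    if (length(conflict_key) > 0) {
      offender <- records$cdr3_nt[match(conflict_key[1], key)]
      abort_tcr(
        sprintf("Conflicting amino-acid sequences for identical CDR3 nucleotide sequence '%s'.",
                offender),
        "tcrcomp_integrity_error"
      )
    }
    sums <- rowsum(as.numeric(records$count), key)
    first_idx <- which(!duplicated(key))
    count <- as.integer(sums[match(key[first_idx], rownames(sums)), 1])
    total <- sum(count)
    out <- tibble::tibble(
      cdr3_nt = records$cdr3_nt[first_idx],
      cdr3_aa = records$cdr3_aa[first_idx],
      v_segment = records$v_segment[first_idx],
      d_segment = records$d_segment[first_idx],
      j_segment = records$j_segment[first_idx],
      count = count,
      frequency = count / total
    )
    out <- out[order(-out$count, out$cdr3_nt, out$v_segment,
                     method = "radix"), ]
  }
  if (inherits(x, "tcr_repertoire")) rebuild_repertoire(out, inp$meta) else out
}

#' Remove non-functional clonotypes
#'
#' Drops clonotypes whose CDR3 amino-acid sequence carries a stop-codon
#' (`*`) or frameshift (`_`) marker, then renormalizes frequencies over the
#' survivors. The removal tally is reported via `message()`.
#'
#' @param x A `tcr_repertoire` or a clonotype data frame.
#' @param markers Characters whose presence marks a clonotype
#'   non-functional.
#' @return Filtered object of the same kind as `x`.
#' @export
filter_functional <- function(x, markers = c("*", "_")) {
  inp <- as_clonotype_records(x)
  records <- inp$records
  keep <- rep(TRUE, nrow(records))
  for (m in markers) {
    keep <- keep & !grepl(m, records$cdr3_aa, fixed = TRUE)
  }
  removed <- sum(!keep)
  out <- records[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    out$frequency <- out$count / sum(out$count)
  } else if (nrow(records) > 0) {
    rlang::warn("All clonotypes were non-functional; repertoire is empty after filtering.")
  }
  if (removed > 0) {
    message(sprintf("Removed %d non-functional clonotype(s) of %d.",
                    removed, nrow(records)))
  }
  if (inherits(x, "tcr_repertoire")) rebuild_repertoire(out, inp$meta) else out
}
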