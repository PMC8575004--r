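# Tabular I/O for every artifact the pipeline touches. Feature tables and
# affinities are plain tibbles keyed by a lowercase 4-character-style complex
# id; similarity matrices are dense base matrices wrapped in a light S3 class
# (see similarity.R) because 318 x 4154 is the realistic upper bound and a
# long format would triple memory for no benefit.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_quiet <- function(path, ...) {
  readr::read_delim(path, delim = delim_for(path), show_col_types = FALSE,
                    progress = FALSE, ...)
}

normalize_id <- function(id) tolower(trimws(as.character(id)))

#' Read a per-complex feature table
#'
#' Reads a CSV/TSV (delimiter chosen from the extension) with an `id` column
#' followed by numeric descriptor columns, one row per protein-ligand complex.
#' Ids are lowercased; duplicates, missing values and non-numeric cells are
#' errors.
#'
#' @param path file path (`.csv` or `.tsv`).
#' @param expected_columns optional character vector of feature names; when
#'   given, all must be present and the returned columns are reordered to
#'   match it (extra columns are dropped).
#' @return A tibble with column `id` plus one numeric column per feature.
#' @export
read_feature_table <- function(path, expected_columns = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tbl <- read_delim_quiet(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_character()
  ))
  if (!"id" %in% names(tbl)) abort("Feature table must have an 'id' column")
  validate_feature_frame(tbl, expected_columns, what = path)
}

# Shared validator for feature tables arriving from disk or from memory.
validate_feature_frame <- function(tbl, expected_columns = NULL,
                                   what = "feature table") {
  tbl$id <- normalize_id(tbl$id)
  dup <- tbl$id[duplicated(tbl$id)]
  if (length(dup)) {
    abort(paste0("Duplicate complex id(s) in ", what, ": ",
                 paste(unique(dup), collapse = ", ")))
  }
  feat_cols <- setdiff(names(tbl), "id")
  if (anyDuplicated(feat_cols)) abort("Feature column names must be unique")
  for (cn in feat_cols) {
    v <- suppressWarnings(as.numeric(tbl[[cn]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort(paste0("Non-numeric or missing value in ", what,
                   " at row ", bad[1], ", column '", cn, "'"))
    }
    tbl[[cn]] <- v
  }
  if (!is.null(expected_columns) && length(expected_columns)) {
    missing <- setdiff(expected_columns, feat_cols)
    if (length(missing)) {
      abort(paste0("Missing expected feature column(s): ",
                   paste(missing, collapse = ", ")))
    }
    tbl <- tbl[, c("id", expected_columns)]
  }
  tibble::as_tibble(tbl)
}

#' Write a feature table
#'
#' @param x tibble as returned by [read_feature_table()].
#' @param path output path; `.csv` writes comma-separated, anything else tab.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  readr::write_delim(x, path, delim = delim_for(path))
  invisible(path)
}

#' Read measured binding affinities from a PDBbind-style index file
#'
#' PDBbind index files are whitespace-delimited with `#` comment lines; the
#' columns are complex code, resolution, release year, -log(Kd/Ki), and an
#' affinity string (further columns ignored). Only the code (column 1) and
#' the pK value (column 4) are consumed. pKd/pKi is -log10 of the molar
#' dissociation/inhibition constant, the regression target throughout.
#'
#' @param path file path.
#' @return A tibble with columns `id` (lowercase) and `affinity` (pK units).
#' @export
read_pdbbind_index <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keep)) {
    return(tibble::tibble(id = character(), affinity = double()))
  }
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  n_col <- vapply(parts, length, integer(1))
  if (any(n_col < 4)) {
    bad <- keep[which(n_col < 4)[1]]
    abort(paste0("Line ", bad, " of ", path,
                 " has fewer than 4 whitespace-separated columns"))
  }
  id <- normalize_id(vapply(parts, `[[`, "", 1))
  affinity <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4)))
  bad <- which(!is.finite(affinity))
  if (length(bad)) {
    abort(paste0("Non-numeric affinity on line ", keep[bad[1]], " of ", path))
  }
  dup <- id[duplicated(id)]
  if (length(dup)) {
    abort(paste0("Duplicate complex id(s) in index: ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble::tibble(id = id, affinity = affinity)
}

#' Read a test-by-train similarity or dissimilarity matrix
#'
#' The on-disk layout is CSV/TSV with the first column holding test-complex
#' ids and the remaining columns labeled by training-complex ids. Values are
#' validated against the declared kind: similarities must lie in \[0, 1\],
#' dissimilarities must be non-negative; NaN/NA are rejected.
#'
#' @param path file path.
#' @param kind `"similarity"` or `"dissimilarity"`.
#' @param metric_name one of `"protein_structure"`, `"ligand_fingerprint"`,
#'   `"pocket_topology"`, `"other"`.
#' @return A [sim_matrix()] object.
#' @export
read_similarity_matrix <- function(path, kind = c("similarity", "dissimilarity"),
                                   metric_name = "other") {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tbl <- read_delim_quiet(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ))
  if (ncol(tbl) < 1) abort("Similarity matrix file is empty")
  test_ids <- normalize_id(as.character(tbl[[1]]))
  vals <- as.matrix(tbl[, -1, drop = FALSE])
  if (length(vals) && !is.numeric(vals)) {
    abort("Similarity matrix cells must be numeric")
  }
  rownames(vals) <- test_ids
  colnames(vals) <- normalize_id(colnames(vals))
  sim_matrix(vals, kind = kind, metric_name = metric_name)
}

#' Write a similarity matrix
#'
#' Inverse of [read_similarity_matrix()]: first column `id` (test ids),
#' remaining columns labeled by train ids.
#'
#' @param m a [sim_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(m, path) {
  stopifnot(inherits(m, "sim_matrix"))
  out <- tibble::as_tibble(m$values, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(id = rownames(m$values)), out)
  readr::write_delim(out, path, delim = delim_for(path))
  invisible(path)
}

#' Write performance curves as a long-format TSV
#'
#' Serializes the data behind the performance-versus-cutoff figures: one row
#' per scoring function and cutoff, columns `sf_name`, `metric`, `direction`,
#' `cutoff`, `n_train`, `rp`, `rs`, `rmse`. Missing evaluations (empty or
#' degenerate nested sets) are written as `NA`.
#'
#' @param curves an `sf_curves` tibble from [sweep_scoring()] (or a list of
#'   them, which is row-bound).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_performance_table <- function(curves, path) {
  if (is.list(curves) && !is.data.frame(curves)) {
    curves <- dplyr::bind_rows(curves)
  }
  need <- c("sf_name", "metric", "direction", "cutoff", "n_train",
            "rp", "rs", "rmse")
  if (is.null(curves) || nrow(curves) == 0) {
    curves <- tibble::as_tibble(stats::setNames(
      rep(list(logical()), length(need)), need))
  }
  missing <- setdiff(need, names(curves))
  if (length(missing)) {
    abort(paste0("Performance table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  readr::write_delim(curves[, need], path, delim = delim_for(path), na = "NA")
  invisible(path)
}

#' Read back a performance table written by [write_performance_table()]
#'
#' @param path file path.
#' @return An `sf_curves` tibble.
#' @export
read_performance_table <- function(path) {
  tbl <- read_delim_quiet(path, col_types = readr::cols(
    sf_name = readr::col_character(),
    metric = readr::col_character(),
    direction = readr::col_character(),
    .default = readr::col_double()
  ))
  class(tbl) <- c("sf_curves", class(tbl))
  tbl
}

#' Export a nested-set family for audit
#'
#' One row per cutoff with the training-set size and the semicolon-joined
#' member ids, so a nested family can be inspected or diffed outside R.
#'
#' @param family a [build_family()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_family_table <- function(family, path) {
  stopifnot(inherits(family, "nested_family"))
  tbl <- tibble::tibble(
    metric = family$metric_name,
    direction = family$direction,
    cutoff = family$cutoffs,
    n_train = vapply(family$sets, length, integer(1)),
    ids = vapply(family$sets, paste, "", collapse = ";")
  )
  readr::write_delim(tbl, path, delim = "\t")
  invisible(path)
}
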