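#' Dense test-by-train (dis)similarity matrix
#'
#' Wraps a dense numeric matrix whose rows are test complexes and whose
#' columns are training complexes, together with its kind. Similarities
#' (protein-structure TM-scores, ligand-fingerprint Tanimoto coefficients)
#' live in \[0, 1\]; dissimilarities (pocket-topology city-block distances)
#' in \[0, +Inf). Row/column names are the complex ids.
#'
#' @param values numeric matrix with rownames (test ids) and colnames
#'   (train ids).
#' @param kind `"similarity"` or `"dissimilarity"`.
#' @param metric_name one of `"protein_structure"`, `"ligand_fingerprint"`,
#'   `"pocket_topology"`, `"other"`.
#' @return An object of class `sim_matrix` with fields `values`, `kind`,
#'   `metric_name`.
#' @export
sim_matrix <- function(values, kind = c("similarity", "dissimilarity"),
                       metric_name = c("other", "protein_structure",
                                       "ligand_fingerprint", "pocket_topology")) {
  kind <- match.arg(kind)
  metric_name <- match.arg(metric_name)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    # unlabeled matrices get positional ids (convenient for toy examples)
    if (is.null(rownames(values)) && nrow(values) > 0)
      rownames(values) <- paste0("q", seq_len(nrow(values)))
    if (is.null(colnames(values)) && ncol(values) > 0)
      colnames(values) <- paste0("p", seq_len(ncol(values)))
  }
  bad <- which(!is.finite(values))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    abort(paste0("Non-finite value at matrix cell (",
                 rownames(values)[ij[1]], ", ", colnames(values)[ij[2]], ")"))
  }
  lo_bad <- which(values < 0)
  hi_bad <- if (kind == "similarity") which(values > 1) else integer()
  bad <- c(lo_bad, hi_bad)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(values))
    abort(paste0("Value ", values[bad[1]], " at cell (",
                 rownames(values)[ij[1]], ", ", colnames(values)[ij[2]],
                 ") outside the valid range for kind '", kind, "'"))
  }
  structure(list(values = values, kind = kind, metric_name = metric_name),
            class = "sim_matrix")
}

#' @export
print.sim_matrix <- function(x, ...) {
  cat("<sim_matrix> ", x$metric_name, " (", x$kind, "): ",
      nrow(x$values), " test x ", ncol(x$values), " train\n", sep = "")
  invisible(x)
}

#' @export
dim.sim_matrix <- function(x) dim(x$values)

test_ids <- function(m) rownames(m$values)
train_ids <- function(m) colnames(m$values)

#' Tanimoto coefficient of two fingerprints
#'
#' A fingerprint is the set of on-bit identifiers of a hashed circular
#' substructure fingerprint (ECFP4-style), represented as an integer vector.
#' The Tanimoto coefficient is |intersection| / |union|. Two empty
#' fingerprints score 0: an atom-free ligand carries no evidence of
#' similarity.
#'
#' @param a,b integer vectors of on-bits (duplicates ignored).
#' @return A similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
tanimoto <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' City-block (Manhattan) distance between two pocket vectors
#'
#' Pocket-topology vectors are fixed-length numeric encodings of binding
#' pocket shape and partial charges; the city-block distance between two
#' pockets is a dissimilarity in \[0, +Inf), 0 iff identical.
#'
#' @param a,b numeric vectors of equal length.
#' @return Non-negative distance.
#' @examples
#' cityblock(c(0, 0), c(1, 2)) # 3
#' @export
cityblock <- function(a, b) {
  if (length(a) != length(b)) {
    abort(paste0("Pocket vector length mismatch: ", length(a), " vs ",
                 length(b)))
  }
  sum(abs(a - b))
}

#' Assemble a pairwise similarity matrix from per-complex items
#'
#' Computes every test-train pair of either Tanimoto coefficients (items are
#' fingerprints, i.e. integer bit vectors) or city-block distances (items are
#' numeric pocket vectors of a common length).
#'
#' @param test_items,train_items named lists of items (names are complex ids).
#' @param metric `"tanimoto"` or `"cityblock"`.
#' @param metric_name recorded on the result; defaults to the conventional
#'   name for the metric.
#' @return A [sim_matrix()]; `kind` is `"similarity"` for tanimoto and
#'   `"dissimilarity"` for cityblock.
#' @export
build_similarity_matrix <- function(test_items, train_items,
                                    metric = c("tanimoto", "cityblock"),
                                    metric_name = NULL) {
  metric <- match.arg(metric)
  check_modality <- function(items, lbl) {
    ok <- vapply(items, function(x) {
      if (metric == "cityblock") is.numeric(x) else is.numeric(x) || is.integer(x)
    }, logical(1))
    if (length(ok) && !all(ok)) {
      abort(paste0("All ", lbl, " items must be numeric vectors"))
    }
  }
  check_modality(test_items, "test")
  check_modality(train_items, "train")
  if (metric == "cityblock") {
    lens <- unique(vapply(c(test_items, train_items), length, integer(1)))
    if (length(lens) > 1) {
      abort("Pocket vectors must share a single length across the dataset")
    }
  }
  f <- if (metric == "tanimoto") tanimoto else cityblock
  vals <- matrix(0, nrow = length(test_items), ncol = length(train_items),
                 dimnames = list(names(test_items), names(train_items)))
  for (i in seq_along(test_items)) {
    for (j in seq_along(train_items)) {
      vals[i, j] <- f(test_items[[i]], train_items[[j]])
    }
  }
  kind <- if (metric == "tanimoto") "similarity" else "dissimilarity"
  metric_name <- metric_name %||%
    if (metric == "tanimoto") "ligand_fingerprint" else "pocket_topology"
  sim_matrix(vals, kind = kind, metric_name = metric_name)
}

# Per-training-complex summary statistic driving all nested-set logic:
# max over test complexes for similarities, min for dissimilarities.
train_stat <- function(m) {
  stopifnot(inherits(m, "sim_matrix"))
  if (nrow(m$values) == 0) {
    return(stats::setNames(numeric(ncol(m$values)), colnames(m$values)))
  }
  if (m$kind == "similarity") {
    apply(m$values, 2, max)
  } else {
    apply(m$values, 2, min)
  }
}

#' Histogram of training complexes over cutoff increments
#'
#' For each consecutive pair of cutoffs in a schedule, counts the training
#' complexes that would newly enter the nested training set when the cutoff
#' is moved one step in the direction of increasing inclusion (the
#' "dissimilar-first" direction): for similarities, complexes whose maximum
#' similarity to the test set falls in `(c_k, c_{k+1}]`; for dissimilarities,
#' complexes whose minimum distance to the test set falls in `[c_{k+1}, c_k)`.
#' This is the histogram companion of the training-set-size curve and makes
#' distribution skew (e.g. a heavy near-duplicate band just above 0.99)
#' visible.
#'
#' @param m a [sim_matrix()].
#' @param schedule a [cutoff_schedule()]; its kind must match the matrix
#'   (ascending grid for similarities, descending for dissimilarities).
#' @return A tibble with columns `lower`, `upper`, `count` (one row per
#'   increment, in sweep order).
#' @export
skew_histogram <- function(m, schedule) {
  stopifnot(inherits(m, "sim_matrix"), inherits(schedule, "cutoff_schedule"))
  stat <- train_stat(m)
  cuts <- schedule$cutoffs
  if (length(cuts) < 2) abort("Schedule must have at least 2 cutoffs")
  k <- length(cuts) - 1
  count <- integer(k)
  lower <- upper <- numeric(k)
  for (i in seq_len(k)) {
    a <- cuts[i]; b <- cuts[i + 1]
    if (m$kind == "similarity") {
      # ascending grid: bin (a, b]
      count[i] <- sum(stat > a & stat <= b)
      lower[i] <- a; upper[i] <- b
    } else {
      # descending grid: bin [b, a)
      count[i] <- sum(stat >= b & stat < a)
      lower[i] <- b; upper[i] <- a
    }
  }
  tibble::tibble(lower = lower, upper = upper, count = count)
}

#' Fraction of agreeing cells between two matrices
#'
#' Compares two similarity matrices over the same test and train sets and
#' returns the fraction of cells whose absolute difference is at most
#' `threshold` (inclusive) -- e.g. to quantify how often two structure
#' aligners produce TM-scores within 0.1 of each other.
#'
#' @param a,b [sim_matrix()] objects with identical dimensions and id labels.
#' @param threshold non-negative tolerance.
#' @return Fraction in \[0, 1\].
#' @export
matrix_agreement <- function(a, b, threshold) {
  stopifnot(inherits(a, "sim_matrix"), inherits(b, "sim_matrix"))
  if (!identical(dim(a$values), dim(b$values)) ||
      !identical(rownames(a$values), rownames(b$values)) ||
      !identical(colnames(a$values), colnames(b$values))) {
    abort("Matrices must have identical shapes and id labels")
  }
  if (length(a$values) == 0) abort("Cannot compare empty matrices")
  mean(abs(a$values - b$values) <= threshold)
}

#' Read fingerprints from a bit-list file
#'
#' One line per complex: `id<TAB>comma-separated on-bit integers`. An empty
#' bit field yields an empty fingerprint.
#'
#' @param path file path.
#' @return Named list of integer vectors.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- normalize_id(vapply(parts, `[[`, "", 1))
  fps <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(trimws(p[2]))) return(integer())
    v <- suppressWarnings(as.integer(strsplit(p[2], ",", fixed = TRUE)[[1]]))
    if (anyNA(v) || any(v < 0)) {
      abort(paste0("Invalid on-bit list for id '", p[1], "'"))
    }
    v
  })
  stats::setNames(fps, ids)
}

#' Read pocket vectors from a CSV/TSV
#'
#' Expects an `id` column plus a fixed set of numeric columns; every row is
#' one pocket vector.
#'
#' @param path file path.
#' @return Named list of numeric vectors.
#' @export
read_pocket_vectors <- function(path) {
  tbl <- read_feature_table(path)
  cols <- setdiff(names(tbl), "id")
  vecs <- lapply(seq_len(nrow(tbl)), function(i) {
    stats::setNames(as.numeric(tbl[i, cols]), cols)
  })
  stats::setNames(vecs, tbl$id)
}
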