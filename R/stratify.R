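# Nested training-set construction. Given a test-by-train similarity matrix
# and a cutoff c, the dissimilar-first (ds) training set keeps the training
# complexes whose similarity to EVERY test complex is at most c (for
# dissimilarity matrices: whose distance to every test complex is at least c),
# and the similar-first (sd) set is its complement within the full training
# set. Sweeping c over a schedule yields nested families.

#' Build a cutoff schedule
#'
#' Generates the grid of cutoff values a sweep visits. Grid points are
#' produced from integer indices times the decimal step and rounded to the
#' step's decimal places, so comparisons like `s <= 0.99` are made against
#' the exact printed cutoffs with no binary-float drift; the similarity data
#' themselves are never rounded.
#'
#' @param start,end first and last cutoff (either order).
#' @param step positive decimal step size.
#' @return An object of class `cutoff_schedule` with fields `start`, `end`,
#'   `step`, `orientation` (`"ascending"`/`"descending"`) and `cutoffs`.
#' @examples
#' length(cutoff_schedule(0.40, 1.00, 0.01)$cutoffs) # 61
#' @export
cutoff_schedule <- function(start, end, step) {
  stopifnot(is.numeric(start), is.numeric(end), is.numeric(step), step > 0)
  d <- step_decimals(step)
  n <- round(abs(end - start) / step) + 1
  sgn <- if (end >= start) 1 else -1
  cutoffs <- round(start + sgn * step * (seq_len(n) - 1), d)
  structure(
    list(start = start, end = end, step = step,
         orientation = if (sgn > 0) "ascending" else "descending",
         cutoffs = cutoffs),
    class = "cutoff_schedule"
  )
}

# decimal places needed to represent `step` exactly (capped at 6)
step_decimals <- function(step) {
  for (d in 0:6) {
    if (abs(step * 10^d - round(step * 10^d)) < 1e-9) return(d)
  }
  6L
}

#' @export
print.cutoff_schedule <- function(x, ...) {
  cat("<cutoff_schedule> ", x$start, " -> ", x$end, " step ", x$step,
      " (", length(x$cutoffs), " cutoffs, ", x$orientation, ")\n", sep = "")
  invisible(x)
}

#' Default cutoff schedules per similarity metric
#'
#' The conventional sweep grids: protein-structure similarity 0.40 to 1.00
#' in steps of 0.01 (61 cutoffs), ligand-fingerprint similarity 0.50 to 1.00
#' in steps of 0.01 (51 cutoffs), pocket-topology dissimilarity 10.0 down to
#' 0.0 in steps of 0.2 (51 cutoffs). All three move in the direction of
#' increasing similarity to the test set.
#'
#' @param metric_name `"protein_structure"`, `"ligand_fingerprint"` or
#'   `"pocket_topology"`.
#' @return A [cutoff_schedule()].
#' @export
default_schedule <- function(metric_name = c("protein_structure",
                                             "ligand_fingerprint",
                                             "pocket_topology")) {
  metric_name <- match.arg(metric_name)
  switch(metric_name,
    protein_structure = cutoff_schedule(0.40, 1.00, 0.01),
    ligand_fingerprint = cutoff_schedule(0.50, 1.00, 0.01),
    pocket_topology = cutoff_schedule(10.0, 0.0, 0.2)
  )
}

#' Training complexes admitted at one cutoff
#'
#' Implements the four quantifier definitions. With a similarity matrix,
#' direction `"ds"` keeps training complexes `p` with `s(p, q) <= c` for all
#' test complexes `q`, and `"sd"` keeps those with `s(p, q) > c` for some
#' `q`. With a dissimilarity matrix the inequalities flip: `"ds"` keeps
#' `d(p, q) >= c` for all `q`, `"sd"` keeps `d(p, q) < c` for some `q`. At
#' any cutoff the ds and sd sets partition the full training set.
#'
#' @param m a [sim_matrix()].
#' @param cutoff numeric cutoff within the metric's value range.
#' @param direction `"ds"` (dissimilar-first) or `"sd"` (similar-first).
#' @return Character vector of training ids (in matrix column order).
#' @export
nested_set <- function(m, cutoff, direction = c("ds", "sd")) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "sim_matrix"))
  check_cutoff_range(m, cutoff)
  stat <- train_stat(m)
  keep <- if (m$kind == "similarity") {
    if (direction == "ds") stat <= cutoff else stat > cutoff
  } else {
    if (direction == "ds") stat >= cutoff else stat < cutoff
  }
  names(stat)[keep]
}

check_cutoff_range <- function(m, cutoffs) {
  if (m$kind == "similarity") {
    if (any(cutoffs < 0 | cutoffs > 1)) {
      abort("Similarity cutoffs must lie in [0, 1]")
    }
  } else if (any(cutoffs < 0)) {
    abort("Dissimilarity cutoffs must be non-negative")
  }
  invisible(TRUE)
}

#' Build a nested training-set family over a schedule
#'
#' Evaluates [nested_set()] at every cutoff of a schedule. Internally the
#' per-training-complex max (similarity) or min (dissimilarity) over test
#' complexes is computed once and thresholded, which is equivalent to the
#' quantifier definitions. Empty sets are legal; downstream training records
#' a missing curve point for them.
#'
#' @param m a [sim_matrix()].
#' @param schedule a [cutoff_schedule()]; every cutoff must lie in the metric's
#'   value range.
#' @param direction `"ds"` or `"sd"`.
#' @return An object of class `nested_family` with fields `metric_name`,
#'   `kind`, `direction`, `cutoffs`, `sets` (list of id vectors, one per
#'   cutoff) and `full_set`.
#' @export
build_family <- function(m, schedule, direction = c("ds", "sd")) {
  direction <- match.arg(direction)
  stopifnot(inherits(m, "sim_matrix"), inherits(schedule, "cutoff_schedule"))
  check_cutoff_range(m, schedule$cutoffs)
  stat <- train_stat(m)
  ids <- names(stat)
  sets <- lapply(schedule$cutoffs, function(cc) {
    keep <- if (m$kind == "similarity") {
      if (direction == "ds") stat <= cc else stat > cc
    } else {
      if (direction == "ds") stat >= cc else stat < cc
    }
    ids[keep]
  })
  names(sets) <- format_cutoff(schedule$cutoffs, schedule$step)
  structure(
    list(metric_name = m$metric_name, kind = m$kind, direction = direction,
         cutoffs = schedule$cutoffs, sets = sets, full_set = ids,
         schedule = schedule),
    class = "nested_family"
  )
}

format_cutoff <- function(cutoffs, step) {
  formatC(cutoffs, format = "f", digits = step_decimals(step))
}

#' @export
print.nested_family <- function(x, ...) {
  sizes <- vapply(x$sets, length, integer(1))
  cat("<nested_family> ", x$metric_name, " (", x$kind, ", ", x$direction,
      "): ", length(x$cutoffs), " cutoffs, |OT| = ", length(x$full_set),
      "\n  sizes: ", sizes[1], " ... ", sizes[length(sizes)], "\n", sep = "")
  invisible(x)
}

#' Training-set size at each cutoff of a family
#'
#' @param family a [build_family()] result.
#' @return A tibble with columns `cutoff` and `n_train`, in sweep order.
#' @export
family_sizes <- function(family) {
  stopifnot(inherits(family, "nested_family"))
  tibble::tibble(
    cutoff = family$cutoffs,
    n_train = unname(vapply(family$sets, length, integer(1)))
  )
}
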