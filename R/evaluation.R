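# Scoring-power evaluation: Rp/Rs/RMSE of predicted vs measured affinities,
# sweeps of scoring functions across nested training-set families, and the
# two curve diagnostics the analysis turns on -- crossing points (where one
# scoring function's curve first becomes better than another's) and leap
# deltas (per-increment changes, exposing sharp leaps over the
# near-duplicate band).

as_pred_vector <- function(pred) {
  if (is.data.frame(pred)) {
    if (".pred" %in% names(pred)) {
      return(stats::setNames(as.numeric(pred$.pred), normalize_id(pred$id)))
    }
    if ("affinity" %in% names(pred)) {
      return(stats::setNames(as.numeric(pred$affinity), normalize_id(pred$id)))
    }
    abort("Prediction table must have '.pred' or 'affinity' column")
  }
  if (is.numeric(pred) && !is.null(names(pred))) {
    return(stats::setNames(as.numeric(pred), normalize_id(names(pred))))
  }
  abort("Predictions must be a tibble (id, .pred) or a named numeric vector")
}

#' Scoring power of a set of predictions
#'
#' Computes the three standard scoring-power indicators over the complexes
#' shared by the prediction and observation maps: Pearson correlation (Rp),
#' Spearman correlation with average-rank ties (Rs), and root-mean-square
#' error in pK units (RMSE). Higher Rp/Rs and lower RMSE mean better
#' scoring power. Constant predictions have undefined correlations: Rp and
#' Rs come back `NA` while RMSE is still computed.
#'
#' @param pred predictions: tibble with `id`/`.pred` columns (as returned by
#'   [predict.sf_model()]) or a named numeric vector.
#' @param obs observed affinities: tibble with `id`/`affinity` columns or a
#'   named numeric vector.
#' @return A one-row tibble with columns `n`, `rp`, `rs`, `rmse`.
#' @examples
#' scoring_power(c(a = 1, b = 2, c = 3), c(a = 2, b = 4, c = 6))
#' @export
scoring_power <- function(pred, obs) {
  p <- as_pred_vector(pred)
  o <- as_affinity(obs)
  ids <- intersect(names(p), names(o))
  if (length(ids) < 2) {
    abort("Need at least 2 shared complexes to compute scoring power")
  }
  p <- p[ids]
  o <- o[ids]
  rp <- if (stats::sd(p) == 0 || stats::sd(o) == 0) NA_real_ else
    stats::cor(p, o, method = "pearson")
  rs <- if (stats::sd(p) == 0 || stats::sd(o) == 0) NA_real_ else
    stats::cor(p, o, method = "spearman")
  tibble::tibble(
    n = length(ids),
    rp = rp,
    rs = rs,
    rmse = sqrt(mean((p - o)^2))
  )
}

# minimum trainable set size per algorithm (design choice: p+2 rows for
# linear fits, 10 for ensembles; smaller sets become missing curve points)
min_trainable <- function(spec) {
  if (spec$algorithm == "MLR") length(spec$features) + 2L else 10L
}

derive_point_seed <- function(global_seed, k) {
  as.integer((as.numeric(global_seed) * 10007 + k) %% 2147483629)
}

#' Sweep scoring functions across a nested training-set family
#'
#' For every spec and every cutoff of the family: restrict the training
#' table to the nested set, fit the scoring function, predict the test set
#' and record its scoring power. Tree-ensemble fits are seeded per sweep
#' point from `(seed, cutoff index)`, so a sweep is reproducible end to end.
#' Nested sets below the minimum trainable size (p + 2 rows for MLR, 10 for
#' ensembles) yield missing (`NA`) curve points; `n_train` is still
#' recorded.
#'
#' @param specs a single [sf_spec()] or a list of them.
#' @param family a [build_family()] result built from the training side.
#' @param train_X,train_y training feature table and affinities.
#' @param test_X,test_y held-out test feature table and affinities; test ids
#'   must be disjoint from the family's full training set.
#' @param seed global integer seed for the sweep.
#' @return An `sf_curves` tibble: `sf_name`, `metric`, `direction`,
#'   `cutoff`, `n_train`, `rp`, `rs`, `rmse`, ordered by spec then sweep
#'   order.
#' @export
sweep_scoring <- function(specs, family, train_X, train_y, test_X, test_y,
                          seed = 1L) {
  if (inherits(specs, "sf_spec")) specs <- list(specs)
  stopifnot(inherits(family, "nested_family"))
  test_ids_ <- normalize_id(test_X$id)
  overlap <- intersect(test_ids_, family$full_set)
  if (length(overlap)) {
    abort(paste0("Training and test sets overlap: ",
                 paste(utils::head(overlap, 5), collapse = ", ")))
  }
  train_X <- train_X
  train_X$id <- normalize_id(train_X$id)
  rows <- purrr::map_dfr(specs, function(spec) {
    purrr::map_dfr(seq_along(family$cutoffs), function(k) {
      ids <- family$sets[[k]]
      out <- tibble::tibble(
        sf_name = spec$sf_name, metric = family$metric_name,
        direction = family$direction, cutoff = family$cutoffs[k],
        n_train = length(ids), rp = NA_real_, rs = NA_real_, rmse = NA_real_
      )
      if (length(ids) < min_trainable(spec)) return(out)
      sub_X <- train_X[train_X$id %in% ids, , drop = FALSE]
      spec_k <- spec
      spec_k$seed <- derive_point_seed(seed + spec$seed, k)
      fit <- tryCatch(fit_sf(spec_k, sub_X, train_y), error = function(e) NULL)
      if (is.null(fit)) return(out)
      sp <- scoring_power(predict(fit, test_X), test_y)
      out$rp <- sp$rp
      out$rs <- sp$rs
      out$rmse <- sp$rmse
      out
    })
  })
  class(rows) <- c("sf_curves", class(rows))
  rows
}

check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) || !isTRUE(all.equal(a$cutoff, b$cutoff))) {
    abort("Curves must share an identical cutoff grid")
  }
}

#' Locate the crossing point between two performance curves
#'
#' Finds the first cutoff (in sweep order) at which scoring function `sf_a`
#' is strictly better than `sf_b` on the chosen indicator (higher for
#' `rp`/`rs`, lower for `rmse`). Cutoffs where either curve is missing are
#' skipped. `sustained` is `TRUE` when `sf_a` stays at least as good as
#' `sf_b` at every comparable later cutoff -- the "from c onwards" reading
#' -- while the returned cutoff itself is the "surpassed at c" reading.
#'
#' @param curves an `sf_curves` tibble holding both scoring functions on one
#'   metric and direction (e.g. from [sweep_scoring()]).
#' @param sf_a,sf_b scoring-function names present in `curves`.
#' @param metric `"rp"`, `"rs"` or `"rmse"`.
#' @return A one-row tibble `sf_a`, `sf_b`, `metric`, `cutoff`, `n_train`,
#'   `sustained`, or a zero-row tibble when `sf_a` never wins.
#' @export
find_crossing <- function(curves, sf_a, sf_b, metric = c("rp", "rs", "rmse")) {
  metric <- match.arg(metric)
  a <- curves[curves$sf_name == sf_a, , drop = FALSE]
  b <- curves[curves$sf_name == sf_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("Both scoring functions must be present in `curves`")
  }
  check_same_grid(a, b)
  va <- a[[metric]]
  vb <- b[[metric]]
  better <- if (metric == "rmse") va < vb else va > vb
  at_least <- if (metric == "rmse") va <= vb else va >= vb
  comparable <- !is.na(better)
  hit <- which(better & comparable)
  empty <- tibble::tibble(sf_a = character(), sf_b = character(),
                          metric = character(), cutoff = double(),
                          n_train = integer(), sustained = logical())
  if (!length(hit)) return(empty)
  k <- hit[1]
  later <- which(comparable & seq_along(better) > k)
  tibble::tibble(
    sf_a = sf_a, sf_b = sf_b, metric = metric,
    cutoff = a$cutoff[k], n_train = as.integer(a$n_train[k]),
    sustained = all(at_least[later])
  )
}

#' Per-increment changes along a performance curve
#'
#' Returns the difference in the chosen indicator between every pair of
#' consecutive cutoffs, making "sharp leaps" -- unusually large increments,
#' typically over the final near-duplicate band -- easy to locate via the
#' largest delta.
#'
#' @param curves an `sf_curves` tibble (one or several scoring functions).
#' @param metric `"rp"`, `"rs"` or `"rmse"`.
#' @return A tibble `sf_name`, `from`, `to`, `delta` in sweep order; deltas
#'   touching a missing point are `NA`.
#' @export
leap_deltas <- function(curves, metric = c("rp", "rs", "rmse")) {
  metric <- match.arg(metric)
  purrr::map_dfr(split(curves, curves$sf_name), function(cv) {
    cv <- cv[order(seq_len(nrow(cv))), , drop = FALSE]
    if (sum(!is.na(cv[[metric]])) < 2) {
      abort("Need at least 2 non-missing points to compute deltas")
    }
    v <- cv[[metric]]
    n <- length(v)
    tibble::tibble(
      sf_name = cv$sf_name[1],
      from = cv$cutoff[-n],
      to = cv$cutoff[-1],
      delta = v[-1] - v[-n]
    )
  })
}

#' Export measured-versus-predicted pairs for a scatter plot
#'
#' Writes a table with columns `id`, `measured`, `predicted` over the
#' complexes shared by the two maps, and optionally renders a scatter plot
#' alongside it.
#'
#' @param pred predictions (tibble `id`/`.pred` or named vector).
#' @param obs measured affinities (tibble `id`/`affinity` or named vector).
#' @param path output TSV/CSV path.
#' @param plot if `TRUE`, also writes `<path>.png` with the scatter.
#' @return The scatter tibble, invisibly.
#' @export
export_scatter <- function(pred, obs, path, plot = FALSE) {
  p <- as_pred_vector(pred)
  o <- as_affinity(obs)
  ids <- intersect(names(p), names(o))
  if (!length(ids)) abort("No shared complexes between predictions and observations")
  tbl <- tibble::tibble(id = ids, measured = unname(o[ids]),
                        predicted = unname(p[ids]))
  readr::write_delim(tbl, path, delim = delim_for(path))
  if (isTRUE(plot)) {
    gg <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$measured,
                                            y = .data$predicted)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = "Measured affinity (pK)",
                    y = "Predicted affinity (pK)")
    ggplot2::ggsave(paste0(path, ".png"), gg, width = 5, height = 5, dpi = 150)
  }
  invisible(tbl)
}

#' Plot performance curves
#'
#' One line per scoring function against the similarity cutoff, faceted by
#' metric and direction when several are present.
#'
#' @param object an `sf_curves` tibble.
#' @param metric `"rp"`, `"rs"` or `"rmse"`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.sf_curves <- function(object, metric = c("rp", "rs", "rmse"), ...) {
  metric <- match.arg(metric)
  gg <- ggplot2::ggplot(object,
                        ggplot2::aes(x = .data$cutoff, y = .data[[metric]],
                                     colour = .data$sf_name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "similarity cutoff", y = metric, colour = NULL)
  if (length(unique(object$metric)) > 1 ||
      length(unique(object$direction)) > 1) {
    gg <- gg + ggplot2::facet_grid(direction ~ metric)
  }
  gg
}

#' @export
plot.sf_curves <- function(x, ...) print(autoplot.sf_curves(x, ...))

#' Plot a training-complex skew histogram
#'
#' Bars show how many training complexes newly enter the nested training
#' set at each cutoff increment; the line is the cumulative training-set
#' size.
#'
#' @param hist tibble from [skew_histogram()].
#' @return A ggplot object.
#' @export
plot_skew_histogram <- function(hist) {
  hist$mid <- (hist$lower + hist$upper) / 2
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = min(abs(hist$upper - hist$lower)) * 0.9,
                      fill = "grey40") +
    ggplot2::labs(x = "cutoff increment", y = "additional training complexes")
}
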