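# The eight scoring functions behind one fit/predict contract. Classical
# scoring functions are ordinary-least-squares recalibrations of fixed
# descriptor subsets; the machine-learning counterparts reuse exactly the
# same descriptors but swap the regression algorithm for a tree ensemble,
# so any performance difference is attributable to the algorithm alone.

# ---- input alignment ------------------------------------------------------

as_affinity <- function(y) {
  if (is.data.frame(y)) {
    if (!all(c("id", "affinity") %in% names(y))) {
      abort("Affinity table must have columns 'id' and 'affinity'")
    }
    v <- stats::setNames(as.numeric(y$affinity), normalize_id(y$id))
  } else if (is.numeric(y) && !is.null(names(y))) {
    v <- stats::setNames(as.numeric(y), normalize_id(names(y)))
  } else {
    abort("`y` must be a tibble with id/affinity columns or a named numeric")
  }
  if (anyDuplicated(names(v))) abort("Duplicate ids in affinity table")
  if (any(!is.finite(v))) abort("Affinities must be finite")
  v
}

feature_matrix <- function(X, features, sf_name = NULL) {
  if (!is.data.frame(X) || !"id" %in% names(X)) {
    abort("Feature table must be a data frame with an 'id' column")
  }
  missing <- setdiff(features, names(X))
  if (length(missing)) {
    abort(paste0("Feature table lacks column(s) ",
                 paste(missing, collapse = ", "),
                 if (!is.null(sf_name)) paste0(" required by ", sf_name) else ""))
  }
  m <- as.matrix(X[, features, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) abort("Feature values must be finite")
  rownames(m) <- normalize_id(X$id)
  m
}

align_xy <- function(X, y, features, sf_name = NULL) {
  m <- feature_matrix(X, features, sf_name)
  yv <- as_affinity(y)
  ids <- rownames(m)
  missing <- setdiff(ids, names(yv))
  if (length(missing)) {
    abort(paste0("No affinity for complex(es): ",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  list(mat = m, y = unname(yv[ids]), ids = ids)
}

new_sf_model <- function(type, spec, fields) {
  structure(c(list(type = type, spec = spec), fields), class = "sf_model")
}

# ---- ordinary least squares ----------------------------------------------

# OLS with intercept; errors name collinear columns on rank deficiency.
ols_fit <- function(mat, y) {
  n <- nrow(mat)
  p <- ncol(mat)
  if (n < p + 1) {
    abort(paste0("Need at least ", p + 1, " rows to fit ", p,
                 " coefficients plus intercept; got ", n))
  }
  design <- cbind(`(Intercept)` = 1, mat)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    aliased <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    abort(paste0("Rank-deficient design; collinear column(s): ",
                 paste(aliased, collapse = ", ")))
  }
  stats::setNames(as.numeric(qr.coef(qrd, y)), colnames(design))
}

ols_predict <- function(coefs, mat) {
  as.numeric(coefs[1] + mat %*% coefs[-1])
}

#' Fit a multiple-linear-regression scoring function
#'
#' Ordinary least squares with intercept on the given descriptor columns,
#' the calibration procedure of classical scoring functions. Coefficients
#' are unconstrained in sign.
#'
#' @param X feature table (tibble with `id` + descriptor columns).
#' @param y affinities: tibble with `id`/`affinity` columns or a named
#'   numeric vector, pK units.
#' @param features descriptor columns to use; default all non-id columns.
#' @return An `sf_model` of type `"mlr"`.
#' @export
fit_mlr <- function(X, y, features = NULL) {
  features <- features %||% setdiff(names(X), "id")
  d <- align_xy(X, y, features)
  coefs <- ols_fit(d$mat, d$y)
  new_sf_model("mlr", NULL, list(
    sf_name = "MLR", features = features, coefficients = coefs,
    training_ids = d$ids
  ))
}

#' Fit the X-Score consensus scoring function
#'
#' X-Score is a consensus of three parallel linear scoring functions sharing
#' the van der Waals, hydrogen-bond and rotor-penalty terms and differing
#' only in the hydrophobic-effect term (`HP`, `HM` or `HS`). Each
#' constituent is calibrated independently by OLS on the training set and
#' the predicted affinity is the arithmetic mean of the three constituent
#' predictions.
#'
#' @inheritParams fit_mlr
#' @return An `sf_model` of type `"mlr_consensus"`.
#' @export
fit_mlr_xscore <- function(X, y) {
  subsets <- list(
    HP = c("VDW", "HB", "RT", "HP"),
    HM = c("VDW", "HB", "RT", "HM"),
    HS = c("VDW", "HB", "RT", "HS")
  )
  d <- align_xy(X, y, feature_subset("XSCORE6"), "MLR::Xscore")
  constituents <- lapply(subsets, function(f) {
    ols_fit(d$mat[, f, drop = FALSE], d$y)
  })
  new_sf_model("mlr_consensus", NULL, list(
    sf_name = "MLR::Xscore", features = feature_subset("XSCORE6"),
    constituents = constituents, constituent_features = subsets,
    training_ids = d$ids
  ))
}

#' Fit the Vina-style quasi-linear scoring function
#'
#' AutoDock Vina normalizes the weighted sum of its five empirical terms by
#' `1 + w_rot * Nrot`, where `Nrot` is the ligand's rotatable-bond count
#' and `w_rot` is a fixed weight that is adopted without recalibration.
#' Equivalently, each of the five term columns is divided row-wise by
#' `1 + w_rot * Nrot` and OLS is run on the transformed design; the
#' intercept is fitted on the transformed design, i.e. outside the
#' normalization. Prediction applies the same transform.
#'
#' @inheritParams fit_mlr
#' @param nrot_weight fixed rotor weight `w_rot`; the default 0.05846 is the
#'   published AutoDock Vina value.
#' @return An `sf_model` of type `"mlr_vina"`.
#' @export
fit_mlr_vina <- function(X, y, nrot_weight = 0.05846) {
  feats <- feature_subset("VINA6")
  d <- align_xy(X, y, feats, "MLR::Vina")
  terms <- setdiff(feats, "Nrot")
  nrot <- d$mat[, "Nrot"]
  if (any(nrot < 0)) abort("Nrot values must be non-negative")
  denom <- 1 + nrot_weight * nrot
  if (any(denom <= 0)) {
    abort("1 + nrot_weight * Nrot must be positive for every row")
  }
  tmat <- d$mat[, terms, drop = FALSE] / denom
  coefs <- ols_fit(tmat, d$y)
  new_sf_model("mlr_vina", NULL, list(
    sf_name = "MLR::Vina", features = feats, terms = terms,
    coefficients = coefs, nrot_weight = nrot_weight, training_ids = d$ids
  ))
}

# ---- tree ensembles -------------------------------------------------------

rf_defaults <- function(p) list(ntree = 500L, mtry = max(1L, floor(p / 3)),
                                min_node = 5L)
xgb_defaults <- function() list(nrounds = 500L, eta = 0.05, max_depth = 6L,
                                subsample = 0.8, min_node = 5L)

#' Fit a tree-ensemble scoring function
#'
#' Fits either a random forest (bootstrap-aggregated CART regression trees
#' with per-split feature subsampling; `RF::*` names) or a gradient-boosted
#' tree ensemble (squared loss, shrinkage, row subsampling, depth-limited
#' trees; `XGB::*` names) on the spec's descriptor subset. Fits are seeded
#' from `spec$seed`, so the same spec, data and seed give bit-identical
#' predictions.
#'
#' Defaults follow random-forest convention for regression: 500 trees,
#' `mtry = max(1, floor(p/3))`, terminal node size 5. Boosting defaults:
#' 500 rounds, learning rate 0.05, depth 6, subsample 0.8.
#'
#' @inheritParams fit_mlr
#' @param spec an [sf_spec()] whose `sf_name` has an `RF::` or `XGB::`
#'   prefix.
#' @return An `sf_model` of type `"forest"` or `"gbm"`.
#' @export
fit_tree_ensemble <- function(X, y, spec) {
  stopifnot(inherits(spec, "sf_spec"))
  if (!spec$algorithm %in% c("RF", "XGB")) {
    abort(paste0("'", spec$sf_name, "' is not a tree-ensemble scoring function"))
  }
  d <- align_xy(X, y, spec$features, spec$sf_name)
  if (nrow(d$mat) < 2) abort("Need at least 2 training rows")
  set.seed(spec$seed)
  if (spec$algorithm == "RF") {
    hp <- utils::modifyList(rf_defaults(ncol(d$mat)), spec$hyperparams)
    trees <- fit_forest_cpp(d$mat, d$y, as.integer(hp$ntree),
                            as.integer(hp$mtry), as.integer(hp$min_node))
    new_sf_model("forest", spec, list(
      sf_name = spec$sf_name, features = spec$features, trees = trees,
      hyperparams = hp, training_ids = d$ids
    ))
  } else {
    hp <- utils::modifyList(xgb_defaults(), spec$hyperparams)
    fit <- fit_gbm_cpp(d$mat, d$y, as.integer(hp$nrounds), hp$eta,
                       as.integer(hp$max_depth), hp$subsample,
                       as.integer(hp$min_node))
    new_sf_model("gbm", spec, list(
      sf_name = spec$sf_name, features = spec$features, trees = fit$trees,
      init = fit$init, hyperparams = hp, training_ids = d$ids
    ))
  }
}

# ---- unified fit dispatcher ----------------------------------------------

#' Fit any registered scoring function from its specification
#'
#' Dispatches to [fit_mlr_xscore()], [fit_mlr_vina()], [fit_mlr()] (for
#' MLR::Cyscore) or [fit_tree_ensemble()] according to `spec$sf_name`.
#'
#' @inheritParams fit_tree_ensemble
#' @param spec an [sf_spec()].
#' @return An `sf_model`.
#' @examples
#' bench <- generate_benchmark(synth_config(n_train = 80, n_test = 10,
#'                                          n_clusters = 4, seed = 1))
#' m <- fit_sf(sf_spec("MLR::Cyscore"), bench$train_features,
#'             bench$train_affinities)
#' head(predict(m, bench$test_features))
#' @export
fit_sf <- function(spec, X, y) {
  stopifnot(inherits(spec, "sf_spec"))
  switch(spec$sf_name,
    "MLR::Xscore" = {
      m <- fit_mlr_xscore(X, y)
      m$spec <- spec
      m
    },
    "MLR::Vina" = {
      w <- spec$hyperparams$nrot_weight %||% 0.05846
      m <- fit_mlr_vina(X, y, nrot_weight = w)
      m$spec <- spec
      m
    },
    "MLR::Cyscore" = {
      m <- fit_mlr(X, y, features = spec$features)
      m$sf_name <- "MLR::Cyscore"
      m$spec <- spec
      m
    },
    fit_tree_ensemble(X, y, spec)
  )
}

# ---- prediction -----------------------------------------------------------

#' Predict binding affinities with a fitted scoring function
#'
#' @param object an `sf_model`.
#' @param X feature table containing at least the model's descriptor
#'   columns.
#' @param ... unused.
#' @return A tibble with columns `id` and `.pred` (pK units), rows in table
#'   order.
#' @export
predict.sf_model <- function(object, X, ...) {
  mat <- feature_matrix(X, object$features, object$sf_name)
  pred <- switch(object$type,
    mlr = ols_predict(object$coefficients, mat),
    mlr_consensus = {
      ps <- lapply(names(object$constituents), function(k) {
        ols_predict(object$constituents[[k]],
                    mat[, object$constituent_features[[k]], drop = FALSE])
      })
      Reduce(`+`, ps) / length(ps)
    },
    mlr_vina = {
      denom <- 1 + object$nrot_weight * mat[, "Nrot"]
      if (any(denom <= 0)) {
        abort("1 + nrot_weight * Nrot must be positive for every row")
      }
      ols_predict(object$coefficients,
                  mat[, object$terms, drop = FALSE] / denom)
    },
    forest = as.numeric(predict_trees_cpp(object$trees, mat, TRUE, 0, 1)),
    gbm = as.numeric(predict_trees_cpp(object$trees, mat, FALSE, object$init,
                                       object$hyperparams$eta)),
    abort(paste0("Unknown model type '", object$type, "'"))
  )
  if (any(!is.finite(pred))) abort("Non-finite prediction produced")
  tibble::tibble(id = rownames(mat), .pred = pred)
}

#' @export
print.sf_model <- function(x, ...) {
  cat("<sf_model> ", x$sf_name, " (", x$type, "), trained on ",
      length(x$training_ids), " complexes\n", sep = "")
  invisible(x)
}

# ---- broom-style accessors ------------------------------------------------

#' Tidy a fitted scoring function
#'
#' Linear models return one row per coefficient (consensus models add a
#' `constituent` column); tree ensembles return one row per hyperparameter,
#' since individual trees have no meaningful per-term summary.
#'
#' @param x an `sf_model`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.sf_model <- function(x, ...) {
  switch(x$type,
    mlr = ,
    mlr_vina = tibble::tibble(term = names(x$coefficients),
                              estimate = unname(x$coefficients)),
    mlr_consensus = purrr::map_dfr(names(x$constituents), function(k) {
      tibble::tibble(constituent = k, term = names(x$constituents[[k]]),
                     estimate = unname(x$constituents[[k]]))
    }),
    tibble::tibble(term = names(x$hyperparams),
                   estimate = as.numeric(unlist(x$hyperparams)))
  )
}

#' Glance at a fitted scoring function
#'
#' @param x an `sf_model`.
#' @param ... unused.
#' @return A one-row tibble with the scoring-function name, model family,
#'   training-set size and descriptor count.
#' @export
glance.sf_model <- function(x, ...) {
  tibble::tibble(
    sf_name = x$sf_name,
    type = x$type,
    n_train = length(x$training_ids),
    n_features = length(x$features)
  )
}

# ---- serialization --------------------------------------------------------

#' Save or restore a fitted scoring function as JSON
#'
#' The file is self-describing (model type, feature names, coefficients or
#' the full tree ensemble) and a round trip restores identical predictions.
#'
#' @param model an `sf_model`.
#' @param path file path.
#' @return `write_sf_model()`: `path` invisibly; `read_sf_model()`: the
#'   restored `sf_model`.
#' @export
write_sf_model <- function(model, path) {
  stopifnot(inherits(model, "sf_model"))
  payload <- unclass(model)
  payload$spec <- if (!is.null(model$spec)) unclass(model$spec) else NULL
  if (!is.null(payload$trees)) {
    payload$trees <- lapply(payload$trees, function(m) {
      list(dim = dim(m), data = as.numeric(m))
    })
  }
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_sf_model
#' @export
read_sf_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(payload$trees)) {
    if (is.data.frame(payload$trees)) payload$trees <- split_df_rows(payload$trees)
    payload$trees <- lapply(payload$trees, function(t) {
      m <- matrix(as.numeric(unlist(t$data)), nrow = unlist(t$dim)[1])
      colnames(m) <- c("feature", "threshold", "left", "right", "value")
      m
    })
  }
  for (f in c("coefficients")) {
    if (!is.null(payload[[f]])) payload[[f]] <- unlist(payload[[f]])
  }
  if (!is.null(payload$constituents)) {
    payload$constituents <- lapply(payload$constituents, unlist)
    payload$constituent_features <- lapply(payload$constituent_features, unlist)
  }
  if (!is.null(payload$spec)) {
    sp <- payload$spec
    payload$spec <- sf_spec(sp$sf_name, seed = sp$seed,
                            hyperparams = as.list(sp$hyperparams))
  }
  payload$features <- unlist(payload$features)
  payload$training_ids <- unlist(payload$training_ids)
  if (!is.null(payload$terms)) payload$terms <- unlist(payload$terms)
  if (!is.null(payload$hyperparams)) {
    payload$hyperparams <- as.list(payload$hyperparams)
  }
  structure(payload, class = "sf_model")
}

split_df_rows <- function(df) lapply(seq_len(nrow(df)), function(i) df[i, ])
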