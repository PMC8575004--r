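#' Registered scoring-function descriptor vocabulary
#'
#' The pipeline works on a fixed 16-descriptor vocabulary drawn from three
#' classical scoring functions: six X-Score terms (van der Waals, hydrogen
#' bonding, rotor/deformation penalty, and three alternative hydrophobic-effect
#' terms), six Vina terms (two attractive gaussian steric terms, a repulsive
#' steric term, hydrophobic and hydrogen-bond terms, and the ligand-only
#' rotatable-bond count `Nrot`), and four Cyscore terms. `feature_registry()`
#' returns the named subsets; `feature_subset()` resolves a registry key.
#'
#' @return `feature_registry()`: a named list of character vectors with
#'   elements `XSCORE6`, `VINA6`, `CYSCORE4` and `XVC16` (their union, 16
#'   descriptors).
#' @examples
#' feature_registry()$XSCORE6
#' feature_subset("CYSCORE4")
#' @export
feature_registry <- function() {
  xscore6 <- c("VDW", "HB", "RT", "HP", "HM", "HS")
  vina6 <- c("gauss1", "gauss2", "repulsion", "hydrophobic", "hbond", "Nrot")
  cyscore4 <- c("hydrophobic_free_energy", "vdw_energy", "hbond_energy",
                "ligand_entropy")
  list(
    XSCORE6 = xscore6,
    VINA6 = vina6,
    CYSCORE4 = cyscore4,
    XVC16 = c(xscore6, vina6, cyscore4)
  )
}

#' @rdname feature_registry
#' @param key registry key, one of `"XSCORE6"`, `"VINA6"`, `"CYSCORE4"`,
#'   `"XVC16"`.
#' @export
feature_subset <- function(key) {
  reg <- feature_registry()
  if (!key %in% names(reg)) {
    abort(paste0("Unknown feature registry key '", key, "'; expected one of ",
                 paste(names(reg), collapse = ", ")))
  }
  reg[[key]]
}

#' Supported scoring-function names
#'
#' Eight scoring functions are supported: three classical multiple linear
#' regression (MLR) calibrations and five tree-ensemble counterparts. The
#' prefix names the regression algorithm, the suffix the feature subset.
#'
#' @return Character vector of the eight `sf_name` values.
#' @examples
#' sf_names()
#' @export
sf_names <- function() {
  c("MLR::Xscore", "MLR::Vina", "MLR::Cyscore",
    "RF::Xscore", "RF::Vina", "RF::Cyscore",
    "RF::XVC", "XGB::XVC")
}

# sf_name -> registry key (fixed mapping; suffix decides the subset)
sf_feature_key <- function(sf_name) {
  suffix <- sub("^[A-Z]+::", "", sf_name)
  switch(suffix,
    Xscore = "XSCORE6",
    Vina = "VINA6",
    Cyscore = "CYSCORE4",
    XVC = "XVC16",
    abort(paste0("Unknown scoring function '", sf_name, "'"))
  )
}

sf_algorithm <- function(sf_name) {
  prefix <- sub("::.*$", "", sf_name)
  if (!prefix %in% c("MLR", "RF", "XGB")) {
    abort(paste0("Unknown scoring function '", sf_name, "'"))
  }
  prefix
}

#' Declare a scoring-function model specification
#'
#' A model specification pairs a scoring-function name with its (fixed)
#' feature subset, a random seed and optional hyperparameter overrides.
#' The feature subset is determined by the name and cannot be chosen freely:
#' `*::Xscore` models use the six X-Score terms, `*::Vina` the six Vina terms,
#' `*::Cyscore` the four Cyscore terms and `*::XVC` all sixteen.
#'
#' @param sf_name one of [sf_names()].
#' @param seed integer seed used when fitting stochastic models (tree
#'   ensembles); ignored by MLR fits.
#' @param hyperparams named list of hyperparameter overrides. RF family:
#'   `ntree` (500), `mtry` (`max(1, floor(p/3))`), `min_node` (5). XGB family:
#'   `nrounds` (500), `eta` (0.05), `max_depth` (6), `subsample` (0.8),
#'   `min_node` (5). MLR::Vina: `nrot_weight` (0.05846).
#' @return An object of class `sf_spec`.
#' @examples
#' sf_spec("RF::XVC", seed = 7)
#' @export
sf_spec <- function(sf_name, seed = 1L, hyperparams = list()) {
  sf_name <- match.arg(sf_name, sf_names())
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (!is.list(hyperparams)) abort("`hyperparams` must be a named list")
  structure(
    list(
      sf_name = sf_name,
      algorithm = sf_algorithm(sf_name),
      feature_subset = sf_feature_key(sf_name),
      features = feature_subset(sf_feature_key(sf_name)),
      seed = as.integer(seed),
      hyperparams = hyperparams
    ),
    class = "sf_spec"
  )
}

#' @export
print.sf_spec <- function(x, ...) {
  cat("<sf_spec> ", x$sf_name, "\n", sep = "")
  cat("  features (", x$feature_subset, "): ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  if (length(x$hyperparams)) {
    cat("  hyperparams: ",
        paste(names(x$hyperparams), unlist(x$hyperparams),
              sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
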