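# Shared fixtures: everything is generated in code at test time.

# tiny deterministic benchmark for fast end-to-end tests
tiny_bench <- function(seed = 1, n_train = 120, n_test = 15, n_clusters = 5,
                       ...) {
  generate_benchmark(synth_config(n_train = n_train, n_test = n_test,
                                  n_clusters = n_clusters, seed = seed, ...))
}

# random labeled similarity/dissimilarity matrix
random_sim_matrix <- function(n_test, n_train, kind = "similarity",
                              metric_name = "other") {
  vals <- if (kind == "similarity") {
    matrix(runif(n_test * n_train), n_test)
  } else {
    matrix(rexp(n_test * n_train, rate = 0.3), n_test)
  }
  dimnames(vals) <- list(sprintf("q%03d", seq_len(n_test)),
                         sprintf("p%03d", seq_len(n_train)))
  sim_matrix(vals, kind, metric_name)
}

# random sparse-ish fingerprint as an on-bit integer set
random_fp <- function(n_bits = 30, universe = 512) {
  sort(sample.int(universe, n_bits) - 1L)
}

# brute-force quantifier evaluation of the four nested-set definitions;
# independent of the max/min-threshold shortcut used by the package
brute_nested_set <- function(m, cutoff, direction) {
  v <- m$values
  ids <- colnames(v)
  keep <- vapply(seq_along(ids), function(j) {
    col <- v[, j]
    if (m$kind == "similarity") {
      if (direction == "ds") all(col <= cutoff) else any(col > cutoff)
    } else {
      if (direction == "ds") all(col >= cutoff) else any(col < cutoff)
    }
  }, logical(1))
  ids[keep]
}

# small feature table + affinities with a known linear law
linear_toy <- function(n = 50, p = 4, seed = 99, sd = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, dimnames = list(NULL, paste0("f", seq_len(p))))
  w <- seq_len(p) / 2
  y <- 1.5 + as.numeric(X %*% w) + rnorm(n, sd = sd)
  list(
    X = dplyr::bind_cols(tibble::tibble(id = sprintf("c%03d", seq_len(n))),
                         tibble::as_tibble(X)),
    y = tibble::tibble(id = sprintf("c%03d", seq_len(n)), affinity = y),
    w = w, intercept = 1.5
  )
}

# feature table on the registered 16-descriptor vocabulary with random
# values (affinity from an arbitrary fixed law unless given)
xvc_toy <- function(n = 60, seed = 7, y = NULL) {
  set.seed(seed)
  feats <- feature_registry()$XVC16
  X <- matrix(rnorm(n * 16), n, dimnames = list(NULL, feats))
  X[, "Nrot"] <- rpois(n, 5)
  ids <- sprintf("x%03d", seq_len(n))
  if (is.null(y)) y <- 4 + as.numeric(X %*% rep(0.2, 16)) + rnorm(n, 0.3)
  list(
    X = dplyr::bind_cols(tibble::tibble(id = ids),
                         tibble::as_tibble(X, .name_repair = "minimal")),
    y = tibble::tibble(id = ids, affinity = y)
  )
}
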