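# Rp/Rs/RMSE, sweeps, crossing points, leap deltas and scatter export.

test_that("scoring_power matches closed forms and handles degenerate input", {
  sp <- scoring_power(c(a = 1, b = 2, c = 3), c(a = 1, b = 2, c = 3))
  expect_equal(unlist(sp[c("rp", "rs", "rmse")]), c(rp = 1, rs = 1, rmse = 0))

  sp <- scoring_power(c(a = 1, b = 2, c = 3), c(a = 3, b = 2, c = 1))
  expect_equal(sp$rs, -1)

  sp <- scoring_power(c(a = 1, b = 2, c = 3), c(a = 2, b = 4, c = 6))
  expect_equal(sp$rp, 1)
  expect_equal(sp$rmse, sqrt(14 / 3))

  # constant predictions: undefined correlations, RMSE still defined
  sp <- scoring_power(c(a = 2, b = 2, c = 2), c(a = 1, b = 2, c = 3))
  expect_true(is.na(sp$rp) && is.na(sp$rs))
  expect_equal(sp$rmse, sqrt(2 / 3))

  expect_error(scoring_power(c(a = 1), c(a = 1)), "at least 2")
  expect_error(scoring_power(c(a = 1, b = 2), c(x = 1, y = 2)), "at least 2")

  # affine-positive rescaling leaves correlations alone but not RMSE
  set.seed(51)
  pred <- rnorm(20); names(pred) <- letters[1:20]
  obs <- pred + rnorm(20); names(obs) <- letters[1:20]
  a <- scoring_power(pred, obs)
  b <- scoring_power(2.5 * pred + 1, obs)
  expect_equal(a$rp, b$rp, tolerance = 1e-12)
  expect_equal(a$rs, b$rs, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$rmse, b$rmse)))
})

test_that("sweep produces one point per cutoff with family sizes", {
  b <- tiny_bench(seed = 52, n_train = 100, n_test = 12)
  fam <- build_family(b$protein, cutoff_schedule(0.5, 1, 0.25), "ds")
  curves <- sweep_scoring(sf_spec("MLR::Cyscore"), fam,
                          b$train_features, b$train_affinities,
                          b$test_features, b$test_affinities)
  expect_equal(nrow(curves), 3L)
  expect_equal(curves$n_train, family_sizes(fam)$n_train)
  expect_true(all(c("rp", "rs", "rmse") %in% names(curves)))

  # train/test overlap is refused
  expect_error(
    sweep_scoring(sf_spec("MLR::Cyscore"), fam, b$train_features,
                  b$train_affinities, b$train_features[1:5, ],
                  b$train_affinities[1:5, ]),
    "overlap")
})

test_that("noiseless linear truth gives rp = 1 for MLR at every usable cutoff", {
  cfg <- synth_config(n_train = 200, n_test = 25, n_clusters = 6,
                      noise_sd = 0, nonlinear_strength = 0, seed = 53)
  b <- generate_benchmark(cfg)
  fam <- build_family(b$protein, cutoff_schedule(0.4, 1, 0.1), "ds")
  curves <- sweep_scoring(sf_spec("RF::XVC"), fam, b$train_features,
                          b$train_affinities, b$test_features,
                          b$test_affinities)
  # use the full 16-descriptor linear model: MLR::* subsets see only part
  # of the planted law, so recoverability needs all 16 columns
  mlr_fit <- fit_mlr(b$train_features, b$train_affinities)
  sp <- scoring_power(predict(mlr_fit, b$test_features), b$test_affinities)
  expect_equal(sp$rp, 1, tolerance = 1e-9)
  expect_lt(sp$rmse, 1e-9)
  # sub-minimal nested sets are missing points, not errors
  expect_true(all(is.na(curves$rp[curves$n_train < 10])))
})

test_that("find_crossing implements first-strict-win plus sustained flag", {
  grid <- c(0.8, 0.9, 1.0)
  mk <- function(name, rp) tibble::tibble(
    sf_name = name, metric = "protein_structure", direction = "ds",
    cutoff = grid, n_train = c(10L, 20L, 30L), rp = rp, rs = rp, rmse = 1 - rp)
  curves <- dplyr::bind_rows(mk("A", c(0.3, 0.5, 0.6)),
                             mk("B", c(0.4, 0.45, 0.55)))
  hit <- find_crossing(curves, "A", "B", "rp")
  expect_equal(hit$cutoff, 0.9)
  expect_true(hit$sustained)
  expect_equal(hit$n_train, 20L)

  # rmse sense is inverted: lower is better
  hit_rmse <- find_crossing(curves, "A", "B", "rmse")
  expect_equal(hit_rmse$cutoff, 0.9)

  # always-better crosses at the first grid point, sustained
  curves2 <- dplyr::bind_rows(mk("A", c(0.5, 0.6, 0.7)),
                              mk("B", c(0.3, 0.4, 0.5)))
  hit2 <- find_crossing(curves2, "A", "B", "rp")
  expect_equal(hit2$cutoff, 0.8)
  expect_true(hit2$sustained)

  # never better: empty result; grid mismatch: error
  expect_equal(nrow(find_crossing(curves2, "B", "A", "rp")), 0L)
  short <- dplyr::bind_rows(mk("A", c(0.5, 0.6, 0.7)),
                            mk("B", c(0.3, 0.4, 0.5))[1:2, ])
  expect_error(find_crossing(short, "A", "B", "rp"), "identical cutoff grid")

  # a transient win is found but flagged unsustained
  curves3 <- dplyr::bind_rows(mk("A", c(0.5, 0.3, 0.3)),
                              mk("B", c(0.4, 0.4, 0.4)))
  hit3 <- find_crossing(curves3, "A", "B", "rp")
  expect_equal(hit3$cutoff, 0.8)
  expect_false(hit3$sustained)
})

test_that("leap_deltas exposes per-increment changes", {
  cv <- tibble::tibble(
    sf_name = "A", metric = "protein_structure", direction = "ds",
    cutoff = c(0.98, 0.99, 1.0), n_train = c(5L, 6L, 9L),
    rp = c(0.5, 0.5, 0.6), rs = c(0.5, 0.5, 0.6), rmse = c(1, 1, 0.9))
  d <- leap_deltas(cv, "rp")
  expect_equal(d$delta, c(0, 0.1))
  expect_equal(d$to[which.max(d$delta)], 1.0)

  cv$rp <- 0.4
  expect_equal(leap_deltas(cv, "rp")$delta, c(0, 0))

  expect_error(leap_deltas(cv[1, ], "rp"), "at least 2")
})

test_that("scatter export writes shared pairs and refuses empty overlap", {
  pred <- c(a = 1.1, b = 2.2, c = 3.3)
  obs <- c(a = 1, b = 2, c = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  tbl <- export_scatter(pred, obs, path)
  expect_equal(nrow(tbl), 3L)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$measured, c(1, 2, 3), tolerance = 1e-6)
  expect_equal(back$predicted, c(1.1, 2.2, 3.3), tolerance = 1e-6)
  expect_error(export_scatter(c(z = 1), obs, path), "No shared complexes")
})

test_that("curve and histogram plots build", {
  b <- tiny_bench(seed = 54, n_train = 60, n_test = 8)
  fam <- build_family(b$protein, cutoff_schedule(0.5, 1, 0.25), "ds")
  curves <- sweep_scoring(sf_spec("MLR::Cyscore"), fam, b$train_features,
                          b$train_affinities, b$test_features,
                          b$test_affinities)
  expect_s3_class(ggplot2::autoplot(curves, "rp"), "ggplot")
  h <- skew_histogram(b$protein, cutoff_schedule(0.5, 1, 0.05))
  expect_s3_class(plot_skew_histogram(h), "ggplot")
})
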