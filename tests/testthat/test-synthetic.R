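# The synthetic benchmark generator: determinism, shapes, planted skew,
# parameter recovery and the similarity-informativeness coupling the whole
# analysis presumes.

test_that("the generator is deterministic and shape-correct", {
  cfg <- synth_config(n_train = 100, n_test = 10, n_clusters = 6, seed = 61)
  b1 <- generate_benchmark(cfg)
  b2 <- generate_benchmark(cfg)
  expect_identical(b1$train_features, b2$train_features)
  expect_identical(b1$test_affinities, b2$test_affinities)
  expect_identical(b1$protein$values, b2$protein$values)
  expect_identical(b1$ligand$values, b2$ligand$values)
  expect_identical(b1$truth, b2$truth)

  expect_equal(dim(b1$train_features), c(100L, 17L))  # id + 16 descriptors
  expect_equal(dim(b1$test_features), c(10L, 17L))
  expect_equal(dim(b1$protein), c(10L, 100L))
  expect_equal(dim(b1$ligand), c(10L, 100L))
  expect_equal(dim(b1$pocket), c(10L, 100L))
  expect_length(intersect(b1$train_features$id, b1$test_features$id), 0)

  # all three channels satisfy their range contracts by construction
  expect_true(all(b1$protein$values > 0 & b1$protein$values <= 1))
  expect_true(all(b1$ligand$values >= 0 & b1$ligand$values <= 1))
  expect_true(all(b1$pocket$values >= 0))
  expect_true(all(b1$train_affinities$affinity >= 2 &
                    b1$train_affinities$affinity <= 12))
})

test_that("near-duplicate mass lands in the (0.99, 1] band as configured", {
  cfg <- synth_config(n_train = 2000, n_test = 100, n_clusters = 40,
                      near_dup_fraction = 0.25, seed = 62)
  b <- generate_benchmark(cfg)
  h <- skew_histogram(b$protein, default_schedule("protein_structure"))
  top <- h$count[h$lower == 0.99]
  expect_gte(top / 2000, 0.22)   # within +-3% of the configured 25%
  expect_lte(top / 2000, 0.28)
})

test_that("planted linear weights are recovered when the truth is linear", {
  cfg <- synth_config(n_train = 400, n_test = 40, n_clusters = 8,
                      noise_sd = 1e-6, nonlinear_strength = 0, seed = 63)
  b <- generate_benchmark(cfg)
  truth <- b$truth
  m <- fit_mlr(b$train_features, b$train_affinities)
  est <- m$coefficients[names(truth$linear_weights)]
  expect_equal(unname(est), unname(truth$linear_weights), tolerance = 1e-3)

  # cluster labels partition all ids
  expect_setequal(names(truth$clusters_train), b$train_features$id)
  expect_setequal(names(truth$clusters_test), b$test_features$id)

  # planted_truth(cfg) reproduces the truth embedded in the benchmark
  expect_identical(planted_truth(cfg), truth)

  # with exactly zero noise the linear model is perfect on the test side
  cfg0 <- synth_config(n_train = 200, n_test = 30, n_clusters = 6,
                       noise_sd = 0, nonlinear_strength = 0, seed = 64)
  b0 <- generate_benchmark(cfg0)
  m0 <- fit_mlr(b0$train_features, b0$train_affinities)
  expect_equal(scoring_power(predict(m0, b0$test_features),
                             b0$test_affinities)$rp, 1, tolerance = 1e-9)
})

test_that("similar training complexes are more informative than random ones", {
  # restricting training to the test complex's own cluster must beat an
  # equal-size random training subset (5-seed median of mean |error|)
  gaps <- vapply(1:5, function(s) {
    b <- tiny_bench(seed = 70 + s, n_train = 240, n_test = 30, n_clusters = 6,
                    near_dup_fraction = 0)
    cl_tr <- b$truth$clusters_train
    cl_te <- b$truth$clusters_test
    # the best-covered cluster among those the test set actually samples
    k <- as.integer(names(which.max(table(cl_tr[cl_tr %in% cl_te]))))
    own <- names(cl_tr)[cl_tr == k]
    test_ids <- names(cl_te)[cl_te == k]
    if (length(test_ids) < 2) return(NA_real_)
    set.seed(s)
    rand <- sample(names(cl_tr), length(own))
    fit_on <- function(ids) {
      fit_sf(sf_spec("RF::XVC", seed = s, hyperparams = list(ntree = 120)),
             b$train_features[b$train_features$id %in% ids, ],
             b$train_affinities)
    }
    err <- function(fit) {
      pr <- predict(fit, b$test_features[b$test_features$id %in% test_ids, ])
      obs <- b$test_affinities
      mean(abs(pr$.pred - obs$affinity[match(pr$id, obs$id)]))
    }
    err(fit_on(rand)) - err(fit_on(own))
  }, numeric(1))
  expect_gt(stats::median(gaps, na.rm = TRUE), 0)
})

test_that("nonlinearity separates tree ensembles from the linear fit", {
  # Nonlinear truth, realistic world (near-duplicates present): the hybrid
  # forest beats the best classical linear scoring function on held-out rp
  # (5-seed median).
  deltas <- vapply(1:5, function(s) {
    b <- tiny_bench(seed = 80 + s, n_train = 800, n_test = 150,
                    n_clusters = 12, nonlinear_strength = 0.7)
    rf <- fit_sf(sf_spec("RF::XVC", seed = s, hyperparams = list(ntree = 250)),
                 b$train_features, b$train_affinities)
    ml <- fit_mlr_xscore(b$train_features, b$train_affinities)
    scoring_power(predict(rf, b$test_features), b$test_affinities)$rp -
      scoring_power(predict(ml, b$test_features), b$test_affinities)$rp
  }, numeric(1))
  expect_gt(stats::median(deltas), 0)

  # Purely linear truth, algorithm-isolating world: same descriptor subset
  # for both models and no near-duplicate twins (twins smuggle in the
  # complementary descriptors' signal and would blur the comparison). The
  # two calibrations tie within 0.02 (5-seed median).
  ties <- vapply(1:5, function(s) {
    b <- tiny_bench(seed = 90 + s, n_train = 800, n_test = 150,
                    n_clusters = 12, nonlinear_strength = 0,
                    near_dup_fraction = 0)
    rf <- fit_sf(sf_spec("RF::Xscore", seed = s, hyperparams = list(ntree = 250)),
                 b$train_features, b$train_affinities)
    ml <- fit_mlr_xscore(b$train_features, b$train_affinities)
    scoring_power(predict(ml, b$test_features), b$test_affinities)$rp -
      scoring_power(predict(rf, b$test_features), b$test_affinities)$rp
  }, numeric(1))
  expect_lt(abs(stats::median(ties)), 0.02 + 1e-9)
})

test_that("write_benchmark emits every dialect readably", {
  b <- tiny_bench(seed = 65, n_train = 25, n_test = 4)
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  feats <- feature_registry()$XVC16
  tr <- read_feature_table(file.path(dir, "train_features.tsv"), feats)
  expect_equal(dim(tr), c(25L, 17L))
  idx <- read_pdbbind_index(file.path(dir, "train_index.txt"))
  expect_equal(idx$affinity, b$train_affinities$affinity, tolerance = 1e-4)
  pm <- read_similarity_matrix(file.path(dir, "protein.tsv"), "similarity",
                               "protein_structure")
  expect_equal(pm$values, b$protein$values, tolerance = 1e-9)
  dm <- read_similarity_matrix(file.path(dir, "pocket.tsv"), "dissimilarity")
  expect_equal(dm$values, b$pocket$values, tolerance = 1e-9)
})
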