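# Classical MLR scoring functions: exact-line cases, normal-equations
# oracle, the X-Score consensus and the Vina rotor normalization.

test_that("fit_mlr recovers an exact line and validates its inputs", {
  X <- tibble::tibble(id = c("a", "b", "c"), f = c(0, 1, 2))
  y <- tibble::tibble(id = c("a", "b", "c"), affinity = c(1, 3, 5))
  m <- fit_mlr(X, y)
  expect_equal(unname(m$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(predict(m, X)$.pred, c(1, 3, 5), tolerance = 1e-12)

  # constant response: zero slope, intercept = the constant
  X2 <- tibble::tibble(id = letters[1:5], f = rnorm(5))
  y2 <- tibble::tibble(id = letters[1:5], affinity = rep(4.2, 5))
  m2 <- fit_mlr(X2, y2)
  expect_equal(unname(m2$coefficients), c(4.2, 0), tolerance = 1e-10)

  # too few rows, and rank deficiency names the collinear column
  expect_error(fit_mlr(X[1, , drop = FALSE], y), "at least")
  X3 <- tibble::tibble(id = letters[1:6], f1 = rnorm(6), f2 = rnorm(6))
  X3$f3 <- 2 * X3$f1
  y3 <- tibble::tibble(id = letters[1:6], affinity = rnorm(6))
  expect_error(fit_mlr(X3, y3), "collinear column\\(s\\): f3")
})

test_that("OLS equals the normal-equations oracle on random instances", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    p <- sample(2:6, 1)
    toy <- linear_toy(n = n, p = p, seed = 3000 + i, sd = runif(1, 0, 2))
    m <- fit_mlr(toy$X, toy$y)
    D <- cbind(1, as.matrix(toy$X[, -1]))
    beta <- solve(t(D) %*% D, t(D) %*% toy$y$affinity)  # independent oracle
    expect_equal(unname(m$coefficients), as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("X-Score consensus averages three independently fitted constituents", {
  toy <- xvc_toy(n = 100, seed = 32)
  m <- fit_mlr_xscore(toy$X, toy$y)
  pred <- predict(m, toy$X)$.pred

  # oracle: three separate lm() fits, averaged
  df <- dplyr::left_join(toy$X, toy$y, by = "id")
  fits <- lapply(c("HP", "HM", "HS"), function(h) {
    stats::lm(stats::reformulate(c("VDW", "HB", "RT", h), "affinity"), df)
  })
  oracle <- Reduce(`+`, lapply(fits, stats::predict)) / 3
  expect_equal(pred, unname(oracle), tolerance = 1e-10)

  # constituent predictions average to the consensus by definition
  cons <- sapply(names(m$constituents), function(k) {
    f <- m$constituent_features[[k]]
    co <- m$constituents[[k]]
    co[1] + as.matrix(toy$X[, f]) %*% co[-1]
  })
  expect_equal(rowMeans(cons), pred, ignore_attr = TRUE, tolerance = 1e-12)

  # identical hydrophobic columns collapse the consensus to one 4-term MLR
  toy$X$HM <- toy$X$HP
  toy$X$HS <- toy$X$HP
  m_eq <- fit_mlr_xscore(toy$X, toy$y)
  single <- fit_mlr(toy$X, toy$y, features = c("VDW", "HB", "RT", "HP"))
  expect_equal(predict(m_eq, toy$X)$.pred, predict(single, toy$X)$.pred,
               tolerance = 1e-8)
})

test_that("Vina rotor normalization transforms, fits and predicts correctly", {
  toy <- xvc_toy(n = 80, seed = 33)
  w <- 0.05846
  m <- fit_mlr_vina(toy$X, toy$y, nrot_weight = w)

  # oracle: divide the five terms by (1 + w*Nrot), then plain lm()
  terms <- setdiff(feature_registry()$VINA6, "Nrot")
  df <- dplyr::left_join(toy$X, toy$y, by = "id")
  denom <- 1 + w * df$Nrot
  for (tm in terms) df[[tm]] <- df[[tm]] / denom
  fit <- stats::lm(stats::reformulate(terms, "affinity"), df)
  expect_equal(predict(m, toy$X)$.pred, unname(stats::predict(fit)),
               tolerance = 1e-10)

  # Nrot == 0 for all rows: identical to plain MLR on the five terms
  toy0 <- xvc_toy(n = 60, seed = 34)
  toy0$X$Nrot <- 0
  m0 <- fit_mlr_vina(toy0$X, toy0$y)
  plain <- fit_mlr(toy0$X, toy0$y, features = terms)
  expect_equal(m0$coefficients, plain$coefficients, tolerance = 1e-10)
  expect_equal(predict(m0, toy0$X)$.pred, predict(plain, toy0$X)$.pred,
               tolerance = 1e-10)

  # raising Nrot shrinks the normalized term sum when it is positive
  row <- toy$X[5, ]
  base <- predict(m, row)$.pred - m$coefficients[1]
  if (base > 0) {
    row_big <- row
    row_big$Nrot <- row$Nrot * 10 + 10
    shrunk <- predict(m, row_big)$.pred - m$coefficients[1]
    expect_lt(abs(shrunk), abs(base))
  }

  # negative rotor counts are rejected
  toyn <- xvc_toy(n = 30, seed = 35)
  toyn$X$Nrot[1] <- -1
  expect_error(fit_mlr_vina(toyn$X, toyn$y), "non-negative")
})

test_that("fit_sf dispatches every registered name and checks columns", {
  b <- tiny_bench(seed = 36, n_train = 80, n_test = 10)
  for (nm in sf_names()) {
    hp <- if (grepl("^RF", nm)) list(ntree = 30) else
      if (grepl("^XGB", nm)) list(nrounds = 30) else list()
    fit <- fit_sf(sf_spec(nm, seed = 2, hyperparams = hp),
                  b$train_features, b$train_affinities)
    pred <- predict(fit, b$test_features)
    expect_equal(nrow(pred), 10L)
    expect_true(all(is.finite(pred$.pred)))
    expect_equal(glance(fit)$sf_name, nm)
  }
  # a missing descriptor column is reported with the scoring-function name
  crippled <- b$test_features[, setdiff(names(b$test_features), "VDW")]
  fit <- fit_sf(sf_spec("MLR::Cyscore"), b$train_features, b$train_affinities)
  expect_silent(predict(fit, crippled))  # Cyscore does not use VDW
  fitx <- fit_sf(sf_spec("MLR::Xscore"), b$train_features, b$train_affinities)
  expect_error(predict(fitx, crippled), "VDW.*MLR::Xscore")
})

test_that("tidy and glance summarize fitted models", {
  toy <- xvc_toy(n = 60, seed = 37)
  m <- fit_mlr(toy$X, toy$y, features = feature_registry()$CYSCORE4)
  td <- tidy(m)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 5L)
  cons <- fit_mlr_xscore(toy$X, toy$y)
  expect_setequal(unique(tidy(cons)$constituent), c("HP", "HM", "HS"))
  gl <- glance(cons)
  expect_equal(gl$n_train, 60L)
  expect_equal(gl$n_features, 6L)
})

test_that("models round-trip through JSON serialization", {
  b <- tiny_bench(seed = 38, n_train = 60, n_test = 8)
  path <- withr::local_tempfile(fileext = ".json")
  for (nm in c("MLR::Xscore", "MLR::Vina", "RF::Cyscore", "XGB::XVC")) {
    hp <- if (grepl("^(RF|XGB)", nm)) list(ntree = 20, nrounds = 20) else list()
    m <- fit_sf(sf_spec(nm, seed = 3, hyperparams = hp),
                b$train_features, b$train_affinities)
    write_sf_model(m, path)
    m2 <- read_sf_model(path)
    expect_equal(predict(m2, b$test_features)$.pred,
                 predict(m, b$test_features)$.pred, tolerance = 1e-12)
  }
})
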