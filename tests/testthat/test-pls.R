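make_xy <- function(n = 30, p = 5, seed = 1, noise = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(X %*% rnorm(p) + rnorm(n, 0, noise))
  list(X = X, y = y)
}

test_that("full-component PLS and PCR reproduce least squares", {
  d <- make_xy()
  ols <- lm.fit(cbind(1, d$X), d$y)$fitted.values
  expect_lt(max(abs(fit_pls(d$X, d$y, 5)$fitted - ols)), 1e-6)
  expect_lt(max(abs(fit_pcr(d$X, d$y, 5)$fitted - ols)), 1e-6)
})

test_that("exact low-rank relationships are recovered exactly", {
  set.seed(2)
  T0 <- matrix(rnorm(40 * 3), 40, 3)
  P0 <- qr.Q(qr(matrix(rnorm(8 * 3), 8, 3)))
  X <- T0 %*% t(P0)
  y <- as.numeric(T0 %*% c(1, -2, 0.5))
  fit <- fit_pls(X, y, 3)
  expect_gt(r_squared(fit$fitted, y), 1 - 1e-8)
})

test_that("the first NIPALS weight is proportional to X'y", {
  d <- make_xy(seed = 3)
  fit <- fit_pls(d$X, d$y, 3)
  w <- crossprod(sweep(d$X, 2, colMeans(d$X)), d$y - mean(d$y))
  w <- w / sqrt(sum(w^2))
  expect_lt(abs(abs(sum(w * fit$weights[, 1])) - 1), 1e-10)
})

test_that("NIPALS scores are mutually orthogonal", {
  d <- make_xy(n = 40, p = 20, seed = 4)
  fit <- fit_pls(d$X, d$y, 6)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
})

test_that("calibration R2 is non-decreasing in the component count", {
  d <- make_xy(n = 35, p = 10, seed = 5)
  fit <- fit_pls(d$X, d$y, 8)
  r2 <- vapply(1:8, function(k)
    r_squared(predict(fit, d$X, ncomp = k), d$y), numeric(1))
  expect_true(all(diff(r2) > -1e-10))
})

test_that("prediction honours its contracts", {
  d <- make_xy(seed = 6)
  fit <- fit_pls(d$X, d$y, 3)
  # calibration-set predictions reproduce stored fitted values
  expect_identical(predict(fit, d$X), fit$fitted)
  # duplicated rows give duplicated predictions
  X2 <- d$X[c(1, 1, 2), ]
  p2 <- predict(fit, X2)
  expect_identical(p2[1], p2[2])
  # the model-mean spectrum predicts the calibration mean response
  expect_lt(abs(predict(fit, matrix(fit$x_mean, 1)) - fit$y_mean), 1e-8)
  # shifting every spectrum shifts predictions by the projected shift
  shift <- fit$x_mean
  expect_equal(predict(fit, sweep(d$X, 2, shift, `+`)),
               predict(fit, d$X) + sum(shift * fit$regression_vector),
               tolerance = 1e-8)
  expect_error(predict(fit, d$X[, 1:3]), "grid mismatch.*5.*3")
})

test_that("degenerate calibrations fail with clear messages", {
  d <- make_xy()
  expect_error(fit_pls(d$X, rep(1, 30), 2), "constant")
  expect_error(fit_pcr(d$X, rep(1, 30), 2), "constant")
  expect_error(fit_pls(d$X, d$y, 29), "at least")
  # y orthogonal to a rank-deficient X exhausts the weight vector
  X1 <- cbind(rep(c(1, -1), 5))
  X1 <- X1 %*% t(c(1, 1, 1))
  y_perp <- rep(c(1, 1, -1, -1, 0), 2)
  expect_error(fit_pls(X1, y_perp + 1e-30, 2), "component")
})

test_that("cross-validation matches a hand-rolled leave-one-out loop", {
  d <- make_xy(n = 14, p = 4, seed = 7)
  sel <- select_components(d$X, d$y, max_k = 2, folds = 14, seed = 1)
  loo <- matrix(NA_real_, 14, 2)
  for (i in 1:14) {
    fit <- fit_pls(d$X[-i, ], d$y[-i], 2)
    for (k in 1:2) loo[i, k] <- predict(fit, d$X[i, , drop = FALSE], ncomp = k)
  }
  secv_oracle <- sqrt(colMeans((loo - d$y)^2))
  expect_equal(unname(sel$secv), secv_oracle, tolerance = 1e-12)
})

test_that("cross-validation recovers a 3-factor latent dimension", {
  hits <- 0
  for (s in 1:5) {
    set.seed(100 + s)
    T0 <- matrix(rnorm(60 * 3), 60, 3) %*% diag(c(5, 3, 2))
    P0 <- qr.Q(qr(matrix(rnorm(50 * 3), 50, 3)))
    X <- T0 %*% t(P0) + matrix(rnorm(60 * 50, 0, 0.02), 60, 50)
    y <- as.numeric(T0 %*% c(0.5, -1, 0.8) + rnorm(60, 0, 0.3))
    sel <- select_components(X, y, max_k = 8, folds = 10, seed = s)
    if (sel$chosen_k == 3) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("pure-noise responses keep the chosen dimension small", {
  set.seed(11)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  sel <- select_components(X, y, max_k = 10, folds = 10, seed = 2)
  expect_lte(sel$chosen_k, 3)
  # SECV should trend upward as useless components are added
  expect_gt(mean(sel$secv[7:10]), min(sel$secv))
})

test_that("infeasible component requests are rejected", {
  d <- make_xy(n = 12, p = 30, seed = 8)
  expect_error(select_components(d$X, d$y, max_k = 11, folds = 12, seed = 1),
               "infeasible")
  expect_error(select_components(d$X, d$y, max_k = 2, folds = 1, seed = 1),
               "folds")
})

test_that("PCR with one dominant component carrying the signal rivals PLS", {
  set.seed(12)
  v <- qr.Q(qr(matrix(rnorm(20), 20, 1)))
  t1 <- rnorm(50, sd = 6)
  X <- t1 %*% t(v) + matrix(rnorm(50 * 20, 0, 0.1), 50, 20)
  y <- t1 + rnorm(50, 0.1)
  r2_pcr <- r_squared(fit_pcr(X, y, 1)$fitted, y)
  r2_pls <- r_squared(fit_pls(X, y, 1)$fitted, y)
  expect_gte(r2_pcr, r2_pls - 0.05)
})
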