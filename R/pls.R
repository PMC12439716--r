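#' NIPALS PLS1 calibration
#'
#' Fits a single-response partial least squares model by the NIPALS
#' deflation scheme. X and y are centered (never autoscaled: standard for
#' absorbance data); for each component
#' \deqn{w = X^T y / \|X^T y\|,\; t = X w,\; p = X^T t/(t^T t),\; q = y^T t/(t^T t)}
#' then X and y are deflated by `t p^T` and `t q`. For a single response
#' each step is a closed-form computation, so no inner iteration is
#' needed. The regression vector is `b = W (P^T W)^{-1} q`; regression
#' vectors for every sub-model 1..k are stored so nested models come free.
#'
#' @param X A [spectra_set()] or numeric matrix (rows = samples).
#' @param y Numeric response, one value per sample.
#' @param ncomp Number of latent variables (>= 1).
#' @return An object of class `"pls_model"` with elements `x_mean`,
#'   `y_mean`, `weights`, `x_loadings`, `y_loadings`, `scores`,
#'   `coefficients` (p x ncomp, one column per sub-model),
#'   `regression_vector` (the full-`ncomp` column), `fitted`, `ncomp`,
#'   `method`.
#' @export
fit_pls <- function(X, y, ncomp) {
  M <- as_matrix_x(X)
  y <- as.numeric(y)
  n <- nrow(M); p <- ncol(M)
  if (length(y) != n) stop("y must have one value per spectrum")
  if (!all(is.finite(y))) stop("y must be finite")
  if (stats::sd(y) == 0) stop("y is constant; nothing to calibrate")
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (n < ncomp + 2)
    stop(sprintf("need at least ncomp + 2 = %d samples, got %d", ncomp + 2, n))

  x_mean <- colMeans(M)
  y_mean <- mean(y)
  Xc <- sweep(M, 2, x_mean)
  X0 <- Xc
  yc <- y - y_mean

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(X0^2))))
      stop(sprintf("zero-norm weight vector at component %d (y orthogonal to X)", a))
    w <- w / nw
    t <- as.numeric(Xc %*% w)
    tt <- sum(t^2)
    pv <- as.numeric(crossprod(Xc, t)) / tt
    q <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, pv)
    yc <- yc - t * q
    W[, a] <- w; P[, a] <- pv; Q[a] <- q; Tm[, a] <- t
  }
  # nested regression vectors: b_k = W_k (P_k^T W_k)^{-1} q_k
  B <- matrix(0, p, ncomp)
  for (k in seq_len(ncomp)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    B[, k] <- Wk %*% solve(crossprod(Pk, Wk), Q[seq_len(k)])
  }
  b <- B[, ncomp]
  fitted <- as.numeric(X0 %*% b) + y_mean
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = W,
                 x_loadings = P, y_loadings = Q, scores = Tm,
                 coefficients = B, regression_vector = b,
                 fitted = fitted, ncomp = ncomp, n = n,
                 method = "pls"),
            class = "pls_model")
}

#' Principal component regression
#'
#' Same contract and return class as [fit_pls()], but the latent scores
#' are the leading principal components of centered X (via singular value
#' decomposition) instead of covariance-maximizing NIPALS scores.
#'
#' @inheritParams fit_pls
#' @return A `"pls_model"` with `method = "pcr"`.
#' @export
fit_pcr <- function(X, y, ncomp) {
  M <- as_matrix_x(X)
  y <- as.numeric(y)
  n <- nrow(M)
  if (length(y) != n) stop("y must have one value per spectrum")
  if (!all(is.finite(y))) stop("y must be finite")
  if (stats::sd(y) == 0) stop("y is constant; nothing to calibrate")
  if (ncomp < 1) stop("ncomp must be >= 1")
  if (n < ncomp + 2)
    stop(sprintf("need at least ncomp + 2 = %d samples, got %d", ncomp + 2, n))
  x_mean <- colMeans(M)
  y_mean <- mean(y)
  Xc <- sweep(M, 2, x_mean)
  yc <- y - y_mean
  sv <- svd(Xc, nu = ncomp, nv = ncomp)
  if (sv$d[ncomp] < 1e-10 * sv$d[1])
    stop(sprintf("X has numerical rank below %d components", ncomp))
  Tm <- sv$u %*% diag(sv$d[seq_len(ncomp)], ncomp)
  V <- sv$v
  # scores are orthogonal, so each q is a simple projection
  q <- as.numeric(crossprod(Tm, yc)) / colSums(Tm^2)
  B <- vapply(seq_len(ncomp), function(k)
    as.numeric(V[, seq_len(k), drop = FALSE] %*% q[seq_len(k)]),
    numeric(ncol(M)))
  B <- matrix(B, ncol = ncomp)
  b <- B[, ncomp]
  fitted <- as.numeric(Xc %*% b) + y_mean
  structure(list(x_mean = x_mean, y_mean = y_mean, weights = V,
                 x_loadings = V, y_loadings = q, scores = Tm,
                 coefficients = B, regression_vector = b,
                 fitted = fitted, ncomp = ncomp, n = n,
                 method = "pcr"),
            class = "pls_model")
}

#' Predict trait values from a calibration model
#'
#' @param object A `"pls_model"`.
#' @param newdata A [spectra_set()] or matrix on the model's training grid
#'   (same number of points, same preprocessing).
#' @param ncomp Number of components to use (defaults to the fitted
#'   maximum).
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  M <- as_matrix_x(newdata)
  if (ncol(M) != length(object$x_mean))
    stop(sprintf("grid mismatch: model expects %d points, received %d",
                 length(object$x_mean), ncol(M)))
  if (ncomp < 1 || ncomp > object$ncomp)
    stop("ncomp outside the fitted range")
  b <- object$coefficients[, ncomp]
  as.numeric(sweep(M, 2, object$x_mean) %*% b) + object$y_mean
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> method=%s, %d components, %d calibration samples\n",
              x$method, x$ncomp, x$n))
  invisible(x)
}

#' Cross-validated choice of the number of latent variables
#'
#' Seeded k-fold cross-validation. For each candidate k, the standard
#' error of cross-validation SECV(k) is the root mean squared
#' cross-validated residual; the chosen k minimizes SECV, with ties broken
#' toward the smaller (more parsimonious) model.
#'
#' @param X A [spectra_set()] or matrix.
#' @param y Numeric response.
#' @param max_k Largest component count to try.
#' @param folds Number of folds (2..n); `NULL` (the default) uses
#'   leave-one-out, the convention in NIR calibration work.
#' @param seed Integer seed for the fold assignment.
#' @param method `"pls"` or `"pcr"`.
#' @return A list of class `"component_selection"`: `secv` (named vector
#'   over k), `chosen_k`, `folds`, `seed`, `method`.
#' @export
select_components <- function(X, y, max_k = 10, folds = NULL, seed = 1,
                              method = c("pls", "pcr")) {
  method <- match.arg(method)
  M <- as_matrix_x(X)
  y <- as.numeric(y)
  n <- nrow(M)
  if (is.null(folds)) folds <- n
  if (folds < 2 || folds > n) stop("folds must be between 2 and n")
  min_train <- n - ceiling(n / folds)
  if (max_k >= min_train || max_k > ncol(M))
    stop(sprintf("max_k = %d infeasible for n = %d, folds = %d, p = %d",
                 max_k, n, folds, ncol(M)))
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  fitter <- if (method == "pls") fit_pls else fit_pcr
  cv_pred <- matrix(NA_real_, n, max_k)
  for (f in seq_len(folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    fit <- fitter(M[train, , drop = FALSE], y[train], ncomp = max_k)
    for (k in seq_len(max_k))
      cv_pred[test, k] <- predict(fit, M[test, , drop = FALSE], ncomp = k)
  }
  secv <- sqrt(colMeans((cv_pred - y)^2))
  names(secv) <- seq_len(max_k)
  structure(list(secv = secv, chosen_k = unname(which.min(secv)),
                 folds = folds, seed = seed, method = method),
            class = "component_selection")
}

#' @export
print.component_selection <- function(x, ...) {
  cat(sprintf("<component_selection> chosen k = %d (of %d), %d-fold CV, SECV = %.4g\n",
              x$chosen_k, length(x$secv), x$folds, x$secv[x$chosen_k]))
  invisible(x)
}
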