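#' Principal component analysis
#'
#' PCA of a spectra set or trait matrix by singular value decomposition of
#' the (optionally centered and standardized) data — equivalent to an
#' eigen-decomposition of its covariance matrix. The sign of each
#' component is fixed so that its largest-magnitude loading element is
#' positive, making score plots reproducible across runs.
#'
#' @param X A [spectra_set()] or numeric matrix (rows = samples).
#' @param k Number of components (<= min(n - 1, n variables) when
#'   centered).
#' @param center,scale Center and/or standardize columns first.
#' @return A list of class `"pca_result"`: `scores` (n x k), `loadings`
#'   (p x k, orthonormal columns), `explained_variance_pct`,
#'   `cumulative_pct`, `center`, `scale`, `sdev` (all singular-value SDs,
#'   for variance accounting).
#' @export
pca <- function(X, k, center = TRUE, scale = FALSE) {
  M <- as_matrix_x(X)
  n <- nrow(M); p <- ncol(M)
  if (n < 2) stop("PCA needs at least 2 samples")
  kmax <- min(if (center) n - 1 else n, p)
  if (k < 1 || k > kmax)
    stop(sprintf("k must be in 1..%d for these data", kmax))
  ctr <- if (center) colMeans(M) else rep(0, p)
  M <- sweep(M, 2, ctr)
  scl <- rep(1, p)
  if (scale) {
    scl <- apply(M, 2, stats::sd)
    if (any(scl == 0)) stop("cannot standardize a constant column")
    M <- sweep(M, 2, scl, `/`)
  }
  sv <- svd(M)
  denom <- if (center) n - 1 else n
  var_all <- sv$d^2 / denom
  total <- sum(var_all)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  scores <- M %*% loadings
  # deterministic sign: largest |loading| element positive
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- 100 * var_all[seq_len(k)] / total
  structure(list(scores = scores, loadings = loadings,
                 explained_variance_pct = expl,
                 cumulative_pct = cumsum(expl),
                 center = ctr, scale = scl, sdev = sqrt(var_all)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat(sprintf("<pca_result> %d components; explained %% = %s (cum %.1f)\n",
              k, paste(sprintf("%.1f", x$explained_variance_pct),
                       collapse = ", "),
              x$cumulative_pct[k]))
  invisible(x)
}

#' Pearson correlation matrix of the trait table
#'
#' @param reference A reference table (as from [generate_reference()]):
#'   `sample_id` plus numeric trait columns.
#' @return A symmetric correlation matrix with unit diagonal. A constant
#'   trait yields `NA` in its row/column, with a warning.
#' @export
pearson_matrix <- function(reference) {
  M <- as.matrix(reference[reference_traits(reference)])
  if (nrow(M) < 3) stop("need at least 3 samples for a correlation matrix")
  const <- apply(M, 2, stats::sd) == 0
  R <- suppressWarnings(stats::cor(M))
  if (any(const)) {
    warning(sprintf("constant trait(s) %s: correlations undefined",
                    paste(colnames(M)[const], collapse = ", ")))
    R[const, ] <- NA_real_
    R[, const] <- NA_real_
  }
  diag(R) <- ifelse(const, NA_real_, 1)
  R
}

#' Tabulate PC1/PC2 loadings per variable
#'
#' @param pca_result A [pca()] result with at least 2 components.
#' @param labels Variable labels, one per loading row.
#' @return A data.frame with columns `label`, `PC1`, `PC2`.
#' @export
loading_table <- function(pca_result, labels) {
  L <- pca_result$loadings
  if (ncol(L) < 2) stop("need at least 2 components for a loading table")
  if (length(labels) != nrow(L))
    stop("one label per loading row required")
  data.frame(label = as.character(labels), PC1 = L[, 1], PC2 = L[, 2],
             stringsAsFactors = FALSE)
}
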