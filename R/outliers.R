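#' Chemical outlier flags from calibration residuals
#'
#' Flags sample i when `|r_i| > sd_multiple * SD(r)` (SD with n-1
#' denominator) — the classic "outside +/-3 SD of calibration y-residuals"
#' rule. Calibration residuals are centered at zero by construction, so
#' the raw residual is measured directly against the residual spread.
#'
#' @param residuals Numeric residuals (>= 3 values).
#' @param sd_multiple Threshold in residual SDs (default 3).
#' @return Logical flags, one per residual. Zero spread yields no flags
#'   (with a warning).
#' @export
chemical_outliers <- function(residuals, sd_multiple = 3.0) {
  if (length(residuals) < 3) stop("need at least 3 residuals")
  s <- stats::sd(residuals)
  if (!is.finite(s) || s == 0) {
    warning("zero residual spread: no chemical outliers flagged")
    return(rep(FALSE, length(residuals)))
  }
  abs(residuals) > sd_multiple * s
}

#' Mahalanobis H distance of latent scores
#'
#' Squared Mahalanobis distance of each sample's score vector from the
#' score centroid, using the n-1-denominator covariance: the H statistic
#' used to reject atypical spectra in multivariate calibration. Satisfies
#' the identity `sum(H) = k * (n - 1)` for k score dimensions.
#'
#' @param scores Numeric matrix, n samples x k score dimensions.
#' @return Numeric H per sample.
#' @export
mahalanobis_h <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n <= k + 1) stop("need n > k + 1 samples for a stable covariance")
  S <- stats::cov(scores)
  ok <- tryCatch({ solve(S); TRUE }, error = function(e) FALSE)
  if (!ok || !all(is.finite(S)))
    stop("singular score covariance: use fewer components")
  stats::mahalanobis(scores, colMeans(scores), S)
}

#' Two-stage outlier screen
#'
#' Implements the screening sequence used before final calibration:
#' (1) a spectral screen — PCA scores of the (preprocessed) spectra,
#' Mahalanobis H per sample, flag at `H >= h_max` (retention is
#' `H < h_max`); then (2) a chemical screen — a preliminary PLS fit on the
#' spectrally retained samples, with residuals beyond
#' `+/- resid_sd` SD flagged. Residual mean/SD come from the retained
#' set; every sample (including spectrally flagged ones) is reported.
#'
#' @param spectra A [spectra_set()], normally already preprocessed.
#' @param y Trait reference values, one per sample.
#' @param n_components Score-space dimension for both the PCA screen and
#'   the preliminary PLS fit.
#' @param h_max H threshold (default 6; flag at `H >= h_max`).
#' @param resid_sd Residual threshold in SD multiples (default 3).
#' @return A data.frame (one row per sample): `sample_id`, `H`,
#'   `y_residual`, `residual_sd_multiple`, `flagged`, `reason`
#'   (`"spectral"`, `"chemical"`, `"both"` or `"none"`), plus the
#'   thresholds as attributes `h_max` and `resid_sd`.
#' @export
screen_outliers <- function(spectra, y, n_components = 5, h_max = 6,
                            resid_sd = 3) {
  M <- as_matrix_x(spectra)
  n <- nrow(M)
  y <- as.numeric(y)
  if (length(y) != n) stop("y must have one value per spectrum")

  pc <- pca(M, k = n_components)
  H <- mahalanobis_h(pc$scores)
  spectral <- is.finite(h_max) & (H >= h_max)

  keep <- which(!spectral)
  if (length(keep) < n_components + 2)
    stop("too few samples retained by the spectral screen for a preliminary fit")
  fit <- fit_pls(M[keep, , drop = FALSE], y[keep], ncomp = n_components)
  resid_all <- y - predict(fit, M)
  s <- stats::sd(resid_all[keep])
  mult <- if (is.finite(s) && s > 0) abs(resid_all) / s
          else rep(0, n)
  chemical <- is.finite(resid_sd) & (mult > resid_sd)
  if (!is.finite(s) || s == 0) chemical <- rep(FALSE, n)

  reason <- rep("none", n)
  reason[spectral & !chemical] <- "spectral"
  reason[!spectral & chemical] <- "chemical"
  reason[spectral & chemical] <- "both"
  out <- data.frame(
    sample_id = if (inherits(spectra, "spectra_set")) spectra$sample_ids
                else sprintf("S%03d", seq_len(n)),
    H = as.numeric(H),
    y_residual = as.numeric(resid_all),
    residual_sd_multiple = as.numeric(mult),
    flagged = spectral | chemical,
    reason = reason,
    stringsAsFactors = FALSE
  )
  attr(out, "h_max") <- h_max
  attr(out, "resid_sd") <- resid_sd
  out
}
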