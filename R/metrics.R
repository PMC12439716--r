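#' Calibration/validation statistics
#'
#' The standard chemometric model-evaluation suite. With e = pred - ref:
#' \itemize{
#'   \item `r_squared`: \eqn{1 - SS_{res}/SS_{tot}} about the reference
#'     mean.
#'   \item `rmsep`: \eqn{\sqrt{\mathrm{mean}(e^2)}}.
#'   \item `bias`: \eqn{\mathrm{mean}(pred) - \mathrm{mean}(ref)}.
#'   \item `see`: the bias-corrected SD of the errors,
#'     \eqn{\sqrt{\frac{n}{n-1}(RMSEP^2 - Bias^2)}}; identical to the
#'     n-1-denominator SD of e, and linked to the others by
#'     \eqn{RMSEP^2 = Bias^2 + \frac{n-1}{n} SEE^2}.
#'   \item `mae`: mean absolute error.
#'   \item `rpd`: ratio of reference SD to the standard error of
#'     prediction; RPD >= 2 conventionally marks a model usable for
#'     screening, RPD >= 3 for quantification.
#' }
#'
#' @param pred Predicted values.
#' @param ref Reference values (same length).
#' @name calibration_metrics
NULL

check_pairs <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("pred and ref lengths differ")
  if (length(pred) < 2) stop("need at least 2 pairs")
}

#' @rdname calibration_metrics
#' @export
r_squared <- function(pred, ref) {
  check_pairs(pred, ref)
  sst <- sum((ref - mean(ref))^2)
  if (sst == 0) stop("reference values are constant; R2 undefined")
  1 - sum((ref - pred)^2) / sst
}

#' @rdname calibration_metrics
#' @export
rmsep <- function(pred, ref) {
  check_pairs(pred, ref)
  sqrt(mean((pred - ref)^2))
}

#' @rdname calibration_metrics
#' @export
bias <- function(pred, ref) {
  check_pairs(pred, ref)
  mean(pred) - mean(ref)
}

#' @rdname calibration_metrics
#' @export
see <- function(pred, ref) {
  check_pairs(pred, ref)
  n <- length(pred)
  r2 <- rmsep(pred, ref)^2
  b2 <- bias(pred, ref)^2
  gap <- r2 - b2
  if (gap < 0) {
    if (gap < -1e-12 * max(r2, 1)) warning("RMSEP^2 < Bias^2; clamping SEE to 0")
    gap <- 0
  }
  sqrt(n / (n - 1) * gap)
}

#' @rdname calibration_metrics
#' @export
mae <- function(pred, ref) {
  check_pairs(pred, ref)
  mean(abs(pred - ref))
}

#' @param sd_ref SD of the reference values of the evaluation subset.
#' @param sep Standard error of prediction (a [see()] on that subset).
#' @rdname calibration_metrics
#' @export
rpd <- function(sd_ref, sep) {
  if (sep <= 0) stop("RPD undefined for SEP <= 0")
  sd_ref / sep
}

#' Build a full calibration report for one trait
#'
#' Evaluates a fitted model on disjoint calibration and validation sets
#' and assembles every statistic the package reports: R2, RMSEC/RMSEP,
#' MAE, Bias, SEC (SEE on calibration residuals), SEP (SEE on validation
#' residuals), SECV (from the component selection, if given), and RPD on
#' both sets (reference-subset SD over the corresponding standard error).
#'
#' @param model A `"pls_model"`.
#' @param cal_x,cal_y Calibration spectra ([spectra_set()] or matrix) and
#'   reference values.
#' @param val_x,val_y Validation spectra and reference values.
#' @param selection Optional `"component_selection"` supplying SECV.
#' @param trait_name Label stored in the report.
#' @return A list of class `"calibration_report"`.
#' @export
build_report <- function(model, cal_x, cal_y, val_x, val_y,
                         selection = NULL, trait_name = "trait") {
  cal_ids <- if (inherits(cal_x, "spectra_set")) cal_x$sample_ids else NULL
  val_ids <- if (inherits(val_x, "spectra_set")) val_x$sample_ids else NULL
  if (!is.null(cal_ids) && !is.null(val_ids) &&
      length(intersect(cal_ids, val_ids)))
    stop("calibration and validation sets share sample ids")
  pred_cal <- predict(model, cal_x)
  pred_val <- predict(model, val_x)
  n_cal <- length(cal_y); n_val <- length(val_y)
  sec <- see(pred_cal, cal_y)
  sep <- see(pred_val, val_y)
  secv <- if (!is.null(selection)) unname(selection$secv[selection$chosen_k])
          else NA_real_
  rep <- list(
    trait_name = trait_name,
    n_cal = n_cal, n_val = n_val,
    ncomp = model$ncomp,
    r2_cal = r_squared(pred_cal, cal_y),
    r2_val = r_squared(pred_val, val_y),
    rmsec = rmsep(pred_cal, cal_y),
    rmsep = rmsep(pred_val, val_y),
    mae_cal = mae(pred_cal, cal_y),
    mae_val = mae(pred_val, val_y),
    bias = bias(pred_val, val_y),
    sec = sec,
    secv = secv,
    sep = sep,
    see = sep,
    sd_ref_cal = stats::sd(cal_y),
    sd_ref = stats::sd(val_y),
    rpd_cal = stats::sd(cal_y) / sec,
    rpd_val = stats::sd(val_y) / sep,
    rpd_cv = if (is.na(secv)) NA_real_ else stats::sd(cal_y) / secv
  )
  structure(rep, class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report> %s: k=%d, n=%d/%d\n", x$trait_name,
              x$ncomp, x$n_cal, x$n_val))
  cat(sprintf("  cal: R2=%.3f RMSEC=%.3g MAE=%.3g RPD=%.2f\n",
              x$r2_cal, x$rmsec, x$mae_cal, x$rpd_cal))
  cat(sprintf("  val: R2=%.3f RMSEP=%.3g MAE=%.3g Bias=%.3g SEP=%.3g RPD=%.2f\n",
              x$r2_val, x$rmsep, x$mae_val, x$bias, x$sep, x$rpd_val))
  invisible(x)
}

#' Interpret a model's RPD for screening use
#'
#' Conventional reading of the ratio of performance to deviation: below 2
#' the model is unreliable; 2 to 3 is acceptable for screening;
#' above 3 supports quantitative use.
#'
#' @param rpd_value Numeric RPD.
#' @return One of `"unreliable"`, `"acceptable for screening"`,
#'   `"quantitative"`.
#' @export
rpd_grade <- function(rpd_value) {
  if (rpd_value >= 3) "quantitative"
  else if (rpd_value >= 2) "acceptable for screening"
  else "unreliable"
}
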