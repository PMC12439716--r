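#' Standard normal variate transform
#'
#' Centers and scales a single spectrum to zero mean and unit SD
#' (n-1 denominator), the classic per-spectrum correction for
#' multiplicative and additive scatter. Affine-invariant: `a*x + b` with
#' `a > 0` maps to the same output as `x`.
#'
#' @param x Numeric absorbance vector (>= 2 points).
#' @return The transformed vector.
#' @export
snv <- function(x) {
  if (length(x) < 2) stop("SNV needs at least 2 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("SNV undefined for a constant spectrum (zero spread)")
  (x - mean(x)) / s
}

#' Polynomial detrending
#'
#' Subtracts the least-squares polynomial (in wavenumber) of the given
#' order from a spectrum, removing smooth baseline curvature that survives
#' SNV.
#'
#' @param x Numeric absorbance vector.
#' @param grid The [wavenumber_grid()] the spectrum lives on.
#' @param polynomial_order Order of the baseline polynomial (>= 1).
#' @return The residual spectrum (same length as `x`).
#' @export
detrend <- function(x, grid, polynomial_order = 2) {
  if (polynomial_order < 1) stop("polynomial_order must be >= 1")
  if (length(x) <= polynomial_order + 1)
    stop("too few points for the requested polynomial order")
  nu <- as.numeric(unclass(grid))
  if (length(nu) != length(x)) stop("grid and spectrum lengths differ")
  # centered/scaled basis keeps the normal equations well conditioned
  z <- (nu - mean(nu)) / stats::sd(nu)
  B <- stats::poly(z, degree = polynomial_order, raw = FALSE)
  fit <- stats::lm.fit(cbind(1, B), x)
  as.numeric(fit$residuals)
}

#' Norris gap-segment derivative
#'
#' Two-stage gap derivative in the Norris/TQ tradition: a centered moving
#' average of `window` points smooths the spectrum, then a finite
#' difference across a gap of `gap` points forms the derivative. For
#' first order, `d(i) = (m(i+g) - m(i-g)) / (2 g \Delta\nu)`; for second
#' order, `d(i) = (m(i+g) - 2 m(i) + m(i-g)) / (g \Delta\nu)^2`. Edge
#' points whose stencil is incomplete are dropped: the output (and its
#' grid) is shorter than the input by `(window - 1) + 2 * gap` points.
#'
#' @param x Numeric absorbance vector.
#' @param grid The [wavenumber_grid()] of `x`.
#' @param order Derivative order, 1 or 2.
#' @param window Odd smoothing-segment width in points (>= 3).
#' @param gap Gap size in points (>= 1).
#' @return A list with `values` (the derivative) and `grid` (the trimmed
#'   [wavenumber_grid()]).
#' @export
norris_derivative <- function(x, grid, order = 1, window = 5, gap = 3) {
  if (!order %in% c(1, 2)) stop("derivative order must be 1 or 2")
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (gap < 1) stop("gap must be >= 1")
  n <- length(x)
  if (n < window + 2 * gap)
    stop(sprintf("spectrum too short: need at least %d points, got %d",
                 window + 2 * gap, n))
  nu <- as.numeric(unclass(grid))
  if (length(nu) != n) stop("grid and spectrum lengths differ")
  dnu <- nu[2] - nu[1]
  half <- (window - 1) %/% 2

  # stage 1: centered moving average, valid on half+1 .. n-half
  cs <- cumsum(c(0, x))
  m_idx <- (half + 1):(n - half)
  m <- (cs[m_idx + half + 1] - cs[m_idx - half]) / window
  nm <- length(m)

  # stage 2: gap difference, valid on gap+1 .. nm-gap of the smoothed vector
  i <- (gap + 1):(nm - gap)
  d <- if (order == 1) {
    (m[i + gap] - m[i - gap]) / (2 * gap * dnu)
  } else {
    (m[i + gap] - 2 * m[i] + m[i - gap]) / (gap * dnu)^2
  }
  keep <- nu[m_idx][i]
  list(values = d, grid = wavenumber_grid(values = keep))
}

#' Preprocessing step constructors
#'
#' A preprocessing configuration is an ordered list of steps, each a list
#' with an `op` field (`"snv"`, `"detrend"` or `"derivative"`) and the
#' step's parameters. These helpers build well-formed steps.
#'
#' @param order Derivative order (1 or 2).
#' @param window,gap Norris filter segment and gap, in points.
#' @param polynomial_order Detrend baseline order.
#' @return A step list usable in [apply_pipeline()].
#' @export
step_snv <- function() list(op = "snv")

#' @rdname step_snv
#' @export
step_detrend <- function(polynomial_order = 2)
  list(op = "detrend", polynomial_order = polynomial_order)

#' @rdname step_snv
#' @export
step_derivative <- function(order = 1, window = 5, gap = 3)
  list(op = "derivative", order = order, window = window, gap = gap)

#' Default per-trait preprocessing configuration
#'
#' Encodes the treatment used throughout this package. Oil uses detrending
#' followed by SNV on the raw spectra. The remaining traits use SNV
#' followed by a Norris gap derivative (5-point segment, gap 3): second
#' order for the seven fatty acids, first order for protein, glucosinolate
#' and phytic acid. Scatter correction comes first because SNV applied
#' after differentiation rescales each spectrum by a derivative SD that is
#' dominated by high-frequency noise, destroying the per-sample signal
#' scale; differentiating the scatter-corrected spectrum is a purely
#' linear operation and keeps the mixture structure intact. Either order
#' can still be expressed by rearranging the returned list.
#'
#' @param trait Trait name (one of the eleven in
#'   [default_trait_params()]).
#' @return An ordered list of steps for [apply_pipeline()].
#' @export
default_preprocess <- function(trait) {
  second <- c("palmitic", "stearic", "oleic", "linoleic",
              "linolenic", "eicosenoic", "erucic")
  first <- c("protein", "glucosinolate", "phytic_acid")
  if (trait == "oil") {
    list(step_detrend(2), step_snv())
  } else if (trait %in% second) {
    list(step_snv(), step_derivative(order = 2, window = 5, gap = 3))
  } else if (trait %in% first) {
    list(step_snv(), step_derivative(order = 1, window = 5, gap = 3))
  } else {
    stop(sprintf("no default preprocessing for trait '%s'", trait))
  }
}

apply_step_one <- function(x, grid, step) {
  switch(step$op,
    snv = list(values = snv(x), grid = grid),
    detrend = list(values = detrend(x, grid,
                                    polynomial_order = step$polynomial_order),
                   grid = grid),
    derivative = norris_derivative(x, grid, order = step$order,
                                   window = step$window, gap = step$gap),
    stop(sprintf("unknown preprocessing op '%s'", step$op))
  )
}

#' Apply a preprocessing pipeline to a spectra set
#'
#' Applies the configured steps in order, independently to every spectrum.
#' Sample identifiers are preserved; an empty configuration returns the
#' input unchanged. Failures are annotated with the sample id and step
#' index at which they occurred.
#'
#' @param spectra A [spectra_set()].
#' @param config Ordered list of steps (see [step_snv()]); may be empty.
#' @return A [spectra_set()] on the (possibly trimmed) output grid.
#' @export
apply_pipeline <- function(spectra, config = list()) {
  if (length(config) == 0) return(spectra)
  grid <- spectra$grid
  M <- spectra$matrix
  for (s in seq_along(config)) {
    step <- config[[s]]
    out <- vector("list", nrow(M))
    for (i in seq_len(nrow(M))) {
      out[[i]] <- tryCatch(
        apply_step_one(M[i, ], grid, step),
        error = function(e) stop(sprintf(
          "preprocessing failed for sample '%s' at step %d (%s): %s",
          spectra$sample_ids[i], s, step$op, conditionMessage(e)),
          call. = FALSE)
      )
    }
    grid <- out[[1]]$grid
    M <- do.call(rbind, lapply(out, `[[`, "values"))
  }
  spectra_set(M, grid, sample_ids = spectra$sample_ids)
}
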