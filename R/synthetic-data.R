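#' Default per-trait population parameters
#'
#' The eleven seed-quality traits carried through the whole pipeline, with
#' the population mean, standard deviation and range used by the reference
#' generator. Defaults describe a diverse oilseed Brassica germplasm panel:
#' oil and protein in percent of seed weight, glucosinolates in micromoles
#' per gram defatted meal, phytic acid in percent, and the seven fatty
#' acids in percent of total oil. The wide, heavily skewed erucic range
#' (0.2--49.7 %) reflects panels mixing low-erucic (canola-quality) and
#' traditional high-erucic lines.
#'
#' @return A data.frame with columns `trait`, `mean`, `sd`, `min`, `max`
#'   (one row per trait, 11 rows).
#' @export
default_trait_params <- function() {
  df <- data.frame(
    trait = c("oil", "protein", "glucosinolate", "phytic_acid",
              "palmitic", "stearic", "oleic", "linoleic", "linolenic",
              "eicosenoic", "erucic"),
    mean = c(39.1, 27.2, 50.6, 2.7, 4.0, 2.1, 36.9, 31.8, 15.2, 2.8, 9.6),
    sd   = c(1.5,  8.4,  31.1, 0.8, 0.9, 0.6, 12.3, 7.7,  9.1,  3.6, 16.7),
    min  = c(34.9, 11.0, 10.9, 1.5, 2.0, 0.8, 9.7,  14.3, 9.1,  0.2, 0.2),
    max  = c(41.5, 37.4, 116.4, 3.9, 5.4, 3.1, 51.9, 43.2, 36.2, 10.7, 49.7),
    stringsAsFactors = FALSE
  )
  df
}

#' Default trait-trait correlations
#'
#' Only the relationships with a clear biochemical basis are imposed: the
#' strong inverse oleic--erucic relation (elongation of oleic to erucic
#' acid partitions the same C18:1 pool), and weaker negative relations of
#' oil with palmitic acid and with phytic acid. Magnitudes are synthetic
#' defaults, not measured values.
#'
#' @return A data.frame with columns `trait1`, `trait2`, `r`.
#' @export
default_trait_correlations <- function() {
  data.frame(
    trait1 = c("oleic", "oil", "oil"),
    trait2 = c("erucic", "palmitic", "phytic_acid"),
    r = c(-0.8, -0.4, -0.3),
    stringsAsFactors = FALSE
  )
}

#' Default absorbance band library
#'
#' One Gaussian band per informative wavenumber assignment: C-H first
#' overtones near 5,700--5,800 cm^-1, C-H/O-H combination bands near
#' 4,300--4,400 cm^-1 and C-H second overtones near 8,200--8,300 cm^-1 for
#' oil and the fatty acids (each fatty acid at a slightly distinct position
#' within those regions); N-H first overtone (6,500--6,600) and C-H/C=O
#' combination (4,800--4,900) bands for protein and glucosinolates; C-H,
#' P-OH/O-H (6,300) and a broad O-H/P-OH combination band for phytic acid;
#' and broad O-H water bands at 9,500, 7,500 and 5,500 cm^-1.
#'
#' Because the shared C-H regions carry the total lipid signal, each lipid
#' trait also gets the narrow marker band that distinguishes it in real
#' seed spectra: the triglyceride ester C=O second overtone near
#' 5,260 cm^-1 for total oil, cis =C-H first overtones near
#' 6,000--6,200 cm^-1 for the unsaturated fatty acids (position shifting
#' with double-bond count), and chain-length CH2 combination bands at
#' 4,200--4,290 cm^-1 for the saturated and very-long-chain acids. Without
#' these markers the eight lipid traits would be spectrally collinear and
#' no calibration could separate them.
#'
#' Widths are Gaussian sigmas in cm^-1; weights are absorbance per unit
#' concentration, scaled so a typical sample spans roughly 0.1--1.5
#' absorbance units.
#'
#' @return A data.frame with columns `trait`, `center`, `width`, `weight`.
#'   The `"water"` rows describe a nuisance constituent that never appears
#'   in the reference table.
#' @export
default_band_library <- function() {
  fa <- function(trait, c1, c2, c3, w1, marker, mw = 35, mwt = 0.0050)
    data.frame(trait = trait, center = c(c1, c2, c3, marker),
               width = c(80, 80, 80, mw),
               weight = c(w1, w1 * 2 / 3, w1 * 4 / 9, mwt),
               stringsAsFactors = FALSE)
  rbind(
    data.frame(trait = "oil", center = c(5750, 4350, 8250, 5260),
               width = c(80, 80, 80, 60),
               weight = c(0.0140, 0.0090, 0.0064, 0.0080),
               stringsAsFactors = FALSE),
    data.frame(trait = "protein", center = c(6540, 4840), width = 80,
               weight = c(0.0030, 0.0025), stringsAsFactors = FALSE),
    data.frame(trait = "glucosinolate", center = c(6590, 4890), width = 80,
               weight = c(0.0007, 0.0006), stringsAsFactors = FALSE),
    data.frame(trait = "phytic_acid", center = c(5750, 6300, 7000),
               width = c(80, 120, 300),
               weight = c(0.018, 0.022, 0.012), stringsAsFactors = FALSE),
    fa("palmitic",   5715, 4310, 8205, 0.0045, 4145, mw = 30, mwt = 0.0080),
    fa("stearic",    5725, 4325, 8215, 0.0045, 4212, mw = 30, mwt = 0.0150),
    fa("oleic",      5745, 4355, 8245, 0.0018, 6010, mwt = 0.0020),
    fa("linoleic",   5760, 4370, 8260, 0.0025, 6090, mwt = 0.0030),
    fa("linolenic",  5775, 4385, 8275, 0.0035, 6170, mwt = 0.0050),
    fa("eicosenoic", 5735, 4340, 8230, 0.0045, 4270, mw = 30, mwt = 0.0090),
    fa("erucic",     5790, 4395, 8290, 0.0020, 4292, mw = 30, mwt = 0.0025),
    data.frame(trait = "water", center = c(9500, 7500, 5500),
               width = c(150, 120, 130),
               weight = c(0.30, 0.25, 0.20), stringsAsFactors = FALSE),
    # stable seed-matrix absorbance (carbohydrate/fibre hull): constant unit
    # concentration for every sample; anchors the SNV normalization
    data.frame(trait = "background",
               center = c(4750, 5200, 6800, 8500, 10500),
               width = c(250, 200, 350, 400, 500),
               weight = c(0.30, 0.24, 0.18, 0.10, 0.05),
               stringsAsFactors = FALSE)
  )
}

#' Scatter and instrument-noise parameters
#'
#' Per-sample multiplicative gain (particle-size scatter), additive offset,
#' linear baseline tilt, and white per-point instrument noise. Defaults
#' emulate a benchtop FT-NIR: RMS noise 3e-3 absorbance units against a
#' mean-centered spectral signal whose RMS is near 0.3 AU, i.e. a spectral
#' signal-to-noise ratio of about 100; gain variation of 5 %, offsets of
#' 0.02 AU and tilts of 2e-6 AU per cm^-1.
#'
#' @param mult_scatter_sd SD of the multiplicative gain around 1
#'   (dimensionless).
#' @param add_offset_sd SD of the per-sample additive offset (AU).
#' @param baseline_slope_sd SD of the per-sample linear baseline slope
#'   (AU per cm^-1).
#' @param noise_sd SD of the per-point instrument noise (AU).
#' @param seed Integer seed driving every random draw in
#'   [generate_spectra()].
#' @return A list of class `"scatter_params"`.
#' @export
scatter_params <- function(mult_scatter_sd = 0.05, add_offset_sd = 0.02,
                           baseline_slope_sd = 2e-6, noise_sd = 3e-3,
                           seed = 1) {
  sds <- c(mult_scatter_sd, add_offset_sd, baseline_slope_sd, noise_sd)
  if (any(sds < 0)) stop("scatter/noise standard deviations must be >= 0")
  structure(list(mult_scatter_sd = mult_scatter_sd,
                 add_offset_sd = add_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scatter_params")
}

## Truncated-normal moments and moment matching ------------------------------

trunc_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  if (!is.finite(Z) || Z < 1e-12) return(c(NA_real_, NA_real_))
  dd <- stats::dnorm(al) - stats::dnorm(be)
  m <- mu + sigma * dd / Z
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z -
                    (dd / Z)^2)
  c(m, sqrt(max(v, 0)))
}

# Solve for the underlying (mu, sigma) whose [a, b]-truncated normal has the
# target mean exactly and the target SD as closely as the family allows (a
# truncated normal on [a, b] cannot exceed the near-uniform SD (b-a)/sqrt(12),
# which a heavily truncated, in truth bimodal trait such as erucic demands).
# A soft barrier keeps the in-bounds probability Z away from 0 so that the
# downstream resampling scheme stays practical.
match_truncnorm <- function(mean, sd, a, b) {
  obj <- function(p) {
    mu <- p[1]; sigma <- exp(p[2])
    Z <- stats::pnorm((b - mu) / sigma) - stats::pnorm((a - mu) / sigma)
    if (!is.finite(Z) || Z < 1e-12) return(1e6)
    tm <- trunc_moments(mu, sigma, a, b)
    if (anyNA(tm)) return(1e6)
    100 * ((tm[1] - mean) / sd)^2 + ((tm[2] - sd) / sd)^2 +
      25 * max(0, log(0.15 / Z))^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  mu <- fit$par[1]
  s <- exp(fit$par[2])
  # polish the mean to numerical exactness (truncated mean is increasing in mu)
  f <- function(m) trunc_moments(m, s, a, b)[1] - mean
  for (half_width in c(3, 6, 12, 24)) {
    lo <- mu - half_width * s
    hi <- mu + half_width * s
    flo <- f(lo); fhi <- f(hi)
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
      mu <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
      break
    }
  }
  c(mu = mu, sigma = s)
}

## Copula correlation calibration ---------------------------------------------

# Gauss-Hermite nodes/weights for N(0,1) expectations (Golub-Welsch)
gauss_hermite_norm <- function(n) {
  J <- diag(0, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), 2:n)] <- off
  J[cbind(2:n, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values * sqrt(2),
       weights = (e$vectors[1, ]^2))
}

# probabilists' Hermite polynomial values He_0..He_K at x
hermite_he <- function(x, K) {
  H <- matrix(0, length(x), K + 1)
  H[, 1] <- 1
  if (K >= 1) H[, 2] <- x
  if (K >= 2) for (k in 2:K) H[, k + 1] <- x * H[, k] - (k - 1) * H[, k - 1]
  H
}

# Hermite coefficients of the margin transform g (z -> trait value), so that
# the Pearson correlation of two transformed margins under a Gaussian copula
# with latent correlation r is sum_k k! c_ik c_jk r^k / (sd_i sd_j).
margin_hermite_coef <- function(g, K = 12, n_nodes = 80) {
  gh <- gauss_hermite_norm(n_nodes)
  gz <- g(gh$nodes)
  H <- hermite_he(gh$nodes, K)
  ck <- as.numeric(crossprod(H, gh$weights * gz)) / factorial(0:K)
  ck
}

# latent correlation whose transformed Pearson correlation equals `target`
calibrate_latent_r <- function(ci, cj, target, pair_label) {
  K <- length(ci) - 1
  fk <- factorial(1:K)
  num <- function(r) sum(fk * ci[-1] * cj[-1] * r^(1:K))
  sdi <- sqrt(sum(fk * ci[-1]^2))
  sdj <- sqrt(sum(fk * cj[-1]^2))
  f <- function(r) num(r) / (sdi * sdj) - target
  lim <- 0.999
  if (f(-lim) * f(lim) > 0)
    stop(sprintf("correlation %.2f unattainable for pair %s under the copula",
                 target, pair_label))
  stats::uniroot(f, c(-lim, lim), tol = 1e-10)$root
}

## Reference table generation -------------------------------------------------

#' Generate a laboratory reference table
#'
#' Draws per-sample trait values from a box-truncated multivariate normal.
#' Underlying location/scale parameters are moment-matched per trait so
#' that the truncated marginal reproduces the target mean exactly and the
#' target SD as closely as a truncated normal on that interval permits.
#' Cross-trait structure enters through a Gaussian copula: a latent
#' multivariate normal with the requested correlation matrix (repaired to
#' the nearest positive-definite matrix when needed) is mapped through
#' each trait's truncated-normal quantile function, so every margin is an
#' exact truncated normal and every value falls inside its bounds by
#' construction.
#'
#' @param params Trait parameter table as from [default_trait_params()].
#' @param correlations Pairwise correlation list as from
#'   [default_trait_correlations()]; `NULL` for independent traits.
#' @param n Number of samples (>= 2).
#' @param seed Integer seed; identical seed gives an identical table.
#' @return A data.frame: `sample_id` plus one numeric column per trait, all
#'   values inside `[min, max]`.
#' @export
generate_reference <- function(params = default_trait_params(),
                               correlations = default_trait_correlations(),
                               n, seed = 1) {
  if (!is.numeric(n) || n < 2)
    stop("n >= 2 samples are required to form a reference table")
  need <- c("trait", "mean", "sd", "min", "max")
  if (!all(need %in% names(params)))
    stop("params must have columns trait/mean/sd/min/max")
  if (any(params$sd <= 0)) stop("trait sd must be > 0")
  if (any(params$min >= params$mean | params$mean >= params$max))
    stop("each trait needs min < mean < max")
  traits <- params$trait
  k <- length(traits)

  mm <- t(vapply(seq_len(k), function(j)
    match_truncnorm(params$mean[j], params$sd[j], params$min[j], params$max[j]),
    numeric(2)))
  mu0 <- mm[, 1]
  s0 <- mm[, 2]
  margin_transform <- function(j) {
    al <- (params$min[j] - mu0[j]) / s0[j]
    be <- (params$max[j] - mu0[j]) / s0[j]
    pa <- stats::pnorm(al); pb <- stats::pnorm(be)
    function(z) mu0[j] + s0[j] * stats::qnorm(pa + stats::pnorm(z) * (pb - pa))
  }

  R <- diag(k)
  dimnames(R) <- list(traits, traits)
  pair_label <- NULL
  if (!is.null(correlations) && nrow(correlations) > 0) {
    coef_cache <- list()
    coef_of <- function(tr) {
      if (is.null(coef_cache[[tr]]))
        coef_cache[[tr]] <<- margin_hermite_coef(margin_transform(match(tr, traits)))
      coef_cache[[tr]]
    }
    for (i in seq_len(nrow(correlations))) {
      t1 <- correlations$trait1[i]; t2 <- correlations$trait2[i]
      r <- correlations$r[i]
      if (!(t1 %in% traits) || !(t2 %in% traits))
        stop(sprintf("correlation names unknown trait in pair (%s, %s)", t1, t2))
      if (abs(r) >= 1)
        stop(sprintf("correlation |r| >= 1 for pair (%s, %s)", t1, t2))
      # calibrate the latent correlation so the realized Pearson correlation
      # of the transformed margins matches the requested value
      lat <- calibrate_latent_r(coef_of(t1), coef_of(t2), r,
                                sprintf("(%s, %s)", t1, t2))
      R[t1, t2] <- R[t2, t1] <- lat
    }
    idx <- which.max(abs(correlations$r))
    pair_label <- sprintf("(%s, %s)", correlations$trait1[idx],
                          correlations$trait2[idx])
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10)
      stop(sprintf(
        "correlation matrix not positive definite even after repair; strongest pair %s",
        if (is.null(pair_label)) "(none)" else pair_label))
  }

  set.seed(seed)
  Z <- MASS::mvrnorm(n, mu = rep(0, k), Sigma = R)
  X <- matrix(0, n, k)
  for (j in seq_len(k)) {
    al <- (params$min[j] - mu0[j]) / s0[j]
    be <- (params$max[j] - mu0[j]) / s0[j]
    pa <- stats::pnorm(al)
    pb <- stats::pnorm(be)
    u <- stats::pnorm(Z[, j])
    # truncated-normal quantile transform; margins land in (min, max)
    X[, j] <- mu0[j] + s0[j] * stats::qnorm(pa + u * (pb - pa))
  }
  X <- pmin(pmax(X, matrix(params$min, n, k, byrow = TRUE)),
            matrix(params$max, n, k, byrow = TRUE))

  out <- as.data.frame(X)
  names(out) <- traits
  out <- cbind(data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                          stringsAsFactors = FALSE), out)
  out
}

reference_traits <- function(reference) {
  setdiff(names(reference), "sample_id")
}

## Spectra generation ---------------------------------------------------------

gaussian_band <- function(nu, center, width) {
  exp(-((nu - center)^2) / (2 * width^2))
}

# p x n_traits matrix of unit-concentration absorbance profiles
band_profiles <- function(bands, grid, traits) {
  nu <- unclass(grid)
  P <- vapply(traits, function(tr) {
    rows <- bands[bands$trait == tr, , drop = FALSE]
    prof <- numeric(length(nu))
    for (b in seq_len(nrow(rows)))
      prof <- prof + rows$weight[b] *
        gaussian_band(nu, rows$center[b], rows$width[b])
    prof
  }, numeric(length(nu)))
  colnames(P) <- traits
  P
}

#' Generate an FT-NIR spectra set from a reference table
#'
#' Builds a Beer-Lambert-style linear mixture: for sample i with
#' concentrations c and trait band profiles g,
#' \deqn{A_i(\nu) = a_i \sum_t c_{it} g_t(\nu) + b_i + s_i(\nu - \bar\nu) + \epsilon}
#' with per-sample multiplicative gain a, additive offset b, linear
#' baseline tilt s and white noise. A nuisance water constituent (O-H
#' bands, not present in the reference table) is added with per-sample
#' level `~ N(water_level, water_level_sd)` before the gain is applied.
#'
#' @param reference Reference table from [generate_reference()].
#' @param bands Band library as from [default_band_library()]; every trait
#'   in `reference` must have at least one band.
#' @param scatter A [scatter_params()] object (carries the seed).
#' @param grid A [wavenumber_grid()] inside 4,000--12,000 cm^-1.
#' @param water_level,water_level_sd Mean and SD of the per-sample water
#'   level (dimensionless multiplier of the water band weights). Set both
#'   to 0 to disable the water nuisance.
#' @return A [spectra_set()] with one row per reference sample.
#' @export
generate_spectra <- function(reference, bands = default_band_library(),
                             scatter = scatter_params(),
                             grid = wavenumber_grid(),
                             water_level = 1, water_level_sd = 0.05) {
  traits <- reference_traits(reference)
  missing_bands <- setdiff(traits, bands$trait)
  if (length(missing_bands))
    stop(sprintf("no absorbance band assigned to trait(s): %s",
                 paste(missing_bands, collapse = ", ")))
  nu <- unclass(grid)
  if (min(nu) < 4000 || max(nu) > 12000)
    stop("grid must lie within 4,000-12,000 cm^-1")
  conc <- as.matrix(reference[traits])
  n <- nrow(conc)
  p <- length(nu)

  P <- band_profiles(bands, grid, traits)
  A0 <- conc %*% t(P)
  if ("background" %in% bands$trait) {
    # stable seed-matrix absorbance, identical for every sample
    Pb <- band_profiles(bands, grid, "background")
    A0 <- A0 + matrix(as.numeric(Pb), n, p, byrow = TRUE)
  }

  set.seed(scatter$seed)
  has_water <- "water" %in% bands$trait &&
    (water_level != 0 || water_level_sd != 0)
  if (has_water) {
    w <- stats::rnorm(n, water_level, water_level_sd)
    Pw <- band_profiles(bands, grid, "water")
    A0 <- A0 + outer(w, as.numeric(Pw))
  }
  gain <- 1 + stats::rnorm(n, 0, scatter$mult_scatter_sd)
  offset <- stats::rnorm(n, 0, scatter$add_offset_sd)
  slope <- stats::rnorm(n, 0, scatter$baseline_slope_sd)
  noise <- matrix(stats::rnorm(n * p, 0, scatter$noise_sd), n, p)

  A <- A0 * gain + offset + outer(slope, nu - mean(nu)) + noise
  if (!all(is.finite(A))) stop("non-finite absorbance generated")
  spectra_set(A, grid, sample_ids = reference$sample_id)
}

## Outlier injection ----------------------------------------------------------

moisture_signature <- function(grid) {
  nu <- unclass(grid)
  gaussian_band(nu, 9500, 150) + 0.85 * gaussian_band(nu, 7500, 120) +
    0.70 * gaussian_band(nu, 5500, 130)
}

impurity_signature <- function(grid) {
  nu <- unclass(grid)
  gaussian_band(nu, 5800, 120) + 0.8 * gaussian_band(nu, 4400, 100) +
    0.6 * gaussian_band(nu, 6900, 200)
}

#' Inject contaminant outlier samples into a simulated study
#'
#' Mimics the unusable fraction of a seed panel: high-moisture samples gain
#' strong O-H water bands (9,500 / 7,500 / 5,500 cm^-1) scaled by
#' `moisture_boost`; physically impure samples (chaff, dust, broken seed)
#' gain a shared carbohydrate-like band signature plus an individual broad
#' random bump. Non-selected spectra are bit-identical to the input.
#'
#' @param study A study list with elements `spectra`, `reference`,
#'   `outlier_truth` (as returned by [simulate_study()]).
#' @param fraction Proportion of samples to contaminate, in `[0, 0.5)`.
#' @param moisture_boost Peak absorbance added at the strongest O-H band
#'   (AU); the impurity signature uses the same scale.
#' @param seed Integer seed.
#' @return The study with modified spectra and updated `outlier_truth`
#'   (columns `sample_id`, `is_outlier`, `reason`).
#' @export
inject_outliers <- function(study, fraction = 0.2, moisture_boost = 0.3,
                            seed = 1) {
  if (fraction < 0 || fraction >= 0.5)
    stop("outlier fraction must be in [0, 0.5): a majority cannot be outliers")
  n <- nrow(study$spectra$matrix)
  n_out <- round(fraction * n)
  truth <- data.frame(sample_id = study$spectra$sample_ids,
                      is_outlier = FALSE, reason = "none",
                      stringsAsFactors = FALSE)
  if (n_out == 0) {
    study$outlier_truth <- truth
    return(study)
  }
  set.seed(seed)
  chosen <- sort(sample.int(n, n_out))
  n_moist <- ceiling(n_out / 2)
  moist <- chosen[seq_len(n_moist)]
  impure <- setdiff(chosen, moist)

  grid <- study$spectra$grid
  nu <- unclass(grid)
  M <- study$spectra$matrix
  sig_m <- moisture_signature(grid)
  sig_i <- impurity_signature(grid)
  for (i in moist)
    M[i, ] <- M[i, ] + moisture_boost * stats::runif(1, 0.7, 1.3) * sig_m
  for (i in impure) {
    amp <- moisture_boost * stats::runif(1, 0.7, 1.3)
    ctr <- stats::runif(1, 4500, 11000)
    wid <- stats::runif(1, 200, 600)
    bump <- moisture_boost * stats::runif(1, 0.2, 0.5) *
      gaussian_band(nu, ctr, wid)
    M[i, ] <- M[i, ] + amp * sig_i + bump
  }
  truth$is_outlier[chosen] <- TRUE
  truth$reason[moist] <- "moisture"
  truth$reason[impure] <- "impurity"

  study$spectra <- spectra_set(M, grid, sample_ids = study$spectra$sample_ids)
  study$outlier_truth <- truth
  study
}

#' Simulate a complete seed-panel study
#'
#' Convenience wrapper chaining [generate_reference()],
#' [generate_spectra()] and [inject_outliers()] with sub-seeds derived
#' deterministically from one master seed. The default emulates the panel
#' this package targets: 100 seed lots, of which 20 % are unusable through
#' high moisture or physical impurities.
#'
#' @param n Number of samples.
#' @param seed Master integer seed.
#' @param params,correlations,bands,grid See the stage functions.
#' @param scatter A [scatter_params()] object; its `seed` field is
#'   overridden by a sub-seed of `seed`.
#' @param outlier_fraction,moisture_boost Passed to [inject_outliers()].
#' @param water_level,water_level_sd Passed to [generate_spectra()].
#' @return A list of class `"nir_study"`: `spectra` ([spectra_set()]),
#'   `reference` (data.frame) and `outlier_truth` (data.frame).
#' @export
simulate_study <- function(n = 100, seed = 1,
                           params = default_trait_params(),
                           correlations = default_trait_correlations(),
                           bands = default_band_library(),
                           scatter = scatter_params(),
                           grid = wavenumber_grid(),
                           outlier_fraction = 0.2, moisture_boost = 0.3,
                           water_level = 1, water_level_sd = 0.05) {
  set.seed(seed)
  sub <- sample.int(2^31 - 2, 3)
  reference <- generate_reference(params, correlations, n = n, seed = sub[1])
  scatter$seed <- sub[2]
  spectra <- generate_spectra(reference, bands = bands, scatter = scatter,
                              grid = grid, water_level = water_level,
                              water_level_sd = water_level_sd)
  study <- structure(list(spectra = spectra, reference = reference,
                          outlier_truth = NULL), class = "nir_study")
  inject_outliers(study, fraction = outlier_fraction,
                  moisture_boost = moisture_boost, seed = sub[3])
}

#' @export
print.nir_study <- function(x, ...) {
  cat(sprintf("<nir_study> %d samples, %d traits, %d truth outliers\n",
              nrow(x$reference), length(reference_traits(x$reference)),
              sum(x$outlier_truth$is_outlier)))
  invisible(x)
}
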