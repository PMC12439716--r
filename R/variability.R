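#' Descriptive statistics for one trait
#'
#' @param values Numeric trait values.
#' @return A list: `mean`, `min`, `max`, `sd` (n-1 denominator), `cv_pct`
#'   (`100 * sd / mean`; `NA` when the mean is 0).
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, min = min(values), max = max(values), sd = s,
       cv_pct = if (m == 0) NA_real_ else 100 * s / m)
}

#' RCBD analysis of variance for one trait
#'
#' Two-way additive decomposition of a complete, balanced randomized
#' complete block design (g genotypes x r replicate blocks):
#' genotype SS on g-1 df, block SS on r-1 df, error SS on (g-1)(r-1) df;
#' F = MS_genotype / MS_error with its upper-tail p-value.
#'
#' @param values Either a g x r numeric matrix (rows = genotypes,
#'   columns = replicates) or a long data.frame with columns `genotype`,
#'   `replicate`, `value`.
#' @return A data.frame of class `"anova_table"` with rows genotype,
#'   block, error: columns `source`, `df`, `ss`, `ms`, `f_value`,
#'   `p_value`. With zero error mean square the F and p are `NA`.
#' @export
rcbd_anova <- function(values) {
  if (is.data.frame(values)) {
    need <- c("genotype", "replicate", "value")
    if (!all(need %in% names(values)))
      stop("long format needs columns genotype/replicate/value")
    tab <- table(values$genotype, values$replicate)
    if (any(tab != 1)) {
      bad <- which(tab != 1, arr.ind = TRUE)
      stop(sprintf("unbalanced RCBD layout; offending cell(s): %s",
                   paste(sprintf("(%s, %s)", rownames(tab)[bad[, 1]],
                                 colnames(tab)[bad[, 2]]),
                         collapse = ", ")))
    }
    M <- tapply(values$value, list(values$genotype, values$replicate), mean)
  } else {
    M <- as.matrix(values)
  }
  g <- nrow(M); r <- ncol(M)
  if (r < 2) stop("need at least 2 replicate blocks")
  if (g < 2) stop("need at least 2 genotypes")
  if (anyNA(M)) stop("missing cells in the RCBD layout")
  grand <- mean(M)
  gm <- rowMeans(M)
  bm <- colMeans(M)
  ss_g <- r * sum((gm - grand)^2)
  ss_b <- g * sum((bm - grand)^2)
  ss_t <- sum((M - grand)^2)
  ss_e <- ss_t - ss_g - ss_b
  df_g <- g - 1; df_b <- r - 1; df_e <- (g - 1) * (r - 1)
  ms_g <- ss_g / df_g; ms_b <- ss_b / df_b; ms_e <- ss_e / df_e
  f <- if (ms_e > 0) ms_g / ms_e else NA_real_
  p <- if (is.na(f)) NA_real_ else stats::pf(f, df_g, df_e, lower.tail = FALSE)
  out <- data.frame(
    source = c("genotype", "block", "error"),
    df = c(df_g, df_b, df_e),
    ss = c(ss_g, ss_b, ss_e),
    ms = c(ms_g, ms_b, ms_e),
    f_value = c(f, NA_real_, NA_real_),
    p_value = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Genotypic and phenotypic coefficients of variation
#'
#' Standard variance-component estimators from the RCBD ANOVA:
#' \eqn{\hat\sigma^2_g = \max(0, (MS_g - MS_e)/r)},
#' \eqn{\hat\sigma^2_p = \hat\sigma^2_g + MS_e} (per-plot phenotypic
#' variance), GCV = \eqn{100\sqrt{\hat\sigma^2_g}/\bar{x}}, PCV likewise,
#' ratio = GCV/PCV (0 when PCV is 0). GCV <= PCV by construction; a
#' ratio near 1 marks a trait whose variation is almost entirely
#' genotypic.
#'
#' @param anova An `"anova_table"` from [rcbd_anova()].
#' @param r Replicate (block) count.
#' @param grand_mean Trait grand mean (> 0).
#' @return A list: `gcv_pct`, `pcv_pct`, `ratio`.
#' @export
gcv_pcv <- function(anova, r, grand_mean) {
  if (grand_mean <= 0) stop("grand mean must be > 0")
  ms_g <- anova$ms[anova$source == "genotype"]
  ms_e <- anova$ms[anova$source == "error"]
  sg2 <- max(0, (ms_g - ms_e) / r)
  sp2 <- sg2 + ms_e
  gcv <- 100 * sqrt(sg2) / grand_mean
  pcv <- 100 * sqrt(sp2) / grand_mean
  list(gcv_pct = gcv, pcv_pct = pcv,
       ratio = if (pcv == 0) 0 else gcv / pcv)
}

#' Simulate a balanced RCBD layout
#'
#' Genotype effects ~ N(0, sigma2_g), block effects ~ N(0, sigma2_b),
#' plot errors ~ N(0, sigma2_e), around `mean`. Used for Monte-Carlo
#' checks of the ANOVA and the GCV/PCV estimators.
#'
#' @param g,r Genotype and replicate counts.
#' @param mean Grand mean.
#' @param sigma2_g,sigma2_b,sigma2_e Variance components.
#' @param seed Integer seed.
#' @return A g x r matrix suitable for [rcbd_anova()].
#' @export
simulate_rcbd <- function(g, r, mean = 30, sigma2_g = 9, sigma2_b = 0.5,
                          sigma2_e = 1, seed = 1) {
  set.seed(seed)
  ge <- stats::rnorm(g, 0, sqrt(sigma2_g))
  be <- stats::rnorm(r, 0, sqrt(sigma2_b))
  err <- matrix(stats::rnorm(g * r, 0, sqrt(sigma2_e)), g, r)
  mean + outer(ge, be, `+`) + err
}

#' RCBD observations derived from a reference table
#'
#' Treats each reference sample as a genotype mean and emits a balanced
#' genotype x replicate layout per trait, with block effects and plot
#' errors scaled to each trait's SD. Defaults reflect typical laboratory
#' repeatability: plot error at 20 % and block effects at 10 % of the
#' genotypic SD, so most variation stays genotypic (GCV/PCV near 1).
#'
#' @param reference A reference table.
#' @param r Replicates per genotype.
#' @param block_sd_frac,error_sd_frac Block and error SDs as fractions of
#'   each trait's sample SD.
#' @param seed Integer seed.
#' @return A long data.frame: `genotype`, `replicate`, `trait`, `value`.
#' @export
rcbd_from_reference <- function(reference, r = 3, block_sd_frac = 0.1,
                                error_sd_frac = 0.2, seed = 1) {
  traits <- reference_traits(reference)
  set.seed(seed)
  out <- list()
  for (tr in traits) {
    v <- reference[[tr]]
    s <- stats::sd(v)
    be <- stats::rnorm(r, 0, block_sd_frac * s)
    err <- matrix(stats::rnorm(length(v) * r, 0, error_sd_frac * s),
                  length(v), r)
    M <- v + outer(rep(1, length(v)), be) + err
    out[[tr]] <- data.frame(
      genotype = rep(reference$sample_id, times = r),
      replicate = rep(sprintf("R%d", seq_len(r)), each = length(v)),
      trait = tr,
      value = as.numeric(M),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Full variability report per trait
#'
#' Combines descriptive statistics, the RCBD ANOVA and the GCV/PCV
#' estimators for every trait in a long-format RCBD table.
#'
#' @param obs Long data.frame with columns `genotype`, `replicate`,
#'   `trait`, `value`.
#' @return A data.frame, one row per trait: mean, sd, cv_pct, f_value,
#'   p_value, gcv_pct, pcv_pct, ratio.
#' @export
variability_report <- function(obs) {
  need <- c("genotype", "replicate", "trait", "value")
  if (!all(need %in% names(obs)))
    stop("obs needs columns genotype/replicate/trait/value")
  traits <- unique(obs$trait)
  rows <- lapply(traits, function(tr) {
    d <- obs[obs$trait == tr, c("genotype", "replicate", "value")]
    an <- rcbd_anova(d)
    r <- length(unique(d$replicate))
    ds <- descriptive_stats(d$value)
    gp <- gcv_pcv(an, r = r, grand_mean = mean(d$value))
    data.frame(trait = tr, mean = ds$mean, sd = ds$sd, cv_pct = ds$cv_pct,
               f_value = an$f_value[1], p_value = an$p_value[1],
               gcv_pct = gp$gcv_pct, pcv_pct = gp$pcv_pct,
               ratio = gp$ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
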