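test_that("descriptive statistics match their definitions", {
  d <- descriptive_stats(c(1, 2, 3))
  expect_equal(d$mean, 2)
  expect_equal(d$sd, 1)
  expect_equal(d$cv_pct, 50)
  dc <- descriptive_stats(rep(4, 6))
  expect_equal(dc$sd, 0)
  expect_equal(dc$cv_pct, 0)
  expect_true(is.na(descriptive_stats(c(-1, 1))$cv_pct))

  set.seed(1)
  x <- rnorm(30, 10, 2)
  s <- sqrt(sum((x - mean(x))^2) / 29)
  expect_equal(descriptive_stats(x)$sd, s, tolerance = 1e-12)
})

test_that("RCBD ANOVA reproduces the hand decomposition", {
  M <- rbind(g1 = c(1, 2), g2 = c(3, 4))
  an <- rcbd_anova(M)
  expect_equal(an$ss, c(4, 1, 0), tolerance = 1e-12)
  expect_equal(an$df, c(1, 1, 1))
  expect_true(is.na(an$f_value[1]))  # zero error mean square

  # degenerate: all equal
  an0 <- rcbd_anova(matrix(5, 4, 3))
  expect_equal(an0$ss, c(0, 0, 0))
  expect_true(is.na(an0$f_value[1]))
})

test_that("ANOVA SS and df are additive and match aov", {
  M <- simulate_rcbd(g = 12, r = 3, mean = 30, sigma2_g = 4, sigma2_b = 1,
                     sigma2_e = 1, seed = 2)
  an <- rcbd_anova(M)
  expect_equal(sum(an$df), 12 * 3 - 1)
  grand <- mean(M)
  expect_equal(sum(an$ss), sum((M - grand)^2), tolerance = 1e-8)

  d <- data.frame(genotype = factor(rep(1:12, 3)),
                  replicate = factor(rep(1:3, each = 12)),
                  value = as.numeric(M))
  ref <- summary(aov(value ~ genotype + replicate, d))[[1]]
  expect_equal(an$ss[1], ref["genotype", "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$ss[2], ref["replicate", "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$ss[3], ref["Residuals", "Sum Sq"], tolerance = 1e-8)
  expect_equal(an$f_value[1], ref["genotype", "F value"], tolerance = 1e-8)
  expect_equal(an$p_value[1], ref["genotype", "Pr(>F)"], tolerance = 1e-8)
})

test_that("long-format input is validated for balance", {
  d <- data.frame(genotype = c("a", "a", "b"), replicate = c("r1", "r2", "r1"),
                  value = 1:3)
  expect_error(rcbd_anova(d), "unbalanced.*b")
  d2 <- data.frame(genotype = rep(c("a", "b"), each = 2),
                   replicate = rep(c("r1", "r2"), 2), value = c(1, 2, 3, 4))
  expect_equal(rcbd_anova(d2)$ss, c(4, 1, 0), tolerance = 1e-12)
})

test_that("mean F over replicated simulations matches its expectation", {
  fs <- vapply(1:200, function(s)
    rcbd_anova(simulate_rcbd(g = 30, r = 3, sigma2_g = 4, sigma2_b = 0.5,
                             sigma2_e = 1, seed = s))$f_value[1],
    numeric(1))
  expect_lt(abs(mean(fs) - (1 + 3 * 4 / 1)) / (1 + 12), 0.1)
})

test_that("GCV/PCV estimators behave at the boundaries", {
  an <- data.frame(source = c("genotype", "block", "error"),
                   ms = c(2, 1, 2))
  gp <- gcv_pcv(an, r = 3, grand_mean = 10)
  expect_equal(gp$gcv_pct, 0)
  expect_equal(gp$ratio, 0)
  # vanishing error variance drives the ratio to 1
  an2 <- data.frame(source = c("genotype", "block", "error"),
                    ms = c(30, 1, 1e-12))
  gp2 <- gcv_pcv(an2, r = 3, grand_mean = 10)
  expect_gt(gp2$ratio, 0.999)
  expect_error(gcv_pcv(an2, r = 3, grand_mean = 0), "grand mean")
})

test_that("GCV recovers the simulated genotypic coefficient of variation", {
  gcvs <- vapply(1:500, function(s) {
    M <- simulate_rcbd(g = 30, r = 3, mean = 30, sigma2_g = 9,
                       sigma2_b = 0.5, sigma2_e = 1, seed = s)
    gcv_pcv(rcbd_anova(M), r = 3, grand_mean = mean(M))$gcv_pct
  }, numeric(1))
  expect_lt(abs(mean(gcvs) - 10) / 10, 0.1)
  # GCV never exceeds PCV
  M <- simulate_rcbd(g = 20, r = 3, seed = 999)
  gp <- gcv_pcv(rcbd_anova(M), r = 3, grand_mean = mean(M))
  expect_lte(gp$gcv_pct, gp$pcv_pct + 1e-9)
})

test_that("the F test holds its nominal size under no genotypic variance", {
  ps <- vapply(1:2000, function(s)
    rcbd_anova(simulate_rcbd(g = 30, r = 3, sigma2_g = 0, sigma2_b = 0.5,
                             sigma2_e = 1, seed = s))$p_value[1],
    numeric(1))
  rate <- mean(ps < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("reference-derived RCBD layouts yield trait-wise reports", {
  ref <- generate_reference(n = 30, seed = 3)
  obs <- rcbd_from_reference(ref, r = 3, seed = 4)
  expect_equal(nrow(obs), 30 * 3 * 11)
  rep <- variability_report(obs)
  expect_equal(nrow(rep), 11)
  expect_true(all(rep$gcv_pct <= rep$pcv_pct + 1e-9))
  expect_true(all(rep$ratio >= 0 & rep$ratio <= 1))
  # block and plot noise are small fractions of the genotypic spread
  expect_true(all(rep$ratio > 0.8))
  expect_true(all(rep$p_value < 0.01))
})
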