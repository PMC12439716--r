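test_that("default trait parameters describe the eleven-trait panel", {
  p <- default_trait_params()
  expect_equal(nrow(p), 11)
  expect_setequal(p$trait, c("oil", "protein", "glucosinolate", "phytic_acid",
                             "palmitic", "stearic", "oleic", "linoleic",
                             "linolenic", "eicosenoic", "erucic"))
  oil <- p[p$trait == "oil", ]
  expect_equal(unlist(oil[c("mean", "min", "max", "sd")], use.names = FALSE),
               c(39.1, 34.9, 41.5, 1.5))
  glc <- p[p$trait == "glucosinolate", ]
  expect_equal(c(glc$mean, glc$sd), c(50.6, 31.1))
  eru <- p[p$trait == "erucic", ]
  expect_equal(c(eru$mean, eru$min, eru$max), c(9.6, 0.2, 49.7))
  expect_true(all(p$min < p$mean & p$mean < p$max))
  expect_true(all(p$sd > 0))
})

test_that("generated reference respects bounds, targets and determinism", {
  ref <- generate_reference(n = 100, seed = 1)
  expect_equal(dim(ref), c(100, 12))
  p <- default_trait_params()
  for (j in seq_len(nrow(p)))
    expect_true(all(ref[[p$trait[j]]] >= p$min[j] & ref[[p$trait[j]]] <= p$max[j]),
                info = p$trait[j])
  expect_lt(cor(ref$oleic, ref$erucic), -0.6)
  expect_identical(ref, generate_reference(n = 100, seed = 1))
  expect_false(identical(ref, generate_reference(n = 100, seed = 2)))
})

test_that("large-sample means converge to the trait targets", {
  ref <- generate_reference(correlations = NULL, n = 10000, seed = 2)
  expect_lt(abs(mean(ref$oil) - 39.1), 0.05)
  p <- default_trait_params()
  for (j in seq_len(nrow(p))) {
    se <- sd(ref[[p$trait[j]]]) / 100
    expect_lt(abs(mean(ref[[p$trait[j]]]) - p$mean[j]), 3 * se)
  }
  # with no imposed correlations, everything decorrelates
  R <- cor(ref[-1]); diag(R) <- 0
  expect_lt(max(abs(R)), 0.1)
})

test_that("degenerate reference requests fail loudly", {
  expect_error(generate_reference(n = 1, seed = 1), "n >= 2")
  bad <- default_trait_correlations()
  bad$r[1] <- -1.2
  expect_error(generate_reference(correlations = bad, n = 10, seed = 1),
               "oleic, erucic")
  unknown <- data.frame(trait1 = "oil", trait2 = "caffeine", r = 0.5)
  expect_error(generate_reference(correlations = unknown, n = 10, seed = 1),
               "caffeine")
})

test_that("requested pairwise correlations are realized at large n", {
  ref <- generate_reference(n = 1000, seed = 3)
  expect_lt(abs(cor(ref$oleic, ref$erucic) - (-0.8)), 0.05)
  expect_lt(abs(cor(ref$oil, ref$palmitic) - (-0.4)), 0.1)
})

test_that("noiseless spectra are an exact linear map of concentrations", {
  ref <- generate_reference(mini_params(), correlations = NULL, n = 8, seed = 4)
  grid <- tiny_grid(n = 501, from = 4000)
  sp <- generate_spectra(ref, bands = mini_bands(),
                         scatter = noise_free_scatter(),
                         grid = grid, water_level = 0, water_level_sd = 0)
  # single-trait proportionality at each band center
  i5000 <- which.min(abs(unclass(grid) - 5000))
  ratio <- sp$matrix[, i5000] / ref$a
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
  # rank equals the number of traits with distinct band sets
  sv <- svd(sp$matrix)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), 2)
})

test_that("spectra generation is seeded and shape-stable", {
  ref <- generate_reference(n = 20, seed = 5)
  sp1 <- generate_spectra(ref, scatter = scatter_params(seed = 7))
  sp2 <- generate_spectra(ref, scatter = scatter_params(seed = 7))
  expect_identical(sp1$matrix, sp2$matrix)
  expect_equal(dim(sp1$matrix), c(20, 1001))
  expect_true(all(is.finite(sp1$matrix)))
})

test_that("SNV removes pure multiplicative/additive scatter", {
  ref <- generate_reference(mini_params(), correlations = NULL, n = 2, seed = 6)
  ref[2, c("a", "b")] <- ref[1, c("a", "b")]  # identical concentrations
  sp <- generate_spectra(ref, bands = mini_bands(),
                         scatter = scatter_params(0.1, 0.05, 0, 0, seed = 3),
                         grid = tiny_grid(n = 501, from = 4000),
                         water_level = 0, water_level_sd = 0)
  out <- apply_pipeline(sp, list(step_snv()))
  expect_lt(max(abs(out$matrix[1, ] - out$matrix[2, ])), 1e-8)
})

test_that("a trait without an absorbance band is rejected", {
  ref <- generate_reference(mini_params(), correlations = NULL, n = 5, seed = 1)
  bands <- mini_bands()[1, , drop = FALSE]
  expect_error(generate_spectra(ref, bands = bands,
                                scatter = noise_free_scatter(),
                                grid = tiny_grid()),
               "no absorbance band.*b")
})

test_that("outlier injection flags the requested fraction and only adds signal", {
  study <- simulate_study(n = 50, seed = 3, outlier_fraction = 0)
  expect_equal(sum(study$outlier_truth$is_outlier), 0)

  boosted <- inject_outliers(study, fraction = 0.2, moisture_boost = 0.5,
                             seed = 11)
  expect_equal(sum(boosted$outlier_truth$is_outlier), 10)
  expect_setequal(unique(boosted$outlier_truth$reason),
                  c("none", "moisture", "impurity"))

  flagged <- boosted$outlier_truth$is_outlier
  expect_identical(boosted$spectra$matrix[!flagged, ],
                   study$spectra$matrix[!flagged, ])
  # moisture samples gain absorbance at the 7,500 cm^-1 O-H band
  i7500 <- which.min(abs(unclass(study$spectra$grid) - 7500))
  moist <- boosted$outlier_truth$reason == "moisture"
  expect_true(all(boosted$spectra$matrix[moist, i7500] >
                  study$spectra$matrix[moist, i7500]))

  expect_error(inject_outliers(study, fraction = 0.5), "majority")
})

test_that("zero-fraction injection is a no-op", {
  study <- simulate_study(n = 30, seed = 9, outlier_fraction = 0)
  same <- inject_outliers(study, fraction = 0, seed = 4)
  expect_identical(same$spectra$matrix, study$spectra$matrix)
  expect_equal(sum(same$outlier_truth$is_outlier), 0)
})
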