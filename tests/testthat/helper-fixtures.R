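# Small fixtures shared across test files; everything is built in code.

# short uniform grid for fast preprocessing tests
tiny_grid <- function(n = 41, from = 5000, by = 8) {
  wavenumber_grid(from = from, to = from + (n - 1) * by, by = by)
}

random_spectrum <- function(n = 41, seed = 1) {
  set.seed(seed)
  stats::rnorm(n, mean = 0.5, sd = 0.2)
}

# minimal 2-trait simulation setup used where the full 11-trait panel
# would be overkill
mini_params <- function() {
  data.frame(trait = c("a", "b"),
             mean = c(10, 50), sd = c(2, 5),
             min = c(2, 30), max = c(18, 70),
             stringsAsFactors = FALSE)
}

mini_bands <- function() {
  data.frame(trait = c("a", "b"),
             center = c(5000, 7000), width = c(80, 80),
             weight = c(0.01, 0.004), stringsAsFactors = FALSE)
}

noise_free_scatter <- function(seed = 1)
  scatter_params(0, 0, 0, 0, seed = seed)

# independent naive Norris gap-segment derivative (direct double loop)
norris_oracle <- function(x, dnu, order, window, gap) {
  n <- length(x)
  half <- (window - 1) %/% 2
  m <- sapply((half + 1):(n - half), function(i) mean(x[(i - half):(i + half)]))
  nm <- length(m)
  idx <- (gap + 1):(nm - gap)
  if (order == 1) {
    sapply(idx, function(i) (m[i + gap] - m[i - gap]) / (2 * gap * dnu))
  } else {
    sapply(idx, function(i) (m[i + gap] - 2 * m[i] + m[i - gap]) / (gap * dnu)^2)
  }
}
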