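# Fixture builders shared across test files; everything is generated in code.

# A tiny recording with a known annotation pattern.
tiny_recording <- function(annotations = c(0L, 1L, 2L, 1L, 0L), seed = 42L) {
  n <- length(annotations)
  set.seed(seed)
  fog_recording(time = seq(0, by = 15, length.out = n),
                channels = matrix(rnorm(n * 9, sd = 10), n, 9),
                annotation = annotations,
                source_name = "tiny")
}

# Write a Daphnet-style text file from raw lines; returns the path.
write_daphnet_lines <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# Labeled matrix with two well-separated Gaussian classes (freeze = 0 shifted
# by `gap` standard deviations on every feature).
separable_matrix <- function(n = 400L, p = 9L, gap = 6, seed = 1L) {
  set.seed(seed)
  n0 <- n %/% 2L
  X <- rbind(matrix(rnorm(n0 * p), n0, p),
             matrix(rnorm((n - n0) * p, mean = gap), n - n0, p))
  fog_matrix(X, rep(c(0L, 1L), c(n0, n - n0)))
}

# Correlated bivariate normal sample with correlation `rho`.
correlated_gaussian <- function(n, rho = 0.8, seed = 1L) {
  set.seed(seed)
  z <- matrix(rnorm(n * 2), n, 2)
  cbind(z[, 1], rho * z[, 1] + sqrt(1 - rho^2) * z[, 2])
}

# GAN config sized for fast unit tests.
small_gan_cfg <- function(epochs = 5L, seed = 1L, ...) {
  gan_config(epochs = epochs, batch_size = 50L, lr_generator = 0.001,
             seed = seed, ...)
}

small_widths <- list(generator = c(32L, 16L), discriminator = c(32L, 16L))
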