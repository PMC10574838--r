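test_that("generator architecture reproduces the published layer arithmetic", {
  arch <- foggan_architecture()
  spec <- mlp_spec(arch$noise_dim, arch$generator_widths,
                   output_activation = "linear")
  expect_identical(count_parameters(spec), 4152071L)
  expect_identical(layer_parameter_counts(spec),
                   c(13824L, 1964286L, 1309696L, 524800L, 196992L, 98560L,
                     32896L, 8256L, 2080L, 528L, 153L))
  G <- build_generator()
  expect_identical(count_parameters(G), 4152071L)
  expect_identical(G$spec$layer_widths,
                   c(1536L, 1278L, 1024L, 512L, 384L, 256L, 128L, 64L, 32L,
                     16L, 9L))
  expect_identical(G$spec$output_activation, "linear")
  out <- mlp_forward(G, matrix(rnorm(5 * 8), 5, 8))
  expect_equal(dim(out), c(5L, 9L))
})

test_that("discriminator has a bounded logistic head and the printed first-layer count", {
  # the printed table implies an 8-dimensional input: (8 + 1) * 1536 = 13,824
  D8 <- build_discriminator(input_dim = 8)
  expect_identical(layer_parameter_counts(D8$spec)[1], 13824L)
  # functional discriminator: 9 features in, scalar probability out
  D <- build_discriminator(9, small_widths$discriminator)
  X <- matrix(rnorm(30 * 9), 30, 9)
  p <- mlp_forward(D, X)
  expect_equal(dim(p), c(30L, 1L))
  expect_true(all(p > 0 & p < 1))
  # dropout is declared after every hidden layer, never on the head
  expect_equal(D$spec$dropout, c(0.2, 0.2, 0))
  # inference is deterministic despite dropout
  expect_identical(mlp_forward(D, X), mlp_forward(D, X))
  expect_error(build_discriminator(0), "input_dim")
})

test_that("classifier and toy parameter counts match the closed form", {
  arch <- foggan_architecture()
  expect_identical(count_parameters(mlp_spec(9, arch$classifier_widths)), 3402L)
  expect_identical(count_parameters(mlp_spec(2, 3)), 9L)
})

test_that("adversarial training records one finite loss pair per epoch, reproducibly", {
  X <- correlated_gaussian(400, 0.8, seed = 5)
  cfg <- small_gan_cfg(epochs = 4L, seed = 11)
  fit <- train_foggan(X, cfg, noise_spec(4),
                      generator_widths = c(small_widths$generator, 2L),
                      discriminator_widths = small_widths$discriminator)
  expect_equal(nrow(fit$history), 4L)
  expect_true(all(is.finite(fit$history$loss_g)))
  expect_true(all(is.finite(fit$history$loss_d)))
  # identical seeds give identical histories and parameters
  fit2 <- train_foggan(X, cfg, noise_spec(4),
                       generator_widths = c(small_widths$generator, 2L),
                       discriminator_widths = small_widths$discriminator)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$G$W, fit2$G$W)
  # the literal generator loss trains too, with finite losses
  lit <- train_foggan(X, small_gan_cfg(epochs = 2L, seed = 11,
                                       generator_loss = "literal"),
                      noise_spec(4),
                      generator_widths = c(small_widths$generator, 2L),
                      discriminator_widths = small_widths$discriminator)
  expect_true(all(is.finite(lit$history$loss_g)))
  expect_error(train_foggan(X, gan_config(batch_size = 1000L)), "batch_size")
})

test_that("a generator trained on a point mass reproduces it", {
  cc <- c(0.5, -1, 2)
  X <- matrix(rep(cc, each = 500), 500, 3)
  fit <- train_foggan(X, small_gan_cfg(epochs = 200L, seed = 1), noise_spec(4),
                      generator_widths = c(small_widths$generator, 3L),
                      discriminator_widths = small_widths$discriminator)
  g <- mlp_forward(fit$G, matrix(rnorm(1000 * 4), 1000, 4))
  expect_true(all(abs(colMeans(g) - cc) < 0.15))
})

test_that("per-class fitting and sampling produce labeled data in original units", {
  dat <- preprocess(make_fixture_dataset(2, 0.3, 4000L, seed = 2))
  fit <- foggan(dat, small_gan_cfg(epochs = 3L, seed = 1), noise_spec(4),
                generator_widths = c(small_widths$generator, 9L),
                discriminator_widths = small_widths$discriminator)
  expect_named(fit$fits, c("0", "1"))
  expect_equal(sum(fit$class_mix), 1)

  synth <- sample_synthetic(fit, 1000L, class_mix = c("0" = 0.1, "1" = 0.9),
                            seed = 3)
  expect_equal(n_rows(synth), 1000L)
  expect_equal(sum(synth$y == 0L), 100L)
  expect_false(synth$scaled)
  # original units: magnitudes on the scale of the scaler's centers, not N(0,1)
  expect_gt(max(abs(colMeans(synth$X))), 50)

  # determinism of sampling
  synth2 <- sample_synthetic(fit, 1000L, class_mix = c("0" = 0.1, "1" = 0.9),
                             seed = 3)
  expect_identical(synth$X, synth2$X)
  # simulate() is the same path
  via_sim <- simulate(fit, nsim = 50L, seed = 9)
  expect_equal(n_rows(via_sim), 50L)
  expect_error(sample_synthetic(fit, 10L, class_mix = c("5" = 1)), "class")
})

test_that("checkpoints restore a model that samples identically", {
  dat <- preprocess(make_fixture_dataset(1, 0.3, 1500L, seed = 4))
  fit <- foggan(dat, small_gan_cfg(epochs = 2L, seed = 2), noise_spec(4),
                generator_widths = c(16L, 9L),
                discriminator_widths = c(16L))
  path <- tempfile(fileext = ".json")
  save_foggan(fit, path)
  back <- load_foggan(path)
  a <- sample_synthetic(fit, 100L, seed = 5)
  b <- sample_synthetic(back, 100L, seed = 5)
  expect_equal(a$X, b$X, tolerance = 1e-12)
  expect_equal(a$y, b$y)
})
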