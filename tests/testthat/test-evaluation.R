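test_that("correlation matrix matches the definitional sum formula and conventions", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  # definitional oracle: r = sum((x-mx)(y-my)) / sqrt(sum((x-mx)^2) sum((y-my)^2))
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  M <- cbind(x, y)
  R <- pearson_correlation_matrix(M)
  expect_equal(R[1, 2], r_def, tolerance = 1e-12)
  expect_equal(R, t(R), ignore_attr = TRUE)
  expect_equal(diag(R), rep(1, 2), ignore_attr = TRUE)

  # duplicated column and a negated column
  R2 <- pearson_correlation_matrix(cbind(x, x, -x))
  expect_equal(R2[1, 2], 1)
  expect_equal(R2[1, 3], -1)

  # constant column: off-diagonal 0 with a flag
  R3 <- pearson_correlation_matrix(cbind(x, rep(5, 3)))
  expect_equal(R3[1, 2], 0)
  expect_equal(attr(R3, "constant_columns"), 2L, ignore_attr = TRUE)
  expect_error(pearson_correlation_matrix(matrix(1, 1, 2)), "2 rows")
})

test_that("correlation strength bands reproduce the published categories", {
  expect_equal(classify_correlation_strength(0.2), "highly significant")
  expect_equal(classify_correlation_strength(0.12), "high")
  expect_equal(classify_correlation_strength(0.05), "moderate")
  expect_equal(classify_correlation_strength(0.001), "negligible")
  # signs do not matter; boundaries are half-open
  expect_equal(classify_correlation_strength(-0.25), "highly significant")
  expect_equal(classify_correlation_strength(c(0.01, 0.1, 0.16)),
               c("moderate", "high", "highly significant"))
  expect_error(classify_correlation_strength(1.2), "exceed")
})

test_that("correlation report is zero on self-comparison and flags broken columns", {
  set.seed(31)
  X <- matrix(rnorm(500 * 4), 500, 4) %*% matrix(rnorm(16), 4, 4)
  self <- correlation_report(X, X)
  expect_equal(max(self$abs_difference), 0)

  # same distribution, independent halves: differences stay at sampling noise
  set.seed(32)
  Z <- matrix(rnorm(100000 * 3), ncol = 3)
  Z <- cbind(Z[, 1], Z[, 1] * 0.5 + Z[, 2], Z[, 3])
  rep2 <- correlation_report(Z[1:50000, ], Z[50001:100000, ])
  expect_lt(max(rep2$abs_difference), 0.1)

  # permuting one synthetic column destroys its correlations the most
  set.seed(33)
  Y <- Z[1:5000, ]
  Yp <- Y; Yp[, 2] <- sample(Yp[, 2])
  rep3 <- correlation_report(Y, Yp)
  col_dev <- colSums(rep3$abs_difference)
  expect_equal(which.max(col_dev), 2L, ignore_attr = TRUE)
  expect_error(correlation_report(Y, Y[, 1:2]), "same number of columns")
})

test_that("cumulative-sum curves are running totals ending at the column sum", {
  A <- cbind(c(1, 2, 3), c(0, 0, 0))
  B <- cbind(c(2, 2, 2, 2), c(1, 1, 1, 1))
  cv <- cumulative_sum_curves(A, B, 1)
  expect_equal(cv$real, c(1, 3, 6))
  expect_equal(cv$synthetic, c(2, 4, 6, 8))
  expect_equal(cumulative_sum_curves(A, B, 2)$real, c(0, 0, 0))
  set.seed(34)
  R <- matrix(rnorm(200), 50, 4)
  for (j in 1:4)
    expect_equal(cumulative_sum_curves(R, R, j)$real[50], sum(R[, j]))
  expect_error(cumulative_sum_curves(A, B, 9), "out of range")
})

test_that("log mean/SD points follow the log10-epsilon rule", {
  X <- cbind(rep(10, 4) + c(-1, 1, -1, 1), c(0.5, -0.5, 0.5, -0.5))
  pts <- log_mean_std_points(X, X)
  # feature 1: mean 10, SD ~1.155 (n-1 denominator)
  expect_equal(pts$real[1, "log_abs_mean"], 1, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pts$real[1, "log_sd"], log10(sd(X[, 1])), tolerance = 1e-9,
               ignore_attr = TRUE)
  # zero-mean feature collapses to log10(eps)
  expect_equal(pts$real[2, "log_abs_mean"], log10(1e-12 + 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(pts$real, pts$synthetic)
})

test_that("PCA comparison uses the real frame and normalized variance ratios", {
  # rank-1 data: first component explains everything
  set.seed(35)
  t1 <- rnorm(300)
  X1 <- cbind(t1, 2 * t1, -t1)
  p1 <- pca_compare(X1, X1, k = 2)
  expect_equal(p1$explained_variance_ratio, c(1, 0), tolerance = 1e-9)

  # synthetic = real: identical projections
  X <- matrix(rnorm(400 * 5), 400, 5)
  p2 <- pca_compare(X, X, k = 3)
  expect_identical(p2$real_projection, p2$synthetic_projection)
  expect_equal(colMeans(p2$real_projection), rep(0, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(p2$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p2$explained_variance_ratio), 1 + 1e-12)

  # isotropic Gaussian: every ratio near 1/9
  set.seed(36)
  G <- matrix(rnorm(100000 * 9), ncol = 9)
  p3 <- pca_compare(G, G, k = 9)
  expect_equal(p3$explained_variance_ratio, rep(1 / 9, 9), tolerance = 0.02)
  expect_error(pca_compare(X, X, k = 6), "exceeds")
})

test_that("distribution metrics respect their bounds and closed forms", {
  x <- rep(c(1, 2, 3), 20)
  same <- feature_distribution_metrics(cbind(x), cbind(x))
  expect_equal(same$ks, 0)
  expect_equal(same$js, 0)

  # disjoint supports: maximal divergence
  disj <- feature_distribution_metrics(cbind(rep(0:1, 25)), cbind(rep(5:6, 25)))
  expect_equal(disj$ks, 1)
  expect_equal(disj$js, log(2), tolerance = 1e-9)

  # Uniform(0,1) vs Uniform(0.5,1.5): KS -> 0.5 (closed-form CDF gap)
  set.seed(37)
  u1 <- runif(100000); u2 <- runif(100000) + 0.5
  ks <- feature_distribution_metrics(cbind(u1), cbind(u2))$ks
  expect_equal(ks, 0.5, tolerance = 0.02)
  expect_error(feature_distribution_metrics(matrix(0, 0, 1), cbind(1)), "empty")
})

test_that("similarity report assembles, summarizes, and serializes losslessly", {
  set.seed(38)
  base <- matrix(rnorm(4000 * 9), ncol = 9) %*% diag(seq(1, 3, length.out = 9))
  halves <- list(base[1:2000, ], base[2001:4000, ])
  rep_self <- similarity_report(halves[[1]], halves[[1]])
  expect_equal(rep_self$summary[["max_abs_corr_diff"]], 0)
  expect_equal(rep_self$summary[["mean_ks"]], 0)

  rep_halves <- similarity_report(halves[[1]], halves[[2]])
  expect_lt(rep_halves$summary[["mean_ks"]], 0.05)

  path <- tempfile(fileext = ".json")
  write_similarity_report(rep_halves, path)
  back <- read_similarity_report(path)
  expect_equal(back$summary, rep_halves$summary, tolerance = 1e-12)
  expect_equal(back$correlation$real_matrix, rep_halves$correlation$real_matrix,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$cumsum_curves$f3$real, rep_halves$cumsum_curves$f3$real,
               tolerance = 1e-12)
  expect_equal(back$distributions$ks, rep_halves$distributions$ks,
               tolerance = 1e-12)
})

test_that("diagnostics are row-permutation invariant except cumulative sums", {
  set.seed(39)
  X <- matrix(rnorm(300 * 3), 300, 3)
  Y <- matrix(rnorm(300 * 3), 300, 3)
  Yp <- Y[sample(300), ]
  expect_equal(correlation_report(X, Y)$abs_difference,
               correlation_report(X, Yp)$abs_difference, tolerance = 1e-12)
  expect_equal(feature_distribution_metrics(X, Y),
               feature_distribution_metrics(X, Yp), tolerance = 1e-12)
  expect_equal(log_mean_std_points(X, Y), log_mean_std_points(X, Yp),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(cumulative_sum_curves(X, Y, 1)$synthetic,
                                cumulative_sum_curves(X, Yp, 1)$synthetic)))
})
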