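as_feature_matrix <- function(x) {
  if (inherits(x, "fog_matrix")) x <- x$X
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}

#' Pearson correlation matrix with a constant-column convention
#'
#' Like [stats::cor()] but with a fixed convention for degenerate input: a
#' constant column, whose correlations are undefined, gets 0 off-diagonal
#' and 1 on the diagonal, and the affected columns are flagged in the
#' `"constant_columns"` attribute.
#'
#' @param X numeric matrix (or [fog_matrix()]) with at least 2 rows.
#' @return symmetric correlation matrix with unit diagonal, entries in
#'   `[-1, 1]`.
#' @export
pearson_correlation_matrix <- function(X) {
  X <- as_feature_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows for a correlation matrix")
  const <- apply(X, 2L, function(col) all(col == col[1L]))
  r <- suppressWarnings(stats::cor(X))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "constant_columns") <- which(const)
  r
}

#' Categorize a correlation coefficient by magnitude
#'
#' The categorical reading of correlation strength: magnitudes in
#' `[0.16, 1]` are "highly significant", `[0.1, 0.16)` "high",
#' `[0.01, 0.1)` "moderate", and below 0.01 "negligible". The half-open
#' intervals close the gaps between the published interior points (0.01-0.1,
#' 0.1-0.15, 0.16-0.3) without moving any of them.
#'
#' @param r numeric vector of correlations, `|r| <= 1`.
#' @return character vector of band labels.
#' @examples
#' classify_correlation_strength(c(0.2, 0.12, 0.05, 0.001))
#' @export
classify_correlation_strength <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| must not exceed 1")
  a <- abs(r)
  out <- character(length(r))
  out[a < 0.01] <- "negligible"
  out[a >= 0.01 & a < 0.1] <- "moderate"
  out[a >= 0.1 & a < 0.16] <- "high"
  out[a >= 0.16] <- "highly significant"
  if (is.matrix(r)) out <- matrix(out, nrow(r), ncol(r), dimnames = dimnames(r))
  out
}

#' Correlation comparison between a real and a synthetic matrix
#'
#' Computes both correlation matrices, their elementwise absolute
#' difference, and the strength band of every entry of the real matrix.
#'
#' @param real,synthetic feature matrices (or [fog_matrix()]s) with the same
#'   number of columns.
#' @return an object of class `"correlation_report"` with fields
#'   `real_matrix`, `synthetic_matrix`, `abs_difference`, `band_labels`.
#' @export
correlation_report <- function(real, synthetic) {
  real <- as_feature_matrix(real)
  synthetic <- as_feature_matrix(synthetic)
  if (ncol(real) != ncol(synthetic))
    stop("'real' and 'synthetic' must have the same number of columns")
  cr <- pearson_correlation_matrix(real)
  cs <- pearson_correlation_matrix(synthetic)
  structure(list(real_matrix = cr, synthetic_matrix = cs,
                 abs_difference = abs(cr - cs),
                 band_labels = classify_correlation_strength(cr)),
            class = "correlation_report")
}

#' Cumulative-sum curves of one feature
#'
#' Running totals in row order for the real and synthetic columns; the final
#' point of each curve equals the column total. Unlike every other
#' diagnostic here, these curves depend on row order.
#'
#' @param real,synthetic feature matrices (or [fog_matrix()]s).
#' @param feature_index column index, 1 to 9.
#' @return list with numeric vectors `real` and `synthetic`.
#' @export
cumulative_sum_curves <- function(real, synthetic, feature_index) {
  real <- as_feature_matrix(real)
  synthetic <- as_feature_matrix(synthetic)
  if (feature_index < 1L || feature_index > ncol(real) ||
      feature_index > ncol(synthetic))
    stop("'feature_index' out of range")
  list(real = cumsum(real[, feature_index]),
       synthetic = cumsum(synthetic[, feature_index]))
}

#' Per-feature absolute log mean and log SD points
#'
#' For each feature of each matrix: `(log10(|mean| + eps), log10(sd + eps))`
#' with `eps = 1e-12` guarding exact zeros. Overlap of the two point sets
#' indicates matching first and second moments on a log scale.
#'
#' @param real,synthetic feature matrices (or [fog_matrix()]s).
#' @param eps additive guard before taking logs.
#' @return list of two matrices (`real`, `synthetic`), one row per feature,
#'   columns `log_abs_mean` and `log_sd`.
#' @export
log_mean_std_points <- function(real, synthetic, eps = 1e-12) {
  pts <- function(X) {
    X <- as_feature_matrix(X)
    cbind(log_abs_mean = log10(abs(colMeans(X)) + eps),
          log_sd = log10(apply(X, 2L, stats::sd) + eps))
  }
  list(real = pts(real), synthetic = pts(synthetic))
}

#' PCA comparison with the real data as the reference frame
#'
#' Principal components are fit on the standardized real matrix only; the
#' synthetic matrix is centered/scaled with the real statistics and
#' projected onto the real loadings. Matching projection clouds and
#' explained-variance profiles indicate matching covariance structure.
#'
#' @param real,synthetic feature matrices (or [fog_matrix()]s).
#' @param k number of components to return (`k <=` feature count).
#' @return list with `loadings` (p x k), `real_projection`,
#'   `synthetic_projection` (n x k each) and `explained_variance_ratio`
#'   (length k, non-increasing, summing to at most 1).
#' @export
pca_compare <- function(real, synthetic, k = 2L) {
  real <- as_feature_matrix(real)
  synthetic <- as_feature_matrix(synthetic)
  if (k > ncol(real)) stop("'k' exceeds the feature count")
  center <- colMeans(real)
  scl <- apply(real, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  std <- function(X) sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")
  fit <- stats::prcomp(std(real), center = FALSE, scale. = FALSE)
  ratios <- fit$sdev^2 / sum(fit$sdev^2)
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  list(loadings = load,
       real_projection = std(real) %*% load,
       synthetic_projection = std(synthetic) %*% load,
       explained_variance_ratio = ratios[seq_len(k)])
}

# Two-sample Kolmogorov-Smirnov statistic: supremum of the empirical-CDF
# gap, evaluated at the distinct pooled values so ties are handled exactly
# (identical samples score 0).
ks_statistic <- function(x, y) {
  v <- sort(unique(c(x, y)))
  Fx <- findInterval(v, sort(x)) / length(x)
  Fy <- findInterval(v, sort(y)) / length(y)
  max(abs(Fx - Fy))
}

# Jensen-Shannon divergence (natural log) between two samples, on `bins`
# shared equal-width bins spanning the pooled range.
js_divergence <- function(x, y, bins = 50L) {
  rng <- range(c(x, y))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  p <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(x)
  q <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(y)
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log(a[nz] / b[nz]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Per-feature distribution divergences
#'
#' For each feature, the two-sample Kolmogorov-Smirnov statistic (supremum
#' of the empirical-CDF gap, in `[0, 1]`) and the Jensen-Shannon divergence
#' (natural log, 50 shared equal-width bins over the pooled range, in
#' `[0, ln 2]`). Identical samples score 0 on both; disjoint supports score
#' the maxima.
#'
#' @param real,synthetic feature matrices (or [fog_matrix()]s) with matching
#'   columns and at least one row each.
#' @param bins number of shared histogram bins for the JS divergence.
#' @return data frame with columns `feature`, `ks`, `js`.
#' @export
feature_distribution_metrics <- function(real, synthetic, bins = 50L) {
  real <- as_feature_matrix(real)
  synthetic <- as_feature_matrix(synthetic)
  if (nrow(real) == 0L || nrow(synthetic) == 0L) stop("empty input")
  if (ncol(real) != ncol(synthetic)) stop("column-count mismatch")
  p <- ncol(real)
  data.frame(
    feature = if (!is.null(colnames(real))) colnames(real) else paste0("f", seq_len(p)),
    ks = vapply(seq_len(p), function(j)
      ks_statistic(real[, j], synthetic[, j]), numeric(1)),
    js = vapply(seq_len(p), function(j)
      js_divergence(real[, j], synthetic[, j], bins), numeric(1)),
    row.names = NULL)
}

#' Full real-versus-synthetic similarity report
#'
#' Assembles every diagnostic of the similarity suite — correlation matrices
#' and their absolute difference, per-feature cumulative-sum curves,
#' absolute log mean/SD points, a PCA comparison in the real data's frame,
#' and per-feature KS/JS divergences — plus two scalar summaries: the
#' maximum absolute correlation difference and the mean per-feature KS
#' statistic. Both scalars are bounded, zero on self-comparison, and grow
#' with dissimilarity.
#'
#' @param real,synthetic preprocessed feature matrices (or [fog_matrix()]s)
#'   in original units, same column count.
#' @param pca_k number of principal components retained.
#' @param bins histogram bins for the JS divergence.
#' @return an object of class `"similarity_report"`.
#' @export
similarity_report <- function(real, synthetic, pca_k = 2L, bins = 50L) {
  real_m <- as_feature_matrix(real)
  synth_m <- as_feature_matrix(synthetic)
  corr <- correlation_report(real_m, synth_m)
  p <- ncol(real_m)
  curves <- lapply(seq_len(p), function(j)
    cumulative_sum_curves(real_m, synth_m, j))
  names(curves) <- paste0("f", seq_len(p))
  dist <- feature_distribution_metrics(real_m, synth_m, bins)
  structure(list(
    correlation = corr,
    cumsum_curves = curves,
    log_mean_std = log_mean_std_points(real_m, synth_m),
    pca = pca_compare(real_m, synth_m, pca_k),
    distributions = dist,
    summary = c(max_abs_corr_diff = max(corr$abs_difference),
                mean_ks = mean(dist$ks)),
    n_real = nrow(real_m), n_synthetic = nrow(synth_m)),
    class = "similarity_report")
}

#' @export
print.similarity_report <- function(x, ...) {
  cat(sprintf("Similarity report: %d real vs %d synthetic rows, %d features\n",
              x$n_real, x$n_synthetic, ncol(x$correlation$real_matrix)))
  cat(sprintf("  max |corr(real) - corr(synthetic)|: %.4f\n",
              x$summary[["max_abs_corr_diff"]]))
  cat(sprintf("  mean per-feature KS statistic:      %.4f\n",
              x$summary[["mean_ks"]]))
  cat(sprintf("  mean per-feature JS divergence:     %.4f (max ln 2 = %.4f)\n",
              mean(x$distributions$js), log(2)))
  invisible(x)
}

#' Serialize / restore a similarity report
#'
#' JSON round trip of every matrix, curve and scalar in the report.
#' Cumulative-sum curves may be thinned with `max_curve_points` for compact
#' files; the default keeps them whole (lossless round trip).
#'
#' @param report a [similarity_report()].
#' @param path JSON file path.
#' @param max_curve_points optional cap on stored points per curve.
#' @return `path` (writer, invisibly) or a `"similarity_report"` (reader).
#' @export
write_similarity_report <- function(report, path, max_curve_points = Inf) {
  stopifnot(inherits(report, "similarity_report"))
  r <- unclass(report)
  r$correlation <- unclass(r$correlation)
  r$summary <- as.list(r$summary)  # keep names (a bare vector would drop them)
  if (is.finite(max_curve_points)) {
    r$cumsum_curves <- lapply(r$cumsum_curves, function(cv) {
      thin <- function(v) if (length(v) > max_curve_points)
        v[unique(round(seq(1, length(v), length.out = max_curve_points)))] else v
      list(real = thin(cv$real), synthetic = thin(cv$synthetic))
    })
  }
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_similarity_report
#' @export
read_similarity_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  r$correlation <- structure(r$correlation, class = "correlation_report")
  r$distributions <- as.data.frame(r$distributions)
  r$summary <- unlist(r$summary)
  structure(r, class = "similarity_report")
}

#' Render the similarity diagnostics as figures
#'
#' Five figure families on the current graphics device: correlation heatmaps
#' (real, synthetic, absolute difference), cumulative-sum overlays, log
#' mean/SD scatter, PCA projection clouds, and per-feature divergence bars.
#'
#' @param x a [similarity_report()].
#' @param which subset of `c("correlation", "cumsum", "logmoments", "pca",
#'   "distribution")`.
#' @param ... ignored.
#' @export
plot.similarity_report <- function(x, which = c("correlation", "cumsum",
                                                "logmoments", "pca",
                                                "distribution"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  pal <- grDevices::hcl.colors(64, "RdBu", rev = TRUE)
  if ("correlation" %in% which) {
    old <- graphics::par(mfrow = c(1, 3)); on.exit(graphics::par(old), add = TRUE)
    for (nm in c("real_matrix", "synthetic_matrix", "abs_difference")) {
      m <- x$correlation[[nm]]
      graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m[rev(seq_len(nrow(m))), ]),
                      col = pal, zlim = if (nm == "abs_difference") c(0, 1) else c(-1, 1),
                      xlab = "", ylab = "", main = gsub("_", " ", nm), axes = FALSE)
    }
    graphics::par(old)
  }
  if ("cumsum" %in% which) {
    old <- graphics::par(mfrow = c(3, 3)); on.exit(graphics::par(old), add = TRUE)
    for (nm in names(x$cumsum_curves)) {
      cv <- x$cumsum_curves[[nm]]
      graphics::matplot(seq_along(cv$real), cbind(cv$real, cv$synthetic[seq_along(cv$real)]),
                        type = "l", lty = 1, col = c("black", "firebrick"),
                        xlab = "row", ylab = "cumsum", main = nm)
    }
    graphics::par(old)
  }
  if ("logmoments" %in% which) {
    pts <- x$log_mean_std
    graphics::plot(pts$real[, 1L], pts$real[, 2L], pch = 19,
                   xlab = "log10 |mean|", ylab = "log10 SD",
                   main = "absolute log mean / SD")
    graphics::points(pts$synthetic[, 1L], pts$synthetic[, 2L], pch = 1,
                     col = "firebrick")
    graphics::legend("topleft", c("real", "synthetic"), pch = c(19, 1),
                     col = c("black", "firebrick"), bty = "n")
  }
  if ("pca" %in% which) {
    pr <- x$pca$real_projection
    ps <- x$pca$synthetic_projection
    graphics::plot(pr[, 1L], pr[, 2L], pch = ".", col = "black",
                   xlab = "PC1", ylab = "PC2", main = "PCA (real frame)")
    graphics::points(ps[, 1L], ps[, 2L], pch = ".", col = "firebrick")
  }
  if ("distribution" %in% which) {
    old <- graphics::par(mfrow = c(3, 3)); on.exit(graphics::par(old), add = TRUE)
    for (j in seq_len(nrow(x$distributions))) {
      graphics::barplot(c(ks = x$distributions$ks[j], js = x$distributions$js[j]),
                        main = x$distributions$feature[j], ylim = c(0, 1))
    }
    graphics::par(old)
  }
  invisible(x)
}
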