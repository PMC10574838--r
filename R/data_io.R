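#' @keywords internal
#' @importFrom stats predict simulate
"_PACKAGE"

# Canonical channel order: ankle (shank), upper leg (thigh), trunk; each as
# horizontal-forward, vertical, horizontal-lateral acceleration in milli-g.
FOG_CHANNELS <- c("ankle_hor", "ankle_ver", "ankle_lat",
                  "thigh_hor", "thigh_ver", "thigh_lat",
                  "trunk_hor", "trunk_ver", "trunk_lat")

#' Construct a sensor recording
#'
#' A recording is one parsed sensor file: millisecond time stamps, nine
#' acceleration channels (milli-g) in the order ankle/thigh/trunk x
#' horizontal-forward/vertical/lateral, a per-row annotation in `{0, 1, 2}`
#' (0 = not part of the experiment, 1 = experiment without freeze,
#' 2 = freeze), and a source tag.
#'
#' @param time integer vector of millisecond time stamps, strictly increasing.
#' @param channels numeric matrix with 9 columns, one row per time stamp.
#' @param annotation integer vector in `{0, 1, 2}`, same length as `time`.
#' @param source_name single string tagging the recording's origin.
#' @return an object of class `"fog_recording"`.
#' @export
fog_recording <- function(time, channels, annotation, source_name = "recording") {
  if (!is.matrix(channels)) channels <- matrix(channels, ncol = 9L)
  if (ncol(channels) != 9L) stop("'channels' must have exactly 9 columns")
  n <- nrow(channels)
  if (length(time) != n || length(annotation) != n)
    stop("'time', 'channels' and 'annotation' must have equal length")
  if (!all(annotation %in% c(0L, 1L, 2L)))
    stop("annotation values must lie in {0, 1, 2}")
  if (n > 1L && any(diff(time) <= 0))
    stop("'time' must be strictly increasing")
  colnames(channels) <- FOG_CHANNELS
  structure(list(time = as.numeric(time),
                 channels = channels,
                 annotation = as.integer(annotation),
                 source_name = as.character(source_name)[1L]),
            class = "fog_recording")
}

#' Read a Daphnet-style recording file
#'
#' Parses a plain-text sensor file with one sample per line and exactly 11
#' whitespace-separated numeric fields: time stamp (ms), nine acceleration
#' channels (milli-g), and an annotation in `{0, 1, 2}`. Rows annotated 0
#' (outside the experiment) are retained here and removed only by
#' [preprocess()], so corpus-level row counts stay observable.
#'
#' @param path path to the file.
#' @return a [fog_recording()] whose `source_name` is the file's base name.
#' @export
read_daphnet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(fog_recording(numeric(0), matrix(numeric(0), ncol = 9L),
                         integer(0), basename(path)))
  }
  tok <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(tok)
  if (any(nf != 11L)) {
    bad <- which(nf != 11L)[1L]
    stop(sprintf("parse error at line %d of '%s': expected 11 fields, found %d",
                 line_no[bad], basename(path), nf[bad]))
  }
  vals <- suppressWarnings(as.numeric(unlist(tok, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1L] / 11)
    stop(sprintf("parse error at line %d of '%s': non-numeric field",
                 line_no[bad], basename(path)))
  }
  m <- matrix(vals, ncol = 11L, byrow = TRUE)
  ann <- m[, 11L]
  if (!all(ann %in% c(0, 1, 2))) {
    bad <- which(!ann %in% c(0, 1, 2))[1L]
    stop(sprintf("validation error at line %d of '%s': annotation %s not in {0, 1, 2}",
                 line_no[bad], basename(path), format(ann[bad])))
  }
  fog_recording(m[, 1L], m[, 2:10], as.integer(ann), basename(path))
}

#' Write a recording in the Daphnet text format
#'
#' Symmetric counterpart of [read_daphnet()]: one line per sample, 11
#' whitespace-separated fields (time, nine channels, annotation).
#'
#' @param rec a [fog_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_daphnet <- function(rec, path) {
  stopifnot(inherits(rec, "fog_recording"))
  m <- cbind(rec$time, rec$channels, rec$annotation)
  utils::write.table(m, path, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Combine recordings into one collection with per-row source tags
#'
#' @param recordings non-empty list of [fog_recording()] objects sharing the
#'   9-channel schema.
#' @return an object of class `"fog_dataset"`: stacked `time`, `channels`,
#'   `annotation`, and a per-row `source` tag.
#' @export
combine_recordings <- function(recordings) {
  if (inherits(recordings, "fog_recording")) recordings <- list(recordings)
  if (!is.list(recordings) || length(recordings) == 0L)
    stop("'recordings' must be a non-empty list of recordings")
  if (!all(vapply(recordings, inherits, logical(1), "fog_recording")))
    stop("all elements must be 'fog_recording' objects")
  structure(list(
    time = unlist(lapply(recordings, `[[`, "time"), use.names = FALSE),
    channels = do.call(rbind, lapply(recordings, `[[`, "channels")),
    annotation = unlist(lapply(recordings, `[[`, "annotation"), use.names = FALSE),
    source = unlist(lapply(recordings, function(r)
      rep(r$source_name, length(r$time))), use.names = FALSE)),
    class = "fog_dataset")
}

#' Number of rows in a recording, collection or labeled matrix
#' @param x a `"fog_recording"`, `"fog_dataset"` or `"fog_matrix"`.
#' @return integer row count.
#' @export
n_rows <- function(x) {
  if (inherits(x, "fog_matrix")) return(nrow(x$X))
  if (inherits(x, c("fog_recording", "fog_dataset"))) return(length(x$annotation))
  stop("unsupported type")
}

#' Construct a labeled feature matrix
#'
#' The tabular container downstream of preprocessing: an `N x 9` feature
#' matrix plus binary labels with the convention 0 = freeze, 1 = no-freeze.
#'
#' @param X numeric matrix with 9 columns.
#' @param y labels in `{0, 1}`, length `nrow(X)`.
#' @param scaled logical, whether `X` is standardized.
#' @param scaler_state the [fit_scaler()] state used, if `scaled`.
#' @return an object of class `"fog_matrix"`.
#' @export
fog_matrix <- function(X, y, scaled = FALSE, scaler_state = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("'X' and 'y' must have matching length")
  if (length(y) && !all(y %in% c(0L, 1L))) stop("labels must lie in {0, 1}")
  if (scaled && is.null(scaler_state)) stop("scaled data must carry scaler state")
  if (is.null(colnames(X)) && ncol(X) == 9L) colnames(X) <- FOG_CHANNELS
  structure(list(X = X, y = as.integer(y), scaled = isTRUE(scaled),
                 scaler_state = scaler_state),
            class = "fog_matrix")
}

#' Preprocess a recording collection into a labeled matrix
#'
#' Applies the corpus preprocessing rule: rows annotated 0 (outside the
#' experiment) are excluded; the remaining annotations are relabeled to the
#' binary convention freeze = 0 (original annotation 2) and no-freeze = 1
#' (original annotation 1). Time and source columns are dropped; the result
#' keeps only the nine acceleration channels and the binary label.
#'
#' @param data a `"fog_dataset"` (or single `"fog_recording"`).
#' @return a [fog_matrix()] with unscaled features.
#' @export
preprocess <- function(data) {
  if (inherits(data, "fog_recording")) data <- combine_recordings(list(data))
  stopifnot(inherits(data, "fog_dataset"))
  keep <- data$annotation != 0L
  if (!any(keep))
    stop("no rows survive preprocessing (all annotations are 0); training is impossible")
  ann <- data$annotation[keep]
  y <- ifelse(ann == 2L, 0L, 1L)
  fog_matrix(data$channels[keep, , drop = FALSE], y)
}

#' Split a labeled matrix into training and evaluation parts
#'
#' Uniform random row-level split with exactly `floor(train_fraction * N)`
#' training rows; the partition is disjoint, exhaustive and deterministic
#' for a given seed.
#'
#' @param m a [fog_matrix()] with at least 2 rows.
#' @param train_fraction fraction in `(0, 1)`; defaults to 0.8.
#' @param seed integer seed for the row permutation.
#' @return list with elements `train` and `eval`, both `"fog_matrix"`.
#' @export
split_train_eval <- function(m, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(m, "fog_matrix"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie strictly between 0 and 1")
  n <- nrow(m$X)
  if (n < 2L) stop("need at least 2 rows to split")
  n_train <- floor(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  take <- function(i) fog_matrix(m$X[i, , drop = FALSE], m$y[i],
                                 m$scaled, m$scaler_state)
  list(train = take(idx), eval = take(setdiff(seq_len(n), idx)))
}

#' Fit a per-feature standardizing scaler on the training split
#'
#' Location is the per-feature mean, scale the per-feature standard
#' deviation; a constant feature gets scale forced to 1 so it maps to zero
#' and inverts exactly. Fit on the training split only, then applied to
#' every other matrix so evaluation data never leak into the scaling.
#'
#' @param train an unscaled [fog_matrix()].
#' @return an object of class `"fog_scaler"` with fields `center` and `scale`.
#' @export
fit_scaler <- function(train) {
  stopifnot(inherits(train, "fog_matrix"))
  if (train$scaled) stop("scaler must be fit on unscaled data")
  center <- colMeans(train$X)
  scale <- apply(train$X, 2L, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(center = center, scale = scale), class = "fog_scaler")
}

#' Standardize a labeled matrix with a fitted scaler
#' @param m an unscaled [fog_matrix()].
#' @param s a `"fog_scaler"` from [fit_scaler()].
#' @return the scaled [fog_matrix()], carrying `s` as its scaler state.
#' @export
apply_scaler <- function(m, s) {
  stopifnot(inherits(m, "fog_matrix"))
  if (!inherits(s, "fog_scaler")) stop("'s' is not a fitted scaler")
  X <- sweep(sweep(m$X, 2L, s$center, "-"), 2L, s$scale, "/")
  fog_matrix(X, m$y, scaled = TRUE, scaler_state = s)
}

#' Map a scaled matrix back to original units
#' @param m a scaled [fog_matrix()].
#' @param s the scaler used; defaults to the matrix's own scaler state.
#' @return the unscaled [fog_matrix()].
#' @export
invert_scaler <- function(m, s = m$scaler_state) {
  stopifnot(inherits(m, "fog_matrix"))
  if (!inherits(s, "fog_scaler")) stop("'s' is not a fitted scaler")
  X <- sweep(sweep(m$X, 2L, s$scale, "*"), 2L, s$center, "+")
  fog_matrix(X, m$y, scaled = FALSE, scaler_state = NULL)
}

#' Write / read a labeled matrix as CSV
#'
#' Header-bearing CSV with columns `f1..f9,label`.
#'
#' @param m a [fog_matrix()].
#' @param path file path.
#' @return `path` (writer, invisibly) or a [fog_matrix()] (reader).
#' @export
write_fog_matrix <- function(m, path) {
  stopifnot(inherits(m, "fog_matrix"))
  d <- as.data.frame(m$X)
  names(d) <- paste0("f", seq_len(ncol(m$X)))
  d$label <- m$y
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fog_matrix
#' @export
read_fog_matrix <- function(path) {
  d <- utils::read.csv(path)
  if (!"label" %in% names(d)) stop("missing 'label' column")
  fog_matrix(as.matrix(d[setdiff(names(d), "label")]), d$label)
}

#' @export
print.fog_recording <- function(x, ...) {
  cat(sprintf("Sensor recording '%s': %d rows, annotations: %s\n",
              x$source_name, length(x$time),
              paste(names(table(x$annotation)), table(x$annotation),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
print.fog_dataset <- function(x, ...) {
  cat(sprintf("Recording collection: %d rows from %d source(s)\n",
              length(x$time), length(unique(x$source))))
  invisible(x)
}

#' @export
print.fog_matrix <- function(x, ...) {
  n1 <- sum(x$y == 1L)
  cat(sprintf("Labeled matrix: %d x %d (%s), freeze = %d, no-freeze = %d\n",
              nrow(x$X), ncol(x$X), if (x$scaled) "scaled" else "original units",
              sum(x$y == 0L), n1))
  invisible(x)
}
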