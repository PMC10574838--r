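test_that("reader parses the 11-field whitespace format with validation", {
  path <- write_daphnet_lines(c("0 10 980 -20 5 970 -10 0 990 0 1",
                                "15 12 975 -18 6 968 -9 1 991 2 2"))
  rec <- read_daphnet(path)
  expect_s3_class(rec, "fog_recording")
  expect_equal(n_rows(rec), 2L)
  expect_equal(rec$annotation, c(1L, 2L))
  expect_equal(rec$time, c(0, 15))
  expect_equal(rec$channels[2, 1], 12, ignore_attr = TRUE)
  expect_equal(rec$source_name, basename(path))

  # wrong token count names the offending line
  bad <- write_daphnet_lines(c("0 1 2 3 4 5 6 7 8 9 1",
                               "1 2 3 4 5 6 7 8 9 1"))
  expect_error(read_daphnet(bad), "line 2")
  # non-numeric token
  nn <- write_daphnet_lines("0 a 2 3 4 5 6 7 8 9 1")
  expect_error(read_daphnet(nn), "non-numeric")
  # annotation outside {0,1,2}
  ann <- write_daphnet_lines("0 1 2 3 4 5 6 7 8 9 7")
  expect_error(read_daphnet(ann), "annotation")
  # empty file is a valid zero-row recording
  empty <- write_daphnet_lines(character(0))
  expect_equal(n_rows(read_daphnet(empty)), 0L)
})

test_that("writer and reader round-trip a recording", {
  rec <- tiny_recording(c(1L, 2L, 0L, 1L))
  path <- tempfile(fileext = ".txt")
  write_daphnet(rec, path)
  back <- read_daphnet(path)
  expect_equal(back$annotation, rec$annotation)
  expect_equal(back$channels, rec$channels, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("combining recordings conserves rows and source tags", {
  r3 <- tiny_recording(rep(1L, 3), seed = 1)
  r4 <- tiny_recording(rep(2L, 4), seed = 2)
  r4$source_name <- "other"
  ds <- combine_recordings(list(r3, r4))
  expect_equal(n_rows(ds), 7L)
  expect_equal(ds$source, rep(c("tiny", "other"), c(3, 4)))

  one <- combine_recordings(list(r3))
  expect_equal(one$channels, r3$channels)
  expect_equal(one$annotation, r3$annotation)

  expect_error(combine_recordings(list()), "non-empty")

  # configured corpus size is honored exactly by the simulator
  ds1k <- make_fixture_dataset(2, 0.2, 1000L, seed = 5)
  expect_equal(n_rows(ds1k), 1000L)
})

test_that("preprocessing filters annotation 0 and relabels freeze to 0", {
  rec <- tiny_recording(c(0L, 1L, 2L, 1L, 0L))
  m <- preprocess(rec)
  expect_equal(n_rows(m), 3L)
  expect_equal(m$y, c(1L, 0L, 1L))
  # surviving rows keep their channel values
  expect_equal(m$X, rec$channels[c(2, 3, 4), ], ignore_attr = TRUE)

  expect_error(preprocess(tiny_recording(rep(0L, 4))), "annotation")
  all1 <- preprocess(tiny_recording(rep(1L, 5)))
  expect_equal(all1$y, rep(1L, 5))
})

test_that("preprocessing conserves rows and freeze fraction on random fixtures", {
  set.seed(11)
  for (i in 1:5) {
    ann <- sample(0:2, 200, replace = TRUE, prob = c(0.2, 0.6, 0.2))
    rec <- tiny_recording(as.integer(ann), seed = i)
    m <- preprocess(rec)
    expect_equal(n_rows(m), sum(ann != 0))
    expect_true(all(m$y %in% c(0L, 1L)))
    expect_equal(mean(m$y == 0L), sum(ann == 2) / sum(ann != 0))
  }
})

test_that("train/eval split reproduces the published 80/20 arithmetic", {
  # corpus-scale check on a single-column matrix to keep memory small
  big <- fog_matrix(matrix(0, 1140835L, 1L), rep(1L, 1140835L))
  parts <- split_train_eval(big, 0.8, seed = 1)
  expect_equal(n_rows(parts$train), 912668L)
  expect_equal(n_rows(parts$eval), 228167L)
})

test_that("split is a deterministic, disjoint, exhaustive partition", {
  m <- fog_matrix(matrix(seq_len(90), 10, 9), rep(c(0L, 1L), 5))
  a <- split_train_eval(m, 0.8, seed = 3)
  b <- split_train_eval(m, 0.8, seed = 3)
  expect_identical(a$train$X, b$train$X)
  expect_identical(a$eval$X, b$eval$X)
  expect_equal(n_rows(a$train), 8L)
  expect_equal(n_rows(a$eval), 2L)
  # partition: every original row appears exactly once (rows are unique here)
  all_rows <- rbind(a$train$X, a$eval$X)
  expect_equal(sort(all_rows[, 1]), seq_len(10))
  expect_error(split_train_eval(m, 1.2), "between 0 and 1")
})

test_that("scaler standardizes, round-trips, and handles constant features", {
  X <- cbind(c(1, 2, 3), c(5, 5, 5), c(-1, 0, 4))
  m <- fog_matrix(X, c(0L, 1L, 1L))
  s <- fit_scaler(m)
  sc <- apply_scaler(m, s)
  expect_equal(colMeans(sc$X), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(sc$X[, c(1, 3)], 2, sd), rep(1, 2), tolerance = 1e-12)
  # constant column maps to zeros and inverts exactly
  expect_equal(sc$X[, 2], rep(0, 3))
  back <- invert_scaler(sc)
  expect_equal(back$X, X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(apply_scaler(m, list()), "not a fitted scaler")
  expect_error(fit_scaler(sc), "unscaled")
})

test_that("scaler round-trip identity holds on random matrices", {
  set.seed(21)
  for (i in 1:5) {
    X <- matrix(rnorm(50 * 9, mean = rnorm(1, sd = 100), sd = runif(1, 0.1, 50)),
                50, 9)
    m <- fog_matrix(X, sample(0:1, 50, TRUE))
    s <- fit_scaler(m)
    expect_equal(invert_scaler(apply_scaler(m, s))$X, X,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("labeled-matrix CSV serialization round-trips", {
  m <- separable_matrix(20)
  path <- tempfile(fileext = ".csv")
  write_fog_matrix(m, path)
  header <- readLines(path, n = 1)
  expect_match(header, "^\"?f1\"?,.*\"?label\"?$")
  back <- read_fog_matrix(path)
  expect_equal(back$X, m$X, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$y, m$y)
})
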