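# Enumeration oracle for the window count formula.
count_windows <- function(n, len, inc) {
  k <- 0L; s <- 1L
  while (s + len - 1L <= n) { k <- k + 1L; s <- s + inc }
  k
}

test_that("window segmentation matches the enumeration oracle", {
  rec <- tiny_recording(duration_s = 1)
  ar <- synchronize(rec)
  win <- segment_windows(ar, window_config(256, 50))
  expect_equal(nrow(win), count_windows(2000L, 512L, 100L))
  expect_equal(nrow(win), 15L)
  expect_equal(win$end - win$start + 1L, rep(512L, 15L))
  # increment = length tiles without overlap
  win2 <- segment_windows(ar, window_config(100, 100))
  expect_equal(nrow(win2), floor(2000 / 200))
  expect_error(segment_windows(synchronize(tiny_recording(duration_s = 0.1)),
                               window_config(256, 50)),
               "shorter")
})

test_that("mixed windows take the majority label, ties to the window end", {
  rec <- tiny_recording(duration_s = 1)
  rec$labels <- c(rep(0L, 1200L), rep(1L, 800L))
  ar <- synchronize(rec)
  win <- segment_windows(ar, window_config(256, 50))
  # window starting at 901 covers 901..1412: 300 rest vs 212 active
  w <- which(win$start == 901L)
  expect_equal(win$label[w], 0L)
  w <- which(win$start == 1001L)  # 200 rest vs 312 active
  expect_equal(win$label[w], 1L)
})

test_that("time-domain EMG features match hand-computed values", {
  x <- c(1, -1, 1, -1, 1, -1, 1, -1)
  f <- emg_td_features(x, ar_order = 2L)
  expect_equal(unname(f["MAV"]), 1)
  expect_equal(unname(f["WL"]), 14)
  f2 <- emg_td_features(rep(3, 10))
  expect_equal(unname(f2["MAV"]), 3)
  expect_equal(unname(f2["WL"]), 0)
  expect_equal(unname(f2["LogVar"]), log(1e-12))
  expect_error(emg_td_features(c(1, 2, 3)), "too short")
  expect_error(emg_td_features(c(rnorm(10), NA)), "non-finite")
})

test_that("Burg AR agrees with stats::ar.burg and recovers planted models", {
  set.seed(5)
  x <- as.numeric(arima.sim(list(ar = c(0.4, -0.2, 0.1, 0.05)), 512))
  mine <- unname(emg_td_features(x)[3:6])
  ref <- ar.burg(x, aic = FALSE, order.max = 4L, demean = FALSE)$ar
  expect_equal(mine, ref, tolerance = 1e-10)
  # parameter recovery averaged over 100 seeded windows
  truth <- c(0.5, -0.3, 0.2, -0.1)
  set.seed(17)
  est <- replicate(100, {
    w <- as.numeric(arima.sim(list(ar = truth), 512))
    unname(emg_td_features(w)[3:6])
  })
  expect_lt(max(abs(rowMeans(est) - truth)), 0.1)
})

test_that("scaling homogeneity: MAV/WL scale, LogVar shifts, AR invariant", {
  set.seed(3)
  x <- rnorm(512)
  f1 <- emg_td_features(x)
  f2 <- emg_td_features(2.5 * x)
  expect_equal(unname(f2["MAV"]), unname(2.5 * f1["MAV"]))
  expect_equal(unname(f2["WL"]), unname(2.5 * f1["WL"]))
  expect_equal(unname(f2["LogVar"]), unname(f1["LogVar"] + 2 * log(2.5)))
  expect_equal(unname(f2[3:6]), unname(f1[3:6]), tolerance = 1e-10)
})

test_that("inertial means are exact for constants and ramps", {
  w <- matrix(0, 100, 9)
  w[, 1L] <- 7
  w[, 2L] <- seq(0, 99)          # ramp: mean is the midpoint
  f <- im_mean_features(w)
  expect_equal(unname(f[1L]), 7)
  expect_equal(unname(f[2L]), 49.5)
  expect_error(im_mean_features(w[0, ]), "empty")
})

test_that("feature matrix dimensionality follows the modality contract", {
  F <- small_features(seed = 2, n_sensors = 4L)
  expect_equal(ncol(F$X), 16L * 4L)
  expect_equal(nrow(F$columns), ncol(F$X))
  expect_false(anyDuplicated(F$columns) > 0)
  # per-sensor blocks contiguous
  expect_identical(F$columns$sensor, rep(1:4, each = 16L))
  Fe <- small_features(seed = 2, n_sensors = 4L, modality = "emg")
  expect_equal(ncol(Fe$X), 7L * 4L)
  Fi <- small_features(seed = 2, n_sensors = 4L, modality = "im")
  expect_equal(ncol(Fi$X), 9L * 4L)
  rec <- generate_recording(small_cfg(seed = 2, n_sensors = 4L))
  expect_error(build_feature_matrix(synchronize(rec), sensors = 9L),
               "subset")
})

test_that("standardizer uses training statistics only", {
  F <- small_features(seed = 3, n_sensors = 2L)
  train <- which(F$repetition <= 4L)
  S <- fit_standardizer(F, train)
  Fz <- apply_standardizer(S, F)
  expect_lt(max(abs(colMeans(Fz$X[train, ]))), 1e-10)
  expect_lt(max(abs(apply(Fz$X[train, ], 2L, sd) - 1)), 1e-10)
  # affine contract on test rows
  Fshift <- F
  Fshift$X <- F$X + 2
  Fz2 <- apply_standardizer(S, Fshift)
  expect_equal(Fz2$X, Fz$X + rep(2 / S$scale, each = nrow(F$X)),
               tolerance = 1e-12)
  # zero-variance column dropped with warning
  Fc <- F
  Fc$X[, 1L] <- 5
  expect_warning(S2 <- fit_standardizer(Fc, train), "zero-variance")
  expect_false(1L %in% S2$keep)
})

test_that("features are invariant to the recording start time", {
  rec <- generate_recording(small_cfg(seed = 21, n_sensors = 2L,
                                      n_classes = 2L, n_repetitions = 2L,
                                      f_im = 125))
  F1 <- build_feature_matrix(synchronize(rec))
  shift <- 400L  # four increments: same windows at an index offset
  rec2 <- rec
  rec2$emg <- rec$emg[-(1:shift), , drop = FALSE]
  rec2$labels <- rec$labels[-(1:shift)]
  rec2$im <- rec$im[-(1:(shift * rec$f_im / rec$f_emg)), , drop = FALSE]
  F2 <- build_feature_matrix(synchronize(rec2))
  k <- shift / 100L
  expect_equal(F2$X[1:20, 1:7], F1$X[(1 + k):(20 + k), 1:7],
               tolerance = 1e-10, ignore_attr = TRUE)
})
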