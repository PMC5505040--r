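#' Sliding-window configuration
#'
#' Defaults follow the real-time decoding cadence: 256 ms analysis windows
#' shifted by 50 ms (80% overlap), a standard compromise between
#' classification performance and controller delay.
#'
#' @param length_ms window length in ms (default 256).
#' @param increment_ms window shift in ms (default 50).
#' @return object of class `window_config`.
#' @export
window_config <- function(length_ms = 256, increment_ms = 50) {
  if (increment_ms <= 0 || increment_ms > length_ms)
    stop("require 0 < increment_ms <= length_ms", call. = FALSE)
  structure(list(length_ms = length_ms, increment_ms = increment_ms),
            class = "window_config")
}

#' Segment an aligned recording into analysis windows
#'
#' Window `k` (1-based) covers EMG samples
#' `[(k-1) * inc + 1, (k-1) * inc + len]` with
#' `len = length_ms * f_emg / 1000` and `inc = increment_ms * f_emg / 1000`,
#' giving `floor((n - len) / inc) + 1` windows. Each window's label is the
#' majority label among its samples, ties broken toward the label at the
#' window end. The repetition index of a non-rest window is the ordinal of
#' its enclosing segment within that class; rest windows inherit the
#' repetition of the preceding non-rest segment (leading rest inherits 1).
#'
#' @param ar an [synchronize()]d `aligned_recording`.
#' @param cfg a [window_config()].
#' @return data.frame with columns `start`, `end` (sample indices), `t`
#'   (window end time, seconds), `label`, `repetition`.
#' @export
segment_windows <- function(ar, cfg = window_config()) {
  n <- nrow(ar$emg)
  len <- round(cfg$length_ms * ar$f_emg / 1000)
  inc <- round(cfg$increment_ms * ar$f_emg / 1000)
  if (n < len)
    stop("recording shorter than one window", call. = FALSE)
  starts <- seq.int(1L, n - len + 1L, by = inc)
  ends <- starts + len - 1L
  segs <- label_segments(ar$labels)
  # repetition ordinal per segment: per-class counter for non-rest,
  # carried over to following rest segments
  rep_of_seg <- integer(nrow(segs))
  counter <- integer(max(segs$class) + 1L)
  current <- 1L
  for (k in seq_len(nrow(segs))) {
    if (segs$class[k] != 0L) {
      counter[segs$class[k] + 1L] <- counter[segs$class[k] + 1L] + 1L
      current <- counter[segs$class[k] + 1L]
    }
    rep_of_seg[k] <- current
  }
  # majority label per window: most windows lie inside one segment
  seg_of_start <- findInterval(starts, segs$first)
  seg_of_end <- findInterval(ends, segs$first)
  label <- segs$class[seg_of_start]
  repetition <- rep_of_seg[seg_of_end]
  straddle <- which(seg_of_start != seg_of_end)
  for (w in straddle) {
    ks <- seg_of_start[w]:seg_of_end[w]
    overlap <- pmin(segs$last[ks], ends[w]) - pmax(segs$first[ks], starts[w]) + 1L
    cls <- segs$class[ks]
    tot <- tapply(overlap, cls, sum)
    best <- names(tot)[tot == max(tot)]
    if (length(best) > 1L) {
      # tie: take the label at the window end
      label[w] <- ar$labels[ends[w]]
    } else label[w] <- as.integer(best)
  }
  data.frame(start = starts, end = ends, t = ends / ar$f_emg,
             label = as.integer(label), repetition = repetition)
}

# Burg-method AR coefficients, vectorised across the columns of a
# samples-by-windows matrix. Returns an order-by-windows matrix of
# forward-prediction coefficients a_j in x_t = sum_j a_j x_{t-j} + e_t.
burg_ar_matrix <- function(X, order = 4L) {
  n <- nrow(X); W <- ncol(X)
  f <- X; b <- X                # forward/backward prediction errors
  A <- matrix(0, order, W)      # current coefficient stack
  for (m in seq_len(order)) {
    rows_f <- (m + 1L):n        # f_{m-1}(t),   t = m+1..n
    rows_b <- m:(n - 1L)        # b_{m-1}(t-1), t = m+1..n
    fm <- f[rows_f, , drop = FALSE]
    bm <- b[rows_b, , drop = FALSE]
    num <- 2 * colSums(fm * bm)
    den <- colSums(fm^2) + colSums(bm^2)
    k <- ifelse(den > 0, num / den, 0)
    if (m > 1L) {
      prev <- A[1:(m - 1L), , drop = FALSE]
      A[1:(m - 1L), ] <- prev - rep(k, each = m - 1L) *
        prev[(m - 1L):1L, , drop = FALSE]
    }
    A[m, ] <- k
    f[rows_f, ] <- fm - rep(k, each = n - m) * bm
    b[rows_f, ] <- bm - rep(k, each = n - m) * fm
  }
  A
}

#' Time-domain EMG features of one analysis window
#'
#' Returns the seven per-channel time-domain features used for intent
#' decoding: mean absolute value (`MAV = mean(|x|)`), waveform length
#' (`WL = sum(|x_{i+1} - x_i|)`), the four coefficients of a 4th-order
#' autoregressive model `x_t = a_1 x_{t-1} + ... + a_4 x_{t-4} + e_t`
#' estimated by the Burg method, and the log-variance
#' (`LogVar = log(var(x))`, unbiased variance, floored at 1e-12 so a
#' constant window maps to `log(1e-12)`).
#'
#' @param window numeric vector of EMG samples, length >= `ar_order + 2`.
#' @param ar_order autoregressive model order (default 4).
#' @return named numeric vector `(MAV, WL, AR1..AR4, LogVar)`.
#' @export
emg_td_features <- function(window, ar_order = 4L) {
  if (!all(is.finite(window)))
    stop("window contains non-finite values", call. = FALSE)
  if (length(window) < ar_order + 2L)
    stop("window too short for AR order ", ar_order, call. = FALSE)
  a <- drop(burg_ar_matrix(matrix(window, ncol = 1L), ar_order))
  v <- max(stats::var(window), 1e-12)
  out <- c(mean(abs(window)), sum(abs(diff(window))), a, log(v))
  names(out) <- c("MAV", "WL", paste0("AR", seq_len(ar_order)), "LogVar")
  out
}

#' Window means of the nine inertial channels
#'
#' Inertial information enters the decoder as the per-channel arithmetic
#' mean (MV) over the analysis window, computed on the synchronised grid.
#'
#' @param window numeric matrix `[samples x 9]` of one sensor's inertial
#'   channels over one window.
#' @return numeric vector of 9 channel means.
#' @export
im_mean_features <- function(window) {
  window <- as.matrix(window)
  if (nrow(window) < 1L) stop("empty window", call. = FALSE)
  out <- colMeans(window)
  names(out) <- paste0("MV_", IM_AXES[seq_len(ncol(window))])
  out
}

#' Build the windows-by-features design matrix
#'
#' Extracts, for every analysis window and every requested sensor, the 7
#' time-domain EMG features and/or the 9 inertial window means, yielding
#' `7 |sensors|` (emg), `9 |sensors|` (im) or `16 |sensors|` (both)
#' columns. Per-sensor feature blocks are contiguous, EMG features first,
#' enabling grouped sensor selection. With the default 12 sensors and both
#' modalities the matrix has 192 columns.
#'
#' @param ar an `aligned_recording` from [synchronize()].
#' @param cfg a [window_config()].
#' @param modality `"both"`, `"emg"` or `"im"`.
#' @param sensors sensor indices to include (default all).
#' @param ar_order AR model order for the EMG features.
#' @return object of class `feature_matrix`: list with `X` (matrix),
#'   `y` (integer labels), `t` (window end times), `repetition`,
#'   `columns` (data.frame: sensor, modality, feature), `class_map`.
#' @export
build_feature_matrix <- function(ar, cfg = window_config(),
                                 modality = c("both", "emg", "im"),
                                 sensors = NULL, ar_order = 4L) {
  modality <- match.arg(modality)
  ns <- ar$layout$n_sensors
  if (is.null(sensors)) sensors <- seq_len(ns)
  sensors <- as.integer(sensors)
  if (!length(sensors) || !all(sensors %in% seq_len(ns)))
    stop("sensors must be a non-empty subset of 1..", ns, call. = FALSE)
  win <- segment_windows(ar, cfg)
  W <- nrow(win)
  len <- win$end[1L] - win$start[1L] + 1L
  emg_names <- c("MAV", "WL", paste0("AR", seq_len(ar_order)), "LogVar")
  im_names <- paste0("MV_", IM_AXES)
  per_sensor <- switch(modality, emg = length(emg_names),
                       im = length(im_names),
                       both = length(emg_names) + length(im_names))
  X <- matrix(0, W, per_sensor * length(sensors))
  cols <- data.frame(sensor = integer(0), modality = character(0),
                     feature = character(0))
  # index matrix: samples of all windows, built once, chunked over windows
  chunk <- max(1L, 2e6 %/% len)
  col0 <- 0L
  for (s in sensors) {
    if (modality %in% c("both", "emg")) {
      for (w0 in seq.int(1L, W, by = chunk)) {
        w1 <- min(w0 + chunk - 1L, W)
        idx <- outer(0:(len - 1L), win$start[w0:w1], `+`)
        M <- matrix(ar$emg[, s][idx], nrow = len)
        a <- burg_ar_matrix(M, ar_order)
        v <- pmax(colSums((M - rep(colMeans(M), each = len))^2) / (len - 1L),
                  1e-12)
        X[w0:w1, col0 + 1L] <- colMeans(abs(M))
        X[w0:w1, col0 + 2L] <- colSums(abs(M[-1L, , drop = FALSE] -
                                             M[-len, , drop = FALSE]))
        X[w0:w1, col0 + 2L + seq_len(ar_order)] <- t(a)
        X[w0:w1, col0 + 3L + ar_order] <- log(v)
      }
      cols <- rbind(cols, data.frame(sensor = s, modality = "emg",
                                     feature = emg_names))
      col0 <- col0 + length(emg_names)
    }
    if (modality %in% c("both", "im")) {
      base <- (s - 1L) * 9L
      cs <- apply(ar$im[, base + 1:9, drop = FALSE], 2L,
                  function(ch) cumsum(c(0, ch)))
      for (a9 in 1:9)
        X[, col0 + a9] <- (cs[win$end + 1L, a9] - cs[win$start, a9]) / len
      cols <- rbind(cols, data.frame(sensor = s, modality = "im",
                                     feature = im_names))
      col0 <- col0 + 9L
    }
  }
  colnames(X) <- sprintf("s%02d_%s", cols$sensor, cols$feature)
  structure(list(X = X, y = win$label, t = win$t,
                 repetition = win$repetition, columns = cols,
                 class_map = ar$class_map),
            class = "feature_matrix")
}

#' Fit a train-set standardizer
#'
#' Estimates per-column mean and standard deviation on the training rows
#' only, so that test rows are transformed with training statistics and no
#' information leaks across the cross-validation split. Columns with zero
#' training variance are dropped (with a warning) from both train and test.
#'
#' @param F a `feature_matrix`.
#' @param train_rows integer row indices of the training set.
#' @return object of class `standardizer`: `center`, `scale`, `keep`
#'   (retained column indices).
#' @export
fit_standardizer <- function(F, train_rows = seq_len(nrow(F$X))) {
  if (!length(train_rows)) stop("train_rows must be non-empty", call. = FALSE)
  Xt <- F$X[train_rows, , drop = FALSE]
  center <- colMeans(Xt)
  scale <- apply(Xt, 2L, stats::sd)
  keep <- which(scale > 0 & is.finite(scale))
  if (length(keep) < ncol(Xt))
    warning(sprintf("dropping %d zero-variance column(s)",
                    ncol(Xt) - length(keep)))
  if (!length(keep))
    stop("all columns have zero training variance", call. = FALSE)
  structure(list(center = center[keep], scale = scale[keep], keep = keep),
            class = "standardizer")
}

#' Apply a fitted standardizer to a feature matrix
#'
#' @param S a [fit_standardizer()] result.
#' @param F a `feature_matrix` with the same columns the standardizer was
#'   fitted on.
#' @return the transformed `feature_matrix` (columns restricted to the
#'   retained set).
#' @export
apply_standardizer <- function(S, F) {
  X <- F$X[, S$keep, drop = FALSE]
  F$X <- sweep(sweep(X, 2L, S$center, `-`), 2L, S$scale, `/`)
  F$columns <- F$columns[S$keep, , drop = FALSE]
  F
}
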