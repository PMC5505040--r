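#' Hampel filter configuration
#'
#' @param half_window half-width of the sliding window in samples
#'   (default 100, i.e. 50 ms at 2 kHz on either side).
#' @param n_sigmas MAD multiplier above which a sample counts as an
#'   outlier (default 3).
#' @return object of class `hampel_config`.
#' @export
hampel_config <- function(half_window = 100L, n_sigmas = 3) {
  half_window <- as.integer(half_window)
  if (is.na(half_window) || half_window < 1L)
    stop("half_window must be >= 1", call. = FALSE)
  if (n_sigmas <= 0) stop("n_sigmas must be > 0", call. = FALSE)
  structure(list(half_window = half_window, n_sigmas = n_sigmas),
            class = "hampel_config")
}

#' Sliding-window Hampel filter
#'
#' Suppresses impulsive interference (e.g. powerline transients) in a raw
#' EMG channel: each sample is replaced by its window median when its
#' absolute deviation from that median exceeds
#' `n_sigmas * 1.4826 * MAD` of the window. Signal length is preserved;
#' edge windows are truncated symmetrically. A window with MAD = 0 (flat
#' segment) never flags an outlier, so constant signals pass unchanged.
#'
#' @param signal numeric vector, length > `2 * half_window`.
#' @param cfg a [hampel_config()].
#' @return filtered numeric vector of the same length.
#' @export
hampel_filter <- function(signal, cfg = hampel_config()) {
  if (length(signal) <= 2L * cfg$half_window)
    stop("signal must be longer than 2 * half_window", call. = FALSE)
  if (anyNA(signal)) stop("signal contains NA", call. = FALSE)
  .hampel_cpp(as.numeric(signal), cfg$half_window, cfg$n_sigmas)
}

#' Synchronise inertial channels onto the EMG sample grid
#'
#' Linearly interpolates every inertial channel from its native grid
#' (`f_im`, 128 Hz by default) to the EMG grid (`f_emg`, 2 kHz), so both
#' modalities share exact window boundaries downstream. Outside the
#' inertial time span the nearest inertial sample is held constant (no
#' linear extrapolation). Optionally Hampel-filters the EMG channels
#' first; only EMG is ever filtered.
#'
#' @param rec a valid [recording()].
#' @param hampel `NULL` (no filtering) or a [hampel_config()].
#' @return object of class `aligned_recording`: `emg`, `im` (now on the
#'   EMG grid, one row per EMG sample), `labels`, `f_emg`, `layout`,
#'   `class_map`, `meta`.
#' @export
synchronize <- function(rec, hampel = NULL) {
  problems <- validate_recording(rec)
  if (length(problems))
    stop("invalid recording: ", paste(problems, collapse = "; "),
         call. = FALSE)
  if (nrow(rec$im) < 2L)
    stop("need at least 2 IM samples to interpolate", call. = FALSE)
  emg <- rec$emg
  if (!is.null(hampel))
    for (s in seq_len(ncol(emg)))
      emg[, s] <- hampel_filter(emg[, s], hampel)
  t_emg <- (seq_len(nrow(emg)) - 1L) / rec$f_emg
  t_im <- (seq_len(nrow(rec$im)) - 1L) / rec$f_im
  im_sync <- matrix(0, nrow(emg), ncol(rec$im))
  for (j in seq_len(ncol(rec$im)))
    im_sync[, j] <- stats::approx(t_im, rec$im[, j], xout = t_emg,
                                  method = "linear", rule = 2)$y
  structure(list(emg = emg, im = im_sync, labels = rec$labels,
                 f_emg = rec$f_emg, f_im = rec$f_im, layout = rec$layout,
                 class_map = rec$class_map, meta = rec$meta),
            class = "aligned_recording")
}

# Run-length segments of a label series: class, first sample, last sample.
label_segments <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(class = r$values,
             first = c(1L, head(ends, -1L) + 1L),
             last = ends)
}

#' Refine label onsets/offsets against the measured EMG power
#'
#' Protocol-driven labels lag or lead the true muscle activity because
#' subjects react to on-screen cues with variable delay. This refiner
#' moves each labelled onset and offset, within `+/- search_ms`, to the
#' point where the multi-channel smoothed EMG power (moving average of the
#' mean squared sample over `smooth_ms`) crosses the midpoint between the
#' neighbouring rest and active power levels. Segment order and count are
#' preserved; only boundary times move. Search windows that would overlap
#' an adjacent segment are clipped with a warning.
#'
#' @param rec a [recording()] whose labels contain non-rest segments.
#' @param search_ms half-width of the boundary search window (ms).
#' @param smooth_ms moving-average length for the power envelope (ms).
#' @return the recording with refined labels.
#' @export
refine_labels <- function(rec, search_ms = 500, smooth_ms = 50) {
  labels <- rec$labels
  segs <- label_segments(labels)
  act <- which(segs$class != 0L)
  if (!length(act)) stop("no non-rest segments to refine", call. = FALSE)
  n <- nrow(rec$emg)
  p <- rowMeans(rec$emg^2)
  w <- max(1L, round(smooth_ms / 1000 * rec$f_emg))
  cs <- cumsum(c(0, p))
  lo <- pmax(seq_len(n) - (w %/% 2L), 1L)
  hi <- pmin(lo + w - 1L, n)
  pw <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  half <- round(search_ms / 1000 * rec$f_emg)
  new_labels <- labels
  clipped <- FALSE
  for (i in seq_along(act)) {
    k <- act[i]
    seg_lo <- segs$first[k]; seg_hi <- segs$last[k]
    active_level <- stats::median(pw[seg_lo:seg_hi])
    rest_idx <- c(if (k > 1L) segs$first[k - 1L]:segs$last[k - 1L],
                  if (k < nrow(segs)) segs$first[k + 1L]:segs$last[k + 1L])
    rest_level <- stats::median(pw[rest_idx])
    thr <- (active_level + rest_level) / 2
    prev_act_end <- if (i > 1L) segs$last[act[i - 1L]] else 0L
    next_act_start <- if (i < length(act)) segs$first[act[i + 1L]] else n + 1L
    # onset: first power crossing above thr inside the clipped search window
    on_lo <- max(seg_lo - half, prev_act_end + 1L, 1L)
    on_hi <- min(seg_lo + half, seg_hi)
    if (on_lo > seg_lo - half) clipped <- clipped || (seg_lo - half >= 1L)
    above <- which(pw[on_lo:on_hi] > thr)
    new_on <- if (length(above)) on_lo + above[1L] - 1L else seg_lo
    # offset: last power crossing above thr inside the clipped search window
    off_lo <- max(seg_hi - half, new_on)
    off_hi <- min(seg_hi + half, next_act_start - 1L, n)
    if (off_hi < seg_hi + half && seg_hi + half <= n) clipped <- TRUE
    above <- which(pw[off_lo:off_hi] > thr)
    new_off <- if (length(above)) off_lo + above[length(above)] - 1L else seg_hi
    new_labels[seg_lo:seg_hi] <- 0L
    new_labels[new_on:new_off] <- segs$class[k]
  }
  if (clipped)
    warning("one or more search windows clipped at adjacent segments")
  rec$labels <- new_labels
  rec
}
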