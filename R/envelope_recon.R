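#' Reconstruct an sEMG envelope from three inertial channels
#'
#' Ordinary least squares with intercept regressing the window-level EMG
#' envelope (the MAV series) on the window means of one inertial modality
#' (3 axes of the same sensor's accelerometer, gyroscope or magnetometer).
#' Scored by variance accounted for,
#' `VAF = 1 - var(envelope - prediction) / var(envelope)`, reported both
#' in-sample and on held-out folds (repetition-wise by default when a
#' repetition vector is supplied, contiguous blocks otherwise). Held-out
#' VAF is the headline number and may be negative.
#'
#' @param im_feats numeric matrix `[n x 3]` of inertial window means.
#' @param envelope numeric MAV series of length `n` on the same window
#'   grid.
#' @param folds optional integer fold id per window; `NULL` assigns `k`
#'   contiguous blocks.
#' @param k number of cross-validation folds (default 6).
#' @return object of class `reconstruction_result`: `coefficients`
#'   (intercept + 3 weights), `vaf_train`, `vaf_cv`.
#' @export
fit_reconstruction <- function(im_feats, envelope, folds = NULL, k = 6L) {
  Z <- as.matrix(im_feats)
  n <- length(envelope)
  if (nrow(Z) != n) stop("series must share the window grid", call. = FALSE)
  if (n <= 4L) stop("need more than 4 windows", call. = FALSE)
  if (stats::var(envelope) == 0)
    stop("constant envelope: VAF undefined", call. = FALSE)
  if (is.null(folds) || length(unique(folds)) < 2L)
    folds <- as.integer(cut(seq_len(n), breaks = k, labels = FALSE))
  X <- cbind(1, Z)
  beta <- qr.solve(X, envelope)
  vaf_train <- 1 - stats::var(envelope - X %*% beta) / stats::var(envelope)
  resid_cv <- numeric(n)
  for (j in unique(folds)) {
    te <- folds == j
    bj <- qr.solve(X[!te, , drop = FALSE], envelope[!te])
    resid_cv[te] <- envelope[te] - X[te, , drop = FALSE] %*% bj
  }
  vaf_cv <- 1 - stats::var(resid_cv) / stats::var(envelope)
  structure(list(coefficients = drop(beta), vaf_train = drop(vaf_train),
                 vaf_cv = vaf_cv),
            class = "reconstruction_result")
}

#' Per-sensor, per-modality envelope reconstruction survey
#'
#' For every sensor and each inertial modality (accelerometer, gyroscope,
#' magnetometer) fits [fit_reconstruction()] from that modality's three
#' axes to the same sensor's EMG MAV series, pooling windows across all
#' movements. A 12-sensor recording yields 36 results.
#'
#' @param rec a [recording()].
#' @param wc a [window_config()].
#' @param k cross-validation folds.
#' @return data.frame: `sensor`, `modality` (`acc`/`gyro`/`mag`),
#'   `vaf_train`, `vaf_cv`.
#' @export
reconstruction_suite <- function(rec, wc = window_config(), k = 6L) {
  ar <- synchronize(rec)
  F <- build_feature_matrix(ar, wc, modality = "both")
  folds <- ((F$repetition - 1L) %% k) + 1L
  mods <- c(acc = "MV_ax", gyro = "MV_gx", mag = "MV_mx")
  axes <- list(acc = c("MV_ax", "MV_ay", "MV_az"),
               gyro = c("MV_gx", "MV_gy", "MV_gz"),
               mag = c("MV_mx", "MV_my", "MV_mz"))
  out <- list()
  for (s in seq_len(ar$layout$n_sensors)) {
    env <- F$X[, F$columns$sensor == s & F$columns$feature == "MAV"]
    for (m in names(axes)) {
      cols <- which(F$columns$sensor == s & F$columns$feature %in% axes[[m]])
      fit <- fit_reconstruction(F$X[, cols, drop = FALSE], env,
                                folds = folds)
      out[[length(out) + 1L]] <- data.frame(sensor = s, modality = m,
                                            vaf_train = fit$vaf_train,
                                            vaf_cv = fit$vaf_cv)
    }
  }
  do.call(rbind, out)
}
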