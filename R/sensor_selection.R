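#' Sensor-selection configuration
#'
#' @param gain_threshold marginal cross-validated CA gain (percentage
#'   points) a sensor must contribute to stay in the selected subset
#'   (default 1.0).
#' @param cv a [cv_config()] used inside the search (default 3-fold,
#'   matching selection on training data with few repetitions).
#' @param shrinkage LDA diagonal shrinkage.
#' @param balance balance the rest class when scoring candidates.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(gain_threshold = 1.0, cv = cv_config(3L),
                             shrinkage = 1e-3, balance = TRUE) {
  if (gain_threshold < 0) stop("gain_threshold must be >= 0", call. = FALSE)
  structure(list(gain_threshold = gain_threshold, cv = cv,
                 shrinkage = shrinkage, balance = balance),
            class = "selection_config")
}

# Per-fold CA for a column subset of F, reusing precomputed fold splits.
fold_cas_for_columns <- function(F, cols, folds, shrinkage, balance) {
  vapply(folds, function(fd) {
    Fs <- F
    Fs$X <- F$X[, cols, drop = FALSE]
    Fs$columns <- F$columns[cols, , drop = FALSE]
    S <- fit_standardizer(Fs, fd$train)
    Fz <- suppressWarnings(apply_standardizer(S, Fs))
    model <- fit_lda(Fz$X[fd$train, , drop = FALSE], F$y[fd$train],
                     shrinkage)
    te <- if (balance) balance_rest(F, fd$test) else fd$test
    P <- predict_posterior(model, Fz$X[te, , drop = FALSE])
    pred <- model$classes[max.col(P, ties.method = "first")]
    classification_accuracy(pred, F$y[te])
  }, numeric(1))
}

#' Sequential forward sensor selection (grouped greedy search)
#'
#' Adapted sequential forward selection operating on whole sensors rather
#' than individual features: a candidate sensor contributes its full
#' feature block (16 columns for both modalities, 7 EMG-only, 9 IM-only).
#' Starting from the empty set, every remaining sensor is scored by
#' per-fold cross-validated classification accuracy after adding its
#' block; each fold votes for its best candidate and the sensor with most
#' votes is added (vote ties broken by higher mean CA across folds, then
#' lower sensor index). The search continues until all sensors are
#' ranked. Deterministic given the feature matrix and configuration.
#'
#' @param F a `feature_matrix` with grouped per-sensor column blocks and
#'   at least 2 sensors.
#' @param cfg a [selection_config()].
#' @return object of class `selection_result`: `ranking` (sensor
#'   permutation), `ca_curve` (mean CV accuracy after each addition),
#'   `per_step_votes` (list of named vote tallies), `subset` (prefix
#'   passing the gain threshold, see [select_subset()]).
#' @export
sfss_rank <- function(F, cfg = selection_config()) {
  sensors <- sort(unique(F$columns$sensor))
  if (length(sensors) < 2L)
    stop("need >= 2 sensors to rank", call. = FALSE)
  folds <- repetition_folds(F, cfg$cv)
  ranking <- integer(0)
  ca_curve <- numeric(0)
  votes_log <- list()
  remaining <- sensors
  sel_cols <- integer(0)
  while (length(remaining)) {
    cand_ca <- matrix(NA_real_, length(folds), length(remaining),
                      dimnames = list(NULL, remaining))
    for (ci in seq_along(remaining)) {
      cols <- c(sel_cols, which(F$columns$sensor == remaining[ci]))
      cand_ca[, ci] <- fold_cas_for_columns(F, cols, folds,
                                            cfg$shrinkage, cfg$balance)
    }
    # each fold votes for its best candidate (fold ties -> lower index)
    fold_best <- max.col(cand_ca, ties.method = "first")
    tally <- tabulate(fold_best, nbins = length(remaining))
    names(tally) <- remaining
    top <- which(tally == max(tally))
    if (length(top) > 1L) {
      mean_ca <- colMeans(cand_ca)[top]
      top <- top[mean_ca == max(mean_ca)]
      top <- top[which.min(remaining[top])]
    }
    winner <- remaining[top[1L]]
    ranking <- c(ranking, winner)
    ca_curve <- c(ca_curve, mean(cand_ca[, as.character(winner)]))
    votes_log[[length(votes_log) + 1L]] <- tally
    sel_cols <- c(sel_cols, which(F$columns$sensor == winner))
    remaining <- setdiff(remaining, winner)
  }
  res <- structure(list(ranking = ranking, ca_curve = ca_curve,
                        per_step_votes = votes_log, subset = NULL),
                   class = "selection_result")
  res$subset <- select_subset(res, cfg)
  res
}

#' Threshold the ranked sensors into a working subset
#'
#' Applies the marginal-gain stopping rule to a completed ranking: walk
#' down the accuracy curve and stop at the first sensor whose addition
#' improves mean CA by no more than `gain_threshold` percentage points.
#' The first-ranked sensor is always included, so the subset is a
#' non-empty prefix of the ranking.
#'
#' @param r a [sfss_rank()] result.
#' @param cfg a [selection_config()].
#' @return integer vector of selected sensor indices (prefix of
#'   `r$ranking`).
#' @export
select_subset <- function(r, cfg = selection_config()) {
  gains <- diff(c(0, r$ca_curve))
  size <- 1L
  for (i in seq_along(gains)[-1L]) {
    if (gains[i] > cfg$gain_threshold) size <- i else break
  }
  r$ranking[seq_len(size)]
}
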