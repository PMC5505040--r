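#' Repetition-wise cross-validation configuration
#'
#' The split unit is the movement repetition: with the default six
#' repetitions per class, five train the decoder and the left-out
#' repetition is scored, rotating over folds (6-fold CV).
#'
#' @param k number of folds (default 6).
#' @return object of class `cv_config`.
#' @export
cv_config <- function(k = 6L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be >= 2", call. = FALSE)
  structure(list(k = k, split_unit = "repetition"), class = "cv_config")
}

#' Repetition-wise fold assignment
#'
#' Fold `j`'s test set is every window whose repetition index maps to `j`
#' (rest windows inherit the repetition of the neighbouring movement
#' segment, so they follow their repetition into the fold). Repetition `r`
#' maps to fold `((r - 1) mod k) + 1`, which keeps the partition exhaustive
#' when more than `k` repetitions are present. Every non-rest class must
#' have at least `k` repetitions.
#'
#' @param F a `feature_matrix`.
#' @param cfg a [cv_config()].
#' @return list of `k` lists with integer `train` / `test` row indices.
#' @export
repetition_folds <- function(F, cfg = cv_config()) {
  k <- cfg$k
  for (cl in setdiff(sort(unique(F$y)), 0L)) {
    n_rep <- length(unique(F$repetition[F$y == cl]))
    if (n_rep < k)
      stop(sprintf("class %d has %d repetitions, need >= %d folds",
                   cl, n_rep, k), call. = FALSE)
  }
  fold <- ((F$repetition - 1L) %% k) + 1L
  lapply(seq_len(k), function(j)
    list(train = which(fold != j), test = which(fold == j)))
}

#' Balance the rest class in a test fold
#'
#' The rest class dominates the window counts and would bias accuracy, so
#' test folds are balanced by removing most rest windows. Rest windows are
#' ranked by temporal distance to the nearest muscle-activity window; the
#' nearest (hardest) windows are retained until the rest count equals the
#' rounded mean per-class count of the non-rest classes. Non-rest rows are
#' never removed, retained rows keep their original order, and distance
#' ties are broken toward the earlier window, so the procedure is fully
#' deterministic.
#'
#' @param F a `feature_matrix`.
#' @param rows integer row indices of the fold to balance (default all).
#' @return integer subset of `rows` to retain, in original order.
#' @export
balance_rest <- function(F, rows = seq_along(F$y)) {
  y <- F$y[rows]; t <- F$t[rows]
  rest <- which(y == 0L)
  if (!length(rest)) {
    warning("no rest rows to balance; returning input unchanged")
    return(rows)
  }
  active <- which(y != 0L)
  if (!length(active))
    stop("balance_rest needs at least one non-rest row", call. = FALSE)
  target <- round(mean(tabulate(match(y[active], sort(unique(y[active]))))))
  if (length(rest) <= target) return(rows)
  dist <- vapply(t[rest], function(tr) min(abs(tr - t[active])), numeric(1))
  ord <- order(dist, rest)              # ties -> earlier window
  keep_rest <- sort(rest[ord[seq_len(target)]])
  rows[sort(c(active, keep_rest))]
}

#' Classification accuracy (percent)
#'
#' `CA = 100 * correctly classified / total classified`.
#'
#' @param pred,true equal-length class vectors.
#' @return accuracy in percent.
#' @export
classification_accuracy <- function(pred, true) {
  if (!length(pred) || length(pred) != length(true))
    stop("pred and true must be non-empty and of equal length",
         call. = FALSE)
  100 * mean(pred == true)
}

#' Row-normalized confusion matrix
#'
#' Entry `(i, j)` is the fraction of true-class-`i` windows predicted as
#' class `j`; rows for classes with no true instances are all zero.
#'
#' @param pred,true class vectors.
#' @param class_map named class map (names are class ids) fixing row/column
#'   order.
#' @return `C x C` matrix with class names on both dimensions.
#' @export
confusion <- function(pred, true, class_map) {
  ids <- as.integer(names(class_map))
  bad <- setdiff(unique(c(pred, true)), ids)
  if (length(bad))
    stop("label(s) outside class_map: ", paste(bad, collapse = ","),
         call. = FALSE)
  M <- table(factor(true, levels = ids), factor(pred, levels = ids))
  M <- unclass(M) + 0
  rs <- rowSums(M)
  M[rs > 0, ] <- M[rs > 0, , drop = FALSE] / rs[rs > 0]
  dimnames(M) <- list(true = unname(class_map), pred = unname(class_map))
  M
}

#' Repetition-wise cross-validated decoding evaluation
#'
#' For each fold: fit the standardizer and LDA on the training rows only,
#' balance the test fold's rest class (optional), and score classification
#' accuracy; the confusion matrix is pooled (counts accumulated) across
#' folds and then row-normalized.
#'
#' @param F a `feature_matrix`.
#' @param cv a [cv_config()].
#' @param shrinkage LDA diagonal shrinkage.
#' @param balance logical: balance the rest class in test folds.
#' @return object of class `eval_result`: `fold_ca` (per-fold CA %),
#'   `confusion`, `retained` (per-fold scored-window counts).
#' @export
crossval_evaluate <- function(F, cv = cv_config(), shrinkage = 1e-3,
                              balance = TRUE) {
  folds <- repetition_folds(F, cv)
  ids <- as.integer(names(F$class_map))
  counts <- matrix(0, length(ids), length(ids))
  fold_ca <- numeric(length(folds))
  retained <- integer(length(folds))
  for (j in seq_along(folds)) {
    tr <- folds[[j]]$train; te <- folds[[j]]$test
    S <- fit_standardizer(F, tr)
    Fz <- apply_standardizer(S, F)
    model <- fit_lda(Fz$X[tr, , drop = FALSE], F$y[tr], shrinkage)
    if (balance) te <- balance_rest(F, te)
    retained[j] <- length(te)
    P <- predict_posterior(model, Fz$X[te, , drop = FALSE])
    pred <- model$classes[max.col(P, ties.method = "first")]
    fold_ca[j] <- classification_accuracy(pred, F$y[te])
    counts <- counts + table(factor(F$y[te], levels = ids),
                             factor(pred, levels = ids))
  }
  rs <- rowSums(counts)
  conf <- unclass(counts) + 0
  conf[rs > 0, ] <- conf[rs > 0, , drop = FALSE] / rs[rs > 0]
  dimnames(conf) <- list(true = unname(F$class_map),
                         pred = unname(F$class_map))
  structure(list(fold_ca = fold_ca, confusion = conf, retained = retained),
            class = "eval_result")
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values numeric sample (length >= 2).
#' @param n_boot bootstrap iterations (default 100).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed for reproducibility.
#' @return named vector `c(low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 100L, level = 0.95, seed = 1L) {
  if (length(values) < 2L) stop("need >= 2 values", call. = FALSE)
  set.seed(seed)
  means <- vapply(seq_len(n_boot), function(i)
    mean(sample(values, replace = TRUE)), numeric(1))
  ci <- unname(stats::quantile(means, c((1 - level) / 2, (1 + level) / 2)))
  c(low = ci[1L], high = ci[2L])
}
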