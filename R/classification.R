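#' Confidence-rejection configuration
#'
#' @param theta posterior-probability threshold above which a prediction
#'   is emitted (default 0.995, the a-priori value used for real-time
#'   control).
#' @return object of class `rejection_config`.
#' @export
rejection_config <- function(theta = 0.995) {
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]", call. = FALSE)
  structure(list(theta = theta), class = "rejection_config")
}

#' Sentinel for a rejected (low-confidence) prediction
#' @export
NO_DECISION <- NA_integer_

#' Fit a shared-covariance Gaussian (LDA) classifier
#'
#' Class-conditional Gaussian model with a covariance matrix shared across
#' classes, yielding linear decision boundaries and calibrated class
#' posteriors. The pooled within-class covariance is shrunk towards its
#' diagonal as `(1 - lambda) * Sigma + lambda * diag(Sigma)`; the small
#' default keeps the estimate well-conditioned at the full 192-column
#' dimensionality with desk-scale training sets. Priors are the empirical
#' class frequencies.
#'
#' @param X numeric design matrix (rows standardized features).
#' @param y integer class per row (>= 2 distinct classes, each with >= 2
#'   rows).
#' @param shrinkage diagonal shrinkage weight `lambda` in \[0, 1\].
#' @return object of class `lda_model`: `classes`, `means` (C x d),
#'   `covariance`, `chol` (upper Cholesky factor), `priors`, `shrinkage`,
#'   `columns` (colnames of X).
#' @export
fit_lda <- function(X, y, shrinkage = 1e-3) {
  X <- as.matrix(X); y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X rows must match y length", call. = FALSE)
  if (shrinkage < 0 || shrinkage > 1)
    stop("shrinkage must be in [0, 1]", call. = FALSE)
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("need at least 2 classes", call. = FALSE)
  counts <- tabulate(match(y, classes))
  if (any(counts < 2L))
    stop("every class needs >= 2 rows (violated by class ",
         classes[which(counts < 2L)[1L]], ")", call. = FALSE)
  d <- ncol(X); C <- length(classes)
  means <- matrix(0, C, d)
  S <- matrix(0, d, d)
  for (i in seq_len(C)) {
    Xi <- X[y == classes[i], , drop = FALSE]
    means[i, ] <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, means[i, ])
    S <- S + crossprod(Xc)
  }
  S <- S / (nrow(X) - C)
  S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), d)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R))
    stop("pooled covariance is singular; use shrinkage > 0", call. = FALSE)
  structure(list(classes = classes, means = means, covariance = S,
                 chol = R, priors = counts / sum(counts),
                 shrinkage = shrinkage, columns = colnames(X)),
            class = "lda_model")
}

#' Posterior class probabilities under the shared-covariance model
#'
#' Computes `p(c | x) ~ prior_c * N(x; mean_c, Sigma)` normalized over
#' classes. All densities are evaluated in the log domain through the
#' Cholesky factor of the shared covariance, so posteriors neither
#' overflow nor underflow for standardized features.
#'
#' @param m an [fit_lda()] model.
#' @param x feature vector of length `d`, or matrix `[n x d]`.
#' @return probability vector of length `C` (or `[n x C]` matrix), columns
#'   named by class id.
#' @export
predict_posterior <- function(m, x) {
  single <- is.null(dim(x))
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != ncol(m$means))
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(X), ncol(m$means)), call. = FALSE)
  C <- length(m$classes)
  logp <- matrix(0, nrow(X), C)
  for (i in seq_len(C)) {
    Z <- backsolve(m$chol, t(sweep(X, 2L, m$means[i, ])), transpose = TRUE)
    logp[, i] <- log(m$priors[i]) - 0.5 * colSums(Z^2)
  }
  logp <- logp - apply(logp, 1L, max)
  P <- exp(logp)
  P <- P / rowSums(P)
  colnames(P) <- as.character(m$classes)
  if (single) P[1L, ] else P
}

#' Predict with confidence-based rejection
#'
#' Emits the maximum-a-posteriori class only when its posterior exceeds
#' the rejection threshold `theta`; otherwise returns [NO_DECISION]
#' (`NA`), which the controller treats as "hold current state". Posterior
#' ties are broken toward the lower class id (a measure-zero event for
#' continuous features).
#'
#' @param m an [fit_lda()] model.
#' @param x feature vector or matrix as in [predict_posterior()].
#' @param rc a [rejection_config()].
#' @return integer class id(s); `NA` where rejected.
#' @export
predict_with_rejection <- function(m, x, rc = rejection_config()) {
  P <- predict_posterior(m, x)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  best <- max.col(P, ties.method = "first")
  out <- m$classes[best]
  out[P[cbind(seq_len(nrow(P)), best)] <= rc$theta] <- NO_DECISION
  if (length(out) == 1L) out[[1L]] else out
}
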