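# Brute-force posterior oracle: unnormalized Gaussian densities computed
# through solve() and explicit determinants, no Cholesky sharing with the
# implementation path.
oracle_posterior <- function(means, Sigma, priors, x) {
  C <- nrow(means)
  dens <- vapply(seq_len(C), function(i) {
    d <- x - means[i, ]
    priors[i] * exp(-0.5 * drop(t(d) %*% solve(Sigma) %*% d)) /
      sqrt(det(2 * pi * Sigma))
  }, numeric(1))
  dens / sum(dens)
}

random_lda_problem <- function(d = 5L, C = 3L, n_per = 40L) {
  means <- matrix(rnorm(C * d, sd = 2), C, d)
  A <- matrix(rnorm(d * d), d)
  Sigma <- crossprod(A) / d + diag(d)
  X <- do.call(rbind, lapply(seq_len(C), function(i)
    means[rep(i, n_per), ] + matrix(rnorm(n_per * d), n_per) %*% chol(Sigma)))
  list(X = X, y = rep(seq_len(C), each = n_per))
}

test_that("two symmetric 1-D classes split at the midpoint", {
  X <- matrix(c(rnorm(50, -1, 0.5), rnorm(50, 1, 0.5)), ncol = 1)
  m <- fit_lda(X, rep(1:2, each = 50), shrinkage = 0)
  p_lo <- predict_posterior(m, mean(m$means) - 0.5)
  p_hi <- predict_posterior(m, mean(m$means) + 0.5)
  expect_gt(p_lo[1L], 0.5)
  expect_gt(p_hi[2L], 0.5)
  p_mid <- predict_posterior(m, mean(m$means))
  expect_equal(unname(p_mid), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("fit_lda recovers generator parameters at n = 1e4", {
  set.seed(23)
  d <- 4L
  mu <- rbind(rep(0, d), rep(1, d))
  A <- diag(d) + 0.3
  Sigma <- crossprod(A) / d
  n <- 5000L
  X <- rbind(matrix(rnorm(n * d), n) %*% chol(Sigma),
             matrix(rnorm(n * d), n) %*% chol(Sigma) + 1)
  m <- fit_lda(X, rep(1:2, each = n), shrinkage = 0)
  expect_equal(m$means, mu, tolerance = 0.05, ignore_attr = TRUE)
  expect_equal(m$covariance, Sigma, tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(m$priors, c(0.5, 0.5))
})

test_that("fit_lda validates its inputs", {
  X <- matrix(rnorm(20), 10)
  expect_error(fit_lda(X, rep(1L, 10)), "at least 2 classes")
  expect_error(fit_lda(X, c(1L, rep(2L, 9))), ">= 2 rows")
  # collinear columns are singular without shrinkage
  Xs <- cbind(rnorm(20), 0)
  Xs <- cbind(Xs, Xs[, 1])
  expect_error(fit_lda(Xs, rep(1:2, each = 10), shrinkage = 0),
               "shrinkage")
})

test_that("posteriors agree with the density-ratio oracle to 1e-8", {
  set.seed(77)
  for (i in 1:100) {
    prob <- random_lda_problem()
    m <- fit_lda(prob$X, prob$y, shrinkage = 1e-3)
    x <- rnorm(5, sd = 2)
    expect_equal(unname(predict_posterior(m, x)),
                 oracle_posterior(m$means, m$covariance, m$priors, x),
                 tolerance = 1e-8)
  }
})

test_that("posteriors are normalized and never under/overflow", {
  set.seed(12)
  prob <- random_lda_problem(d = 8L)
  m <- fit_lda(prob$X, prob$y)
  X <- matrix(rnorm(200 * 8, sd = 30), 200)   # far-out queries
  P <- predict_posterior(m, X)
  expect_true(all(is.finite(P)))
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
})

test_that("full diagonal shrinkage reduces to shared-variance naive Bayes", {
  set.seed(9)
  prob <- random_lda_problem(d = 4L)
  m <- fit_lda(prob$X, prob$y, shrinkage = 1)
  x <- rnorm(4)
  v <- diag(m$covariance)
  logd <- vapply(1:3, function(i)
    log(m$priors[i]) + sum(dnorm(x, m$means[i, ], sqrt(v), log = TRUE)),
    numeric(1))
  expect_equal(unname(predict_posterior(m, x)),
               unname(exp(logd) / sum(exp(logd))), tolerance = 1e-10)
})

test_that("rejection is monotone in theta and breaks ties as documented", {
  set.seed(41)
  prob <- random_lda_problem()
  m <- fit_lda(prob$X, prob$y)
  X <- prob$X + rnorm(length(prob$X), sd = 0.5)
  thetas <- c(0.5, 0.9, 0.995, 1)
  emitted <- vapply(thetas, function(th)
    sum(!is.na(predict_with_rejection(m, X, rejection_config(th)))),
    numeric(1))
  expect_true(all(diff(emitted) <= 0))
  expect_equal(emitted[length(thetas)], 0)  # theta = 1: strict inequality
  p <- predict_posterior(m, X[1, ])
  expect_identical(predict_with_rejection(m, X[1, ], rejection_config(0.1)),
                   m$classes[which.max(p)])
})

test_that("accuracy saturates with separation and collapses under permutation", {
  set.seed(3)
  d <- 3L
  X <- rbind(matrix(rnorm(300 * d), 300),
             matrix(rnorm(300 * d), 300) + 50)
  y <- rep(1:2, each = 300)
  m <- fit_lda(X, y)
  pred <- predict_with_rejection(m, X, rejection_config(0.5))
  expect_equal(classification_accuracy(pred, y), 100)
  yp <- sample(y)
  mp <- fit_lda(X, yp)
  predp <- m$classes[max.col(predict_posterior(mp, X))]
  expect_lt(abs(classification_accuracy(predp, yp) - 50), 7)
})
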