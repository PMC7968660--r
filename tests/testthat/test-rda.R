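# Redundancy analysis and Monte Carlo permutation test.

test_that("a noiseless linear response loads 100% on axis 1", {
  set.seed(1)
  x <- rnorm(12)
  coefs <- runif(5, -2, 2)
  Y <- outer(x, coefs)
  fit <- rda_fit(Y, cbind(x = x), transform = "none")
  expect_lt(abs(fit$pct_total[1] - 100) / 100, 1e-9)
  expect_equal(fit$trace, fit$total, tolerance = 1e-9)
})

test_that("covariates orthogonal to the community explain ~nothing", {
  set.seed(2)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(10 * 6), 10, 6))))[, -1]
  Y <- Q[, 1:3] %*% matrix(rnorm(9), 3, 3)
  X <- Q[, 5:6]
  colnames(X) <- c("u", "v")
  # vegan warns while scoring the all-but-zero constrained axes
  fit <- suppressWarnings(rda_fit(Y, X, transform = "none"))
  expect_lt(fit$trace / fit$total, 1e-12)
})

test_that("constrained trace matches an explicit hat-matrix projection", {
  set.seed(3)
  for (k in 1:20) {
    n <- sample(8:15, 1)
    Y <- matrix(rnorm(n * 5), n, 5)
    X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
    fit <- rda_fit(Y, X, transform = "none")
    Yc <- scale(Y, scale = FALSE)
    Xs <- scale(X)
    H <- Xs %*% solve(crossprod(Xs)) %*% t(Xs)
    trace_oracle <- sum((H %*% Yc)^2) / (n - 1)
    expect_equal(fit$trace, trace_oracle, tolerance = 1e-10)
    # axis percents: non-increasing eigenvalues, parts sum to the whole
    expect_true(all(diff(fit$eig) <= 1e-12))
    expect_equal(sum(fit$pct_total) + fit$pct_unconstrained, 100,
                 tolerance = 1e-9)
    expect_equal(sum(fit$pct_constrained), 100, tolerance = 1e-9)
  }
})

test_that("axis percents are invariant to rescaling a covariate", {
  set.seed(4)
  Y <- matrix(rpois(60, 20), 12, 5)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("a", "b")))
  f1 <- rda_fit(Y, X)
  X2 <- X; X2[, 1] <- X2[, 1] * 1000
  f2 <- rda_fit(Y, X2)
  expect_equal(f1$pct_total, f2$pct_total, tolerance = 1e-9)
})

test_that("rank-deficient covariates are rejected by name", {
  set.seed(5)
  Y <- matrix(rnorm(40), 10, 4)
  X <- cbind(a = rnorm(10), b = 0)
  X <- cbind(X, c = X[, "a"] * 2)
  expect_error(rda_fit(Y, X, transform = "none"), "b")
  expect_error(rda_fit(Y, X[, c("a", "c")], transform = "none"), "collinear")
})

test_that("permutation p hits the add-one floor on a strong planted signal", {
  set.seed(6)
  x <- rnorm(20)
  Y <- outer(x, runif(6, 1, 2)) + matrix(rnorm(120, sd = 0.01), 20, 6)
  mc <- monte_carlo_test(Y, cbind(x = x), n_perm = 999, seed = 10,
                         transform = "none")
  expect_equal(mc$p_value, 1 / 1000)
  expect_error(monte_carlo_test(Y, cbind(x = x), n_perm = 98), "99")
  expect_error(monte_carlo_test(matrix(1, 20, 3), cbind(x = x), n_perm = 99),
               "constant")
  # deterministic given seed
  mc2 <- monte_carlo_test(Y, cbind(x = x), n_perm = 999, seed = 10,
                          transform = "none")
  expect_identical(mc$permuted, mc2$permuted)
})

test_that("p-values are approximately uniform when Y and X are independent", {
  pvals <- vapply(1:120, function(k) {
    np <- generate_null_pair(n_samples = 14, n_taxa = 8, n_covars = 2,
                             depth = 2000, seed = 5000 + k)
    monte_carlo_test(np$Y, np$X, n_perm = 99, seed = k)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals > 0 & pvals <= 1))
})
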