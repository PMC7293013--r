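test_that("Gamma matches closed forms at reference points", {
  p <- toy_problem(matrix(c(0, 1), 1, 2), fexp = 0.5, sigma = 1, theta = 0)
  expect_equal(bme_gamma(0, p), 0)  # Z(0) = 1 for a normalized prior
  expect_equal(bme_gamma(1, p), log((1 + exp(-1)) / 2) + 0.5,
               tolerance = 1e-12)
  p2 <- toy_problem(matrix(c(0, 1), 1, 2), fexp = 0.5, sigma = 0.3,
                    theta = 2)
  expect_equal(bme_gamma(1.5, p2),
               log((1 + exp(-1.5)) / 2) + 1.5 * 0.5 +
                 2 / 2 * 1.5^2 * 0.3^2, tolerance = 1e-12)
})

test_that("Gamma is convex along random segments", {
  set.seed(10)
  F <- matrix(stats::rnorm(2 * 6), 2, 6)
  p <- toy_problem(F, fexp = c(0.1, -0.2), sigma = c(0.5, 0.8), theta = 0.5)
  for (k in 1:30) {
    a <- stats::rnorm(2, sd = 3); b <- stats::rnorm(2, sd = 3)
    mid <- bme_gamma((a + b) / 2, p)
    expect_lte(mid, (bme_gamma(a, p) + bme_gamma(b, p)) / 2 + 1e-10)
  }
})

test_that("optimal weights follow the exponential reweighting formula", {
  p <- toy_problem(matrix(c(0, 1), 1, 2), fexp = 0.5, sigma = 1)
  expect_equal(bme_optimal_weights(0, p), c(0.5, 0.5))
  expect_equal(bme_optimal_weights(log(3), p), c(3 / 4, 1 / 4),
               tolerance = 1e-12)
  # gauge invariance: shifting a row of F with a compensating fexp shift
  set.seed(11)
  F <- matrix(stats::rnorm(8), 2, 4)
  p1 <- toy_problem(F, fexp = c(0.3, 0.1), sigma = c(1, 1), theta = 0)
  F2 <- F; F2[1, ] <- F2[1, ] + 5
  p2 <- toy_problem(F2, fexp = c(5.3, 0.1), sigma = c(1, 1), theta = 0)
  lam <- c(0.7, -0.4)
  expect_equal(bme_optimal_weights(lam, p1), bme_optimal_weights(lam, p2),
               tolerance = 1e-12)
})

test_that("huge theta returns the prior; sigma -> 0 pins the constraint", {
  p <- toy_problem(matrix(c(0, 1), 1, 2), fexp = 0.75, sigma = 0.5,
                   theta = 1e8)
  res <- bme_solve(p)
  expect_lt(max(abs(as.numeric(res$weights) - c(0.5, 0.5))), 1e-6)
  # exact one-constraint MaxEnt solution: weights (0.25, 0.75)
  p2 <- toy_problem(matrix(c(0, 1), 1, 2), fexp = 0.75, sigma = 1e-8,
                    theta = 0)
  res2 <- bme_solve(p2)
  expect_equal(as.numeric(res2$weights), c(0.25, 0.75), tolerance = 1e-6)
  expect_lte(res2$chi2_after, res2$chi2_before)
})

test_that("solver weights match a brute-force grid search on tiny instances", {
  set.seed(19)
  for (k in 1:12) {
    n <- sample(2:5, 1); m <- sample(1:2, 1)
    F <- matrix(stats::rnorm(m * n), m, n)
    w0 <- as.numeric(weight_set(stats::runif(n) + 0.1))
    avg <- as.vector(F %*% w0)
    fexp <- avg + stats::rnorm(m, sd = 0.3)
    sigma <- stats::runif(m, 0.2, 0.6)
    p <- bme_problem(F, w0, fexp = fexp, sigma = sigma,
                     theta = stats::runif(1, 0.2, 2))
    res <- bme_solve(p)
    oracle <- bme_grid_oracle(p)
    expect_lt(max(abs(as.numeric(res$weights) - oracle$weights)), 1e-3)
  }
})

test_that("solver is deterministic and reports diagnostics", {
  set.seed(3)
  F <- matrix(stats::rnorm(12), 2, 6)
  p <- toy_problem(F, fexp = c(0.2, -0.1), sigma = c(0.4, 0.4), theta = 1)
  r1 <- bme_solve(p); r2 <- bme_solve(p)
  expect_identical(r1$lambda, r2$lambda)
  expect_true(r1$iterations >= 1)
  expect_lt(r1$grad_norm, 1e-6)
})

test_that("chi2 and zscore satisfy their closed forms and identity", {
  expect_equal(chi2(c(1, 2), c(1, 2), c(0.1, 0.2)), 0)
  expect_equal(chi2(1.1, 1.0, 0.1), 1)
  expect_equal(chi2(c(1.1, 1.4), c(1, 1), c(0.1, 0.2)), 2.5)
  expect_equal(zscore(5, 5, 1), 0)
  expect_equal(zscore(4.9, 5, 0.1), 1, tolerance = 1e-12)
  expect_equal(zscore(2, 5, 1), 3)
  set.seed(6)
  avg <- stats::rnorm(10); fexp <- stats::rnorm(10)
  sig <- stats::runif(10, 0.1, 1)
  expect_equal(chi2(avg, fexp, sig), mean(zscore(avg, fexp, sig)^2))
  expect_error(chi2(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("training chi2 decreases along a decreasing theta ladder", {
  set.seed(14)
  F <- matrix(stats::rnorm(4 * 30), 4, 30)
  w0 <- rep(1 / 30, 30)
  fexp <- as.vector(F %*% w0) + c(0.5, -0.3, 0.4, 0.2)
  p0 <- list(F = F, w0 = w0, fexp = fexp, sigma = rep(0.2, 4))
  thetas <- c(1000, 100, 10, 1, 0.1)
  chis <- vapply(thetas, function(th)
    bme_solve(bme_problem(F, w0, fexp = fexp, sigma = p0$sigma,
                          theta = th))$chi2_after, numeric(1))
  expect_true(all(diff(chis) <= 1e-8))
})

test_that("effective fraction obeys its closed forms and the Gibbs bound", {
  expect_equal(effective_fraction(c(0.5, 0.5), c(0.5, 0.5)), 1)
  expect_equal(effective_fraction(c(1, 0), c(0.5, 0.5)), 0.5)
  set.seed(8)
  for (k in 1:20) {
    a <- weight_set(stats::runif(10) + 0.01)
    b <- weight_set(stats::runif(10) + 0.01)
    phi <- effective_fraction(as.numeric(a), as.numeric(b))
    expect_lte(phi, 1 + 1e-12)
    expect_gt(phi, 0)
  }
  expect_error(effective_fraction(c(0.5, 0.5), c(1, 0)), "prior weight")
})

test_that("theta selection returns the grid singleton and handles duplicate folds", {
  set.seed(15)
  F <- matrix(stats::rnorm(6 * 20), 6, 20)
  w0 <- rep(1 / 20, 20)
  fexp <- as.vector(F %*% w0) + stats::rnorm(6, sd = 0.2)
  sel1 <- select_theta(F, w0, fexp = fexp, sigma = rep(0.2, 6),
                       theta_grid = 3.3, k = 3, seed = 2)
  expect_equal(sel1$theta, 3.3)
  # duplicated measurements split into identical folds: train and
  # validation chi2 coincide
  F2 <- rbind(F, F); fexp2 <- c(fexp, fexp)
  sel2 <- select_theta(F2, w0, fexp = fexp2, sigma = rep(0.2, 12),
                       theta_grid = c(1, 100), seed = 7,
                       folds = list(1:6, 7:12))
  expect_equal(sel2$table$chi2_train, sel2$table$chi2_val,
               tolerance = 1e-6)
})

test_that("cross-validation flags overfitting at vanishing theta", {
  # data with noise matching sigma: tiny theta overfits (train << val)
  b <- make_two_state_ensemble(n_frames = 60, population_a = 0.7, seed = 21)
  m <- make_synthetic_measurements(b, noise_scale = 0.05, seed = 22)
  w0 <- uniform_weights(b$ensemble)
  om <- build_observable_matrix(b$ensemble, m, weights = w0)
  sel <- select_theta(om, w0, theta_grid = 10^seq(-2, 3, length.out = 6),
                      seed = 3)
  tab <- sel$table
  smallest <- which.min(tab$theta)
  expect_lt(tab$chi2_train[smallest], tab$chi2_val[smallest] / 5)
  expect_gt(sel$theta, min(tab$theta))
})

test_that("maximum-entropy optimality holds against feasible alternatives", {
  # among weight vectors reproducing the refined averages, w* minimizes
  # relative entropy to the prior (checked by random feasible perturbations
  # projected onto the constraint set of a 1-constraint toy problem)
  p <- toy_problem(matrix(c(0, 0.5, 1), 1, 3), fexp = 0.6, sigma = 1e-7,
                   theta = 0)
  res <- bme_solve(p)
  w <- as.numeric(res$weights)
  relent <- function(w) sum(w[w > 0] * log(w[w > 0] / (1 / 3)))
  base <- relent(w)
  set.seed(30)
  for (k in 1:50) {
    # parametrize the feasible set {w: sum w = 1, sum w F = 0.6}
    t <- stats::runif(1, -0.5, 0.5)
    null1 <- c(1, -2, 1) / sqrt(6)  # orthogonal to both constraint rows
    cand <- w + t * null1
    if (any(cand <= 0)) next
    expect_gte(relent(cand), base - 1e-8)
  }
})
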