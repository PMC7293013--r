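# Bayesian/Maximum-Entropy (BME) ensemble reweighting.
#
# Given per-frame observables F_i(x_j) in a linear-averaging space, prior
# weights w0 and experimental values F_exp with uncertainties sigma, BME
# finds refined weights that (i) bring the ensemble averages close to the
# experimental values given their errors and (ii) maximize the relative
# Shannon entropy to the prior.  The dual formulation minimizes, over m
# Lagrange multipliers lambda,
#
#   Gamma(lambda) = log Z(lambda) + sum_i lambda_i F_exp_i
#                   + (theta/2) sum_i lambda_i^2 sigma_i^2
#   Z(lambda)     = sum_j w0_j exp(-sum_i lambda_i F_i(x_j))
#
# and the refined weights are w*_j = w0_j exp(-sum_i lambda_i F_ij) / Z.
# Gamma is smooth and convex; theta >= 0 trades confidence in the prior
# against fit to the data.

#' Assemble a BME problem
#'
#' @param obsmat an `rw_obsmat` in linear-averaging space (carrying
#'   experimental values and sigmas), or a bare m x n matrix.
#' @param w0 prior weights (normalized, length n).
#' @param fexp,sigma experimental values and uncertainties (needed only when
#'   `obsmat` is a bare matrix).
#' @param theta confidence hyper-parameter, >= 0.
#' @return object of class `bme_problem`.
#' @export
bme_problem <- function(obsmat, w0, fexp = NULL, sigma = NULL, theta = 1) {
  if (inherits(obsmat, "rw_obsmat")) {
    F <- obsmat$F
    if (is.null(fexp)) fexp <- obsmat$fexp
    if (is.null(sigma)) sigma <- obsmat$sigma
    ids <- obsmat$ids
  } else {
    F <- as.matrix(obsmat)
    ids <- rownames(F)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(F)))
  }
  stopifnot(length(w0) == ncol(F), length(fexp) == nrow(F),
            length(sigma) == nrow(F))
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (theta < 0) stop("theta must be non-negative")
  w0 <- as.numeric(w0) / sum(w0)
  structure(list(F = F, w0 = w0, fexp = as.numeric(fexp),
                 sigma = as.numeric(sigma), theta = theta, ids = ids,
                 m = nrow(F), n = ncol(F)),
            class = "bme_problem")
}

# log Z(lambda) with log-sum-exp stabilization
bme_logz <- function(lambda, problem) {
  u <- log(problem$w0) - as.vector(crossprod(problem$F, lambda))
  logsumexp(u)
}

#' The BME dual objective Gamma
#'
#' @param lambda numeric vector of m Lagrange multipliers.
#' @param problem a `bme_problem`.
#' @return scalar Gamma(lambda).
#' @export
bme_gamma <- function(lambda, problem) {
  stopifnot(length(lambda) == problem$m)
  g <- bme_logz(lambda, problem) + sum(lambda * problem$fexp) +
    problem$theta / 2 * sum(lambda^2 * problem$sigma^2)
  if (!is.finite(g)) stop("Gamma overflow despite stabilization")
  g
}

# Analytic gradient: dGamma/dlambda_i = F_exp_i - <F_i>_w(lambda)
#                                        + theta lambda_i sigma_i^2
bme_gamma_grad <- function(lambda, problem) {
  w <- bme_optimal_weights(lambda, problem)
  problem$fexp - as.vector(problem$F %*% w) +
    problem$theta * lambda * problem$sigma^2
}

#' Refined weights at a given set of multipliers
#'
#' `w*_j = w0_j exp(-sum_i lambda_i F_ij) / Z(lambda)`, computed with
#' log-space stabilization and normalized.
#'
#' @inheritParams bme_gamma
#' @return numeric weight vector summing to one.
#' @export
bme_optimal_weights <- function(lambda, problem) {
  u <- log(problem$w0) - as.vector(crossprod(problem$F, lambda))
  u <- u - max(u)
  w <- exp(u)
  w / sum(w)
}

#' Ensemble averages of observable rows under weights
#' @param F m x n matrix (or `rw_obsmat`).
#' @param weights frame weights.
#' @export
average_observables <- function(F, weights) {
  if (inherits(F, "rw_obsmat")) F <- F$F
  as.vector(F %*% (weights / sum(weights)))
}

#' Reduced chi-squared agreement statistic
#'
#' `(1/m) sum_i (<F>_i - F_exp_i)^2 / sigma_i^2`; values below ~1 indicate
#' agreement within experimental error.
#'
#' @param avg back-calculated ensemble averages (length m).
#' @param fexp experimental values.
#' @param sigma uncertainties (> 0).
#' @export
chi2 <- function(avg, fexp, sigma) {
  if (length(avg) == 0) stop("chi2 of an empty measurement set")
  if (any(sigma <= 0)) stop("sigma must be positive")
  mean(((avg - fexp) / sigma)^2)
}

#' Z-score of a back-calculated average
#'
#' Absolute deviation from experiment in units of sigma; the reduced
#' chi-squared equals the mean of squared Z-scores.
#'
#' @inheritParams chi2
#' @export
zscore <- function(avg, fexp, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  abs(avg - fexp) / sigma
}

#' Effective fraction of frames after reweighting
#'
#' `phi_eff = exp(-sum_j w*_j log(w*_j / w0_j))`, in (0, 1]; equals 1 iff
#' the refined weights coincide with the prior.
#'
#' @param w_star refined weights.
#' @param w0 prior weights.
#' @export
effective_fraction <- function(w_star, w0) {
  stopifnot(length(w_star) == length(w0))
  w_star <- w_star / sum(w_star); w0 <- w0 / sum(w0)
  if (any(w_star > 0 & w0 == 0))
    stop("refined weight positive where prior weight is zero")
  pos <- w_star > 0
  exp(-sum(w_star[pos] * log(w_star[pos] / w0[pos])))
}

#' Solve a BME problem
#'
#' Minimizes Gamma by BFGS with the analytic gradient, starting from
#' `init` (all-zero multipliers by default, i.e. the prior).  Convergence is
#' declared when the gradient infinity-norm falls below `tol` (relative to
#' the scale of the experimental values); the optimizer is restarted from
#' its current point up to `max_restarts` times before giving up.
#'
#' @param problem a `bme_problem`.
#' @param init initial multipliers (length m).
#' @param tol gradient-norm tolerance (default 1e-8, scaled by
#'   `max(1, max |F_exp|)`).
#' @param max_iter iteration cap per optimizer run.
#' @param max_restarts restarts before declaring non-convergence.
#' @return object of class `bme_result`: `lambda`, `weights` (refined
#'   `rw_weights`), `log_z`, `chi2_before`, `chi2_after`, `phi_eff`,
#'   `iterations`, `grad_norm`, `theta`.
#' @export
bme_solve <- function(problem, init = rep(0, problem$m), tol = 1e-8,
                      max_iter = 5000, max_restarts = 10) {
  stopifnot(inherits(problem, "bme_problem"))
  # Precondition by reparametrizing in sigma units (lambda~ = lambda * sigma,
  # F~ = (F - F_exp) / sigma): Gamma shifts by an additive constant only, the
  # gradient becomes a Z-score and the Hessian is well-scaled across
  # heterogeneous observable units; centering at F_exp keeps the objective
  # O(1) so the gradient can be resolved to machine precision.
  sp <- bme_problem((problem$F - problem$fexp) / problem$sigma, problem$w0,
                    fexp = rep(0, problem$m),
                    sigma = rep(1, problem$m), theta = problem$theta)
  scale <- 1
  lambda_s <- init * problem$sigma
  fit <- stats::optim(lambda_s, fn = bme_gamma, gr = bme_gamma_grad,
                      problem = sp, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-15))
  lambda_s <- fit$par
  total_iter <- unname(fit$counts[1])
  gnorm <- max(abs(bme_gamma_grad(lambda_s, sp)))
  # Newton polish: the Hessian of Gamma is the weighted covariance of the
  # (scaled) observables plus theta * I, cheap and analytic; damped Newton
  # drives the gradient to machine precision where BFGS stalls.
  for (round in seq_len(max_restarts * 10)) {
    if (gnorm < tol * scale) break
    w <- bme_optimal_weights(lambda_s, sp)
    Fw <- sp$F * rep(w, each = sp$m)
    mu <- rowSums(Fw)
    H <- sp$F %*% t(Fw) - tcrossprod(mu) +
      diag(sp$theta + 1e-13, sp$m)
    g <- bme_gamma_grad(lambda_s, sp)
    d <- tryCatch(-solve(H, g), error = function(e) -g)
    g0 <- bme_gamma(lambda_s, sp)
    step <- 1
    accepted <- FALSE
    repeat {
      cand <- lambda_s + step * d
      gval <- bme_gamma(cand, sp)
      gn_c <- max(abs(bme_gamma_grad(cand, sp)))
      # near the optimum Gamma hits its floating-point resolution floor, so
      # accept on either objective decrease or gradient-norm decrease
      if (gval <= g0 + 1e-4 * step * sum(g * d) || gn_c < gnorm) {
        accepted <- TRUE
        lambda_s <- cand
        gnorm <- gn_c
        break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (!accepted) break
    total_iter <- total_iter + 1L
  }
  lambda <- lambda_s / problem$sigma
  if (gnorm >= tol * scale)
    stop("BME solver did not converge: gradient norm ",
         format(gnorm, digits = 3), " after ", total_iter,
         " iterations (theta = ", problem$theta, ")")
  w_star <- bme_optimal_weights(lambda, problem)
  avg0 <- as.vector(problem$F %*% problem$w0)
  avg1 <- as.vector(problem$F %*% w_star)
  structure(list(
    lambda = lambda,
    weights = weight_set(w_star, tag = "refined", provenance = "BME"),
    log_z = bme_logz(lambda, problem),
    chi2_before = chi2(avg0, problem$fexp, problem$sigma),
    chi2_after = chi2(avg1, problem$fexp, problem$sigma),
    phi_eff = effective_fraction(w_star, problem$w0),
    iterations = unname(total_iter),
    grad_norm = gnorm,
    theta = problem$theta), class = "bme_result")
}

#' @export
print.bme_result <- function(x, ...) {
  cat("<bme_result> theta =", x$theta,
      " chi2:", format(x$chi2_before, digits = 4), "->",
      format(x$chi2_after, digits = 4),
      " phi_eff =", format(x$phi_eff, digits = 3), "\n")
  invisible(x)
}

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Choose theta by k-fold cross-validation
#'
#' Measurements are partitioned into k folds by a seeded shuffle.  For each
#' candidate theta and each fold, BME is solved on the training folds and
#' the reduced chi-squared evaluated on the held-out fold; the theta with
#' the smallest mean validation chi-squared wins, ties going to the larger
#' theta (more confidence in the prior).
#'
#' @param obsmat `rw_obsmat` (or matrix) of all measurements.
#' @param w0 prior weights.
#' @param fexp,sigma experimental values and sigmas (when `obsmat` is bare).
#' @param theta_grid candidate values; default logarithmic, 1e-2..1e4,
#'   13 points.
#' @param k number of folds (default 5).
#' @param seed RNG seed for the fold shuffle (recorded in the output).
#' @param folds optional explicit partition (list of measurement index
#'   vectors) overriding the seeded shuffle.
#' @return list: `theta` (chosen), `table` (data.frame theta, chi2_train,
#'   chi2_val), `k`, `seed`.
#' @export
select_theta <- function(obsmat, w0, fexp = NULL, sigma = NULL,
                         theta_grid = 10^seq(-2, 4, length.out = 13),
                         k = 5, seed = 1, folds = NULL) {
  p0 <- bme_problem(obsmat, w0, fexp = fexp, sigma = sigma, theta = 1)
  m <- p0$m
  if (m < k) stop("need at least k measurements for k-fold CV")
  if (is.null(folds)) {
    idx <- with_seed(seed, sample.int(m))
    folds <- split(idx, rep(seq_len(k), length.out = m))
  } else {
    k <- length(folds)
  }
  if (any(lengths(folds) == 0)) stop("empty cross-validation fold")
  tab <- data.frame(theta = sort(theta_grid),
                    chi2_train = NA_real_, chi2_val = NA_real_)
  for (t in seq_len(nrow(tab))) {
    tr_chi <- val_chi <- numeric(k)
    for (f in seq_len(k)) {
      hold <- folds[[f]]
      train <- setdiff(seq_len(m), hold)
      pt <- bme_problem(p0$F[train, , drop = FALSE], p0$w0,
                        fexp = p0$fexp[train], sigma = p0$sigma[train],
                        theta = tab$theta[t])
      res <- bme_solve(pt)
      tr_chi[f] <- res$chi2_after
      avg_hold <- as.vector(p0$F[hold, , drop = FALSE] %*% res$weights)
      val_chi[f] <- chi2(avg_hold, p0$fexp[hold], p0$sigma[hold])
    }
    tab$chi2_train[t] <- mean(tr_chi)
    tab$chi2_val[t] <- mean(val_chi)
  }
  best <- max(which(tab$chi2_val <= min(tab$chi2_val) + 1e-12))
  list(theta = tab$theta[best], table = tab, k = k, seed = seed)
}
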