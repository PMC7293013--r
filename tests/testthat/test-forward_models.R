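test_that("NOE effective distance matches the r^-6 closed forms", {
  expect_equal(noe_effective_distance(3.0, 1), 3.0)
  expect_equal(noe_effective_distance(c(2, 4), c(0.5, 0.5)),
               (0.5 * 2^-6 + 0.5 * 4^-6)^(-1 / 6))
  expect_equal(noe_effective_distance(c(2, 4), c(0.5, 0.5)), 2.237,
               tolerance = 1e-3)
  expect_equal(noe_effective_distance(c(2, 4), c(1, 0)), 2.0)
  expect_error(noe_effective_distance(c(2, -1), c(0.5, 0.5)), "positive")
})

test_that("NOE averaging is monotone and bounded by the linear mean", {
  set.seed(3)
  for (i in 1:25) {
    r <- stats::runif(6, 2, 8)
    w <- weight_set(stats::runif(6))
    eff <- noe_effective_distance(r, w)
    expect_gte(eff, min(r))
    expect_lte(eff, max(r))
    expect_lte(eff, sum(w * r) + 1e-12)
    # decreasing one distance cannot increase the result
    r2 <- r; r2[3] <- r2[3] * 0.7
    expect_lte(noe_effective_distance(r2, w), eff)
  }
})

test_that("NOE matrix rows live in r^-6 space and back-transform consistently", {
  b <- make_two_state_ensemble(n_frames = 10, seed = 5)
  m <- as_measurements(data.frame(
    id = "n1", class = "noe_distance", resid1 = 1, atom1 = "H1'",
    resid2 = 2, atom2 = "H1'", value = 4, sigma = 0.2,
    stringsAsFactors = FALSE))
  idx <- bind_selectors(m, b$ensemble)
  om <- noe_observable_rows(b$ensemble, m, idx)
  expect_equal(om$transform, "r_minus_6")
  # entries are r^-6
  conf <- get_conformation(b$ensemble, 3)
  r <- sqrt(sum((conf$xyz[idx[1, 1], ] - conf$xyz[idx[1, 2], ])^2))
  expect_equal(om$F[1, 3], r^-6, tolerance = 1e-12)
  # weighted row average back-transforms to the effective distance
  w <- weight_set(stats::runif(10))
  rr <- sqrt(colSums((b$ensemble$xyz[idx[1, 1], , ] -
                        b$ensemble$xyz[idx[1, 2], , ])^2))
  expect_equal((sum(w * om$F[1, ]))^(-1 / 6), noe_effective_distance(rr, w),
               tolerance = 1e-12)
  # experimental value and sigma are transformed to the same space
  expect_equal(om$fexp, 4^-6)
  expect_equal(om$sigma, 6 * 0.2 * 4^-7)
})

test_that("zero-length atom pairs are rejected", {
  hex <- hexagon_residue()
  atoms <- rbind(hex$atoms,
                 data.frame(atom = "H1'", resname = "U", resno = 1,
                            chain = "A"))
  xyz <- rbind(hex$xyz, c(0, 1.39, 0))  # H1' coincides with N1
  ens <- ensemble(atoms, array(xyz, c(nrow(xyz), 3, 1)))
  m <- as_measurements(data.frame(
    id = "bad", class = "noe_distance", resid1 = 1, atom1 = "N1",
    resid2 = 1, atom2 = "H1'", value = 3, sigma = 0.1,
    stringsAsFactors = FALSE))
  idx <- bind_selectors(m, ens)
  expect_error(noe_observable_rows(ens, m, idx), "zero-length")
})

test_that("Karplus couplings reproduce the closed forms at 0, 90 and 180 degrees", {
  tb <- karplus_table()
  row <- tb[tb$coupling_type == "generic", ]
  expect_equal(karplus_coupling(0 - row$phase_deg, "generic"),
               row$A + row$B + row$C)
  expect_equal(karplus_coupling(90 - row$phase_deg, "generic"), row$C,
               tolerance = 1e-12)
  expect_equal(karplus_coupling(180 - row$phase_deg, "generic"),
               row$A - row$B + row$C)
  expect_error(karplus_coupling(10, "nope"), "unknown coupling_type")
})

test_that("coupling rows agree with hand-built geometry", {
  # planar cis quadruplet C3'-O3'-P-O5' => zeta = 0 => J = A + B + C
  atoms <- data.frame(
    atom = c("C3'", "O3'", "P", "O5'"),
    resname = c("U", "U", "U", "U"), resno = c(1, 1, 2, 2),
    chain = "A", stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 1, 0), c(0, 0, 0), c(1.5, 0, 0), c(1.5, 1, 0))
  ens <- ensemble(atoms, array(c(xyz, xyz), c(4, 3, 2)))
  m <- as_measurements(data.frame(
    id = "j1", class = "scalar_coupling", resid1 = 1, atom1 = "C3'",
    resid2 = 1, atom2 = "O3'", torsion_name = "zeta", value = 5,
    sigma = 1, coupling_type = "generic", stringsAsFactors = FALSE))
  idx <- bind_selectors(m, ens)
  om <- coupling_observable_rows(ens, m, idx)
  tb <- karplus_table()
  row <- tb[tb$coupling_type == "generic", ]
  expect_equal(om$F[1, 1],
               karplus_coupling(0, "generic"))
  # two identical frames produce identical columns
  expect_equal(om$F[, 1], om$F[, 2])
  # empty subset yields a 0-row matrix
  om0 <- coupling_observable_rows(ens, m[0, ], idx[0, , drop = FALSE])
  expect_equal(nrow(om0$F), 0)
})

rdc_toy <- function(n_res = 8, seed = 9) {
  b <- make_two_state_ensemble(n_frames = 10, seed = seed)
  res <- c(2, 3, 5, 6, 8, 9, 11, 13)[seq_len(n_res)]
  m <- as_measurements(data.frame(
    id = sprintf("d%d", seq_len(n_res)), class = "rdc",
    resid1 = res, atom1 = "C1'", resid2 = res, atom2 = "H1'",
    value = 0, sigma = 0.05, coupling_type = "CH",
    stringsAsFactors = FALSE))
  list(ens = b$ensemble, m = m, idx = bind_selectors(m, b$ensemble))
}

test_that("alignment-tensor fit recovers a known tensor exactly", {
  toy <- rdc_toy()
  S <- rnareweight:::saupe_from_params(c(0.3, -0.2, 0.1, 0.05, -0.15))
  w <- uniform_weights(toy$ens)
  om <- rdc_observable_rows(toy$ens, S, toy$m, toy$idx)
  toy$m$value <- average_observables(om, w)
  fit <- fit_alignment_tensor(toy$ens, w, toy$m, toy$idx)
  expect_equal(unclass(fit), unclass(S), tolerance = 1e-8,
               ignore_attr = TRUE)
  pred <- average_observables(rdc_observable_rows(toy$ens, fit, toy$m,
                                                  toy$idx), w)
  expect_lt(chi2(pred, toy$m$value, toy$m$sigma), 1e-12)
  # tensors are symmetric and traceless
  expect_equal(sum(diag(unclass(fit))), 0, tolerance = 1e-12)
  expect_equal(unclass(fit), t(unclass(fit)), tolerance = 1e-12)
})

test_that("degenerate RDC designs are rejected", {
  toy <- rdc_toy(n_res = 4)
  expect_error(fit_alignment_tensor(toy$ens, uniform_weights(toy$ens),
                                    toy$m, toy$idx), "underdetermined")
  # all bonds parallel: rank-deficient
  par <- rdc_toy()
  i_c <- par$idx[, 1]; i_h <- par$idx[, 2]
  for (k in seq_along(i_c)) for (f in seq_len(par$ens$n_frames))
    par$ens$xyz[i_h[k], , f] <- par$ens$xyz[i_c[k], , f] + c(0, 0, 1.1)
  expect_error(fit_alignment_tensor(par$ens, uniform_weights(par$ens),
                                    par$m, par$idx), "unidentifiable")
})

test_that("RDC predictions satisfy the closed forms and covariances", {
  toy <- rdc_toy()
  zero <- rnareweight:::saupe_from_params(rep(0, 5))
  om <- rdc_observable_rows(toy$ens, zero, toy$m, toy$idx)
  expect_true(all(om$F == 0))
  # all-zero experimental RDCs fit a zero tensor
  toy$m$value <- rep(0, nrow(toy$m))
  fit0 <- fit_alignment_tensor(toy$ens, uniform_weights(toy$ens), toy$m,
                               toy$idx)
  expect_equal(max(abs(unclass(fit0))), 0, tolerance = 1e-12)
  # bond along z with S = diag(-s/2, -s/2, s): D = Dmax * s
  s <- 0.37
  S <- rnareweight:::saupe_from_params(c(-s / 2, -s / 2, 0, 0, 0))
  atoms <- data.frame(atom = c("C1'", "H1'"), resname = "U", resno = 1,
                      chain = "A", stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.1))
  ens1 <- ensemble(atoms, array(xyz, c(2, 3, 1)))
  m1 <- as_measurements(data.frame(
    id = "dz", class = "rdc", resid1 = 1, atom1 = "C1'", resid2 = 1,
    atom2 = "H1'", value = 0, sigma = 0.1, coupling_type = "CH",
    stringsAsFactors = FALSE))
  i1 <- bind_selectors(m1, ens1)
  expect_equal(rdc_observable_rows(ens1, S, m1, i1)$F[1, 1], s,
               tolerance = 1e-12)
  # rotating frame and tensor together leaves predictions unchanged
  set.seed(12)
  for (k in 1:5) {
    R <- random_rotation()
    Srot <- structure(R %*% unclass(S) %*% t(R),
                      class = class(S))
    ensR <- ensemble(atoms, array(t(R %*% t(xyz)), c(2, 3, 1)))
    expect_equal(rdc_observable_rows(ensR, Srot, m1, i1)$F[1, 1], s,
                 tolerance = 1e-10)
  }
})

test_that("the fitted tensor is chi2-optimal against random alternatives", {
  toy <- rdc_toy()
  w <- uniform_weights(toy$ens)
  set.seed(4)
  truth <- rnareweight:::saupe_from_params(stats::rnorm(5, sd = 0.3))
  om <- rdc_observable_rows(toy$ens, truth, toy$m, toy$idx)
  toy$m$value <- average_observables(om, w) + stats::rnorm(8, sd = 0.05)
  fit <- fit_alignment_tensor(toy$ens, w, toy$m, toy$idx)
  c_fit <- chi2(average_observables(
    rdc_observable_rows(toy$ens, fit, toy$m, toy$idx), w),
    toy$m$value, toy$m$sigma)
  for (k in 1:20) {
    alt <- rnareweight:::saupe_from_params(stats::rnorm(5, sd = 0.3))
    c_alt <- chi2(average_observables(
      rdc_observable_rows(toy$ens, alt, toy$m, toy$idx), w),
      toy$m$value, toy$m$sigma)
    expect_gte(c_alt, c_fit - 1e-10)
  }
})

test_that("rigid-body motion leaves NOE and coupling rows unchanged", {
  b <- make_two_state_ensemble(n_frames = 10, seed = 6)
  m <- as_measurements(data.frame(
    id = c("n1", "j1"), class = c("noe_distance", "scalar_coupling"),
    resid1 = c(1, 4), atom1 = c("H1'", "C3'"),
    resid2 = c(3, 4), atom2 = c("H1'", "O3'"),
    torsion_name = c(NA, "zeta"), value = c(4, 3), sigma = c(0.2, 1),
    coupling_type = c(NA, "generic"), stringsAsFactors = FALSE))
  idx <- bind_selectors(m, b$ensemble)
  ref_noe <- noe_observable_rows(b$ensemble, m[1, ], idx[1, , drop = FALSE])
  ref_j <- coupling_observable_rows(b$ensemble, m[2, ],
                                    idx[2, , drop = FALSE])
  set.seed(8)
  R <- random_rotation(); t0 <- stats::rnorm(3, sd = 5)
  xyz <- b$ensemble$xyz
  for (f in seq_len(dim(xyz)[3])) xyz[, , f] <- t(R %*% t(xyz[, , f])) +
    matrix(t0, dim(xyz)[1], 3, byrow = TRUE)
  moved <- ensemble(b$ensemble$atoms, xyz)
  expect_equal(noe_observable_rows(moved, m[1, ],
                                   idx[1, , drop = FALSE])$F,
               ref_noe$F, tolerance = 1e-9)
  expect_equal(coupling_observable_rows(moved, m[2, ],
                                        idx[2, , drop = FALSE])$F,
               ref_j$F, tolerance = 1e-9)
})
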