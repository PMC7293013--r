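# Fixtures built in code and independently coded oracles used across tests.

# --- fixtures -------------------------------------------------------------

# A single pseudo-residue whose six ring atoms form a regular hexagon of
# radius `r` centered at `center`, optionally rotated.
hexagon_residue <- function(resno = 1, center = c(0, 0, 0), r = 1.39,
                            R = diag(3), resname = "U", drop_atom = NULL) {
  ang <- seq(90, -210, by = -60)[1:6] * pi / 180
  nm <- c("N1", "C2", "N3", "C4", "C5", "C6")
  xyz <- t(vapply(ang, function(a) as.vector(R %*% c(r * cos(a),
                                                     r * sin(a), 0)) + center,
                  numeric(3)))
  keep <- if (is.null(drop_atom)) rep(TRUE, 6) else nm != drop_atom
  list(atoms = data.frame(atom = nm[keep], resname = resname, resno = resno,
                          chain = "A", stringsAsFactors = FALSE),
       xyz = xyz[keep, , drop = FALSE])
}

# Conformation made of several hexagon bases (ring atoms only).
bases_conformation <- function(centers, rotations = NULL) {
  n <- nrow(centers)
  if (is.null(rotations)) rotations <- replicate(n, diag(3), simplify = FALSE)
  parts <- lapply(seq_len(n), function(i)
    hexagon_residue(resno = i, center = centers[i, ], R = rotations[[i]]))
  structure(list(atoms = do.call(rbind, lapply(parts, `[[`, "atoms")),
                 xyz = do.call(rbind, lapply(parts, `[[`, "xyz"))),
            class = "rw_conformation")
}

rigid_copy <- function(conf, axis = c(1, 2, 3), angle = 35,
                       shift = c(1, -2, 3)) {
  R <- rnareweight:::rotation_matrix(axis, angle)
  out <- conf
  out$xyz <- t(R %*% t(conf$xyz)) +
    matrix(shift, nrow(conf$xyz), 3, byrow = TRUE)
  out
}

random_rotation <- function() {
  ax <- stats::rnorm(3)
  rnareweight:::rotation_matrix(ax, stats::runif(1, 0, 360))
}

# Small two-model PDB text fixture (well-formed fixed columns).
write_toy_pdb <- function(path, n_models = 2, drop_last_atom_in_model = 0) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    n_at <- if (m == drop_last_atom_in_model) 2 else 3
    nm <- c("P", "C1'", "N1")[seq_len(n_at)]
    for (i in seq_len(n_at)) {
      writeLines(sprintf(
        "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, sprintf(" %-3s", nm[i]), "U", "A", 1L, i + 0.1 * m, 0, 0), con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}

# --- independent oracles --------------------------------------------------

# Dihedral via the arccos of plane normals plus an explicit sign from the
# scalar triple product (a different formulation than the package's atan2).
dihedral_oracle <- function(p1, p2, p3, p4) {
  n1 <- rnareweight:::cross3(p2 - p1, p3 - p2)
  n2 <- rnareweight:::cross3(p3 - p2, p4 - p3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosphi <- max(-1, min(1, cosphi))
  phi <- acos(cosphi) * 180 / pi
  if (sum(rnareweight:::cross3(n1, n2) * (p3 - p2)) < 0) phi <- -phi
  phi
}

# Step-by-step eRMSD re-derivation, written directly from the definition:
# base-fixed frame (origin = ring centroid, x toward C2, z normal from
# C2 x C4, y completing), pair vectors scaled by (5, 5, 3), G-vector with
# cutoff 2.4 and gamma = pi / 2.4, eRMSD = sqrt(sum |dG|^2 / N).
ermsd_oracle <- function(confA, confB) {
  one_frame <- function(conf, resno) {
    ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
    P <- t(vapply(ring, function(a) {
      i <- which(conf$atoms$resno == resno & conf$atoms$atom == a)
      conf$xyz[i, ]
    }, numeric(3)))
    o <- colMeans(P)
    v1 <- P["C2", ] - o
    v2 <- P["C4", ] - o
    ex <- v1 / sqrt(sum(v1^2))
    ez <- rnareweight:::cross3(ex, v2)
    ez <- ez / sqrt(sum(ez^2))
    ey <- rnareweight:::cross3(ez, ex)
    list(o = o, ax = ex, ay = ey, az = ez)
  }
  gvec <- function(conf) {
    rs <- sort(unique(conf$atoms$resno))
    fr <- lapply(rs, function(r) one_frame(conf, r))
    out <- NULL
    for (a in seq_along(rs)) for (b in seq_along(rs)) {
      if (a == b) next
      d <- fr[[b]]$o - fr[[a]]$o
      rt <- c(sum(d * fr[[a]]$ax) / 5, sum(d * fr[[a]]$ay) / 5,
              sum(d * fr[[a]]$az) / 3)
      rho <- sqrt(sum(rt^2))
      gam <- pi / 2.4
      g <- if (rho < 2.4)
        c(sin(gam * rho) * rt[1] / rho, sin(gam * rho) * rt[2] / rho,
          sin(gam * rho) * rt[3] / rho, 1 + cos(gam * rho)) / gam
      else c(0, 0, 0, 0)
      out <- rbind(out, g)
    }
    out
  }
  gA <- gvec(confA); gB <- gvec(confB)
  sqrt(sum((gA - gB)^2) / length(unique(confA$atoms$resno)))
}

# Brute-force BME oracle: dense grid search over the Lagrange multipliers
# (m <= 2), two refinement passes around the best grid point.
bme_grid_oracle <- function(problem, span = 30, n_grid = 121, passes = 3) {
  m <- problem$m
  center <- rep(0, m)
  width <- span
  best <- NULL
  for (p in seq_len(passes)) {
    axes <- lapply(seq_len(m), function(i)
      seq(center[i] - width, center[i] + width, length.out = n_grid))
    grid <- as.matrix(expand.grid(axes))
    vals <- apply(grid, 1, function(l) bme_gamma(l, problem))
    k <- which.min(vals)
    best <- grid[k, ]
    center <- best
    width <- 2 * width / (n_grid - 1) * 2  # shrink around the winner
  }
  list(lambda = best,
       weights = bme_optimal_weights(best, problem))
}

# Uniform-prior problem from a plain matrix.
toy_problem <- function(F, fexp, sigma, theta = 0) {
  n <- ncol(F)
  bme_problem(F, rep(1 / n, n), fexp = fexp, sigma = sigma, theta = theta)
}
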