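# Base-centric geometry: eRMSD to a reference, backbone torsions, ring
# centers, two-state assignment, weighted populations, free-energy surfaces
# and block standard errors.

RING_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6")

# eRMSD constants: anisotropic scaling of base-base vectors (Angstrom) and
# the G-vector cutoff in scaled units.  Pinned here for reproducibility.
ERMSD_SCALE <- c(5, 5, 3)
ERMSD_CUTOFF <- 2.4

#' Center of a nucleobase six-membered ring
#'
#' Unweighted centroid of the six ring atoms N1 C2 N3 C4 C5 C6 (the
#' six-membered ring shared by purines and pyrimidines).
#'
#' @param conf an `rw_conformation`.
#' @param resno residue index.
#' @return numeric length-3 point in Angstrom.
#' @export
ring_center <- function(conf, resno) {
  pts <- matrix(NA_real_, 6, 3)
  for (k in seq_along(RING_ATOMS)) {
    p <- atom_xyz(conf, resno, RING_ATOMS[k])
    if (is.null(p))
      stop("residue ", resno, " is missing ring atom ", RING_ATOMS[k])
    pts[k, ] <- p
  }
  colMeans(pts)
}

# Local base-fixed frame: origin at the ring centroid, x toward C2,
# z normal to the (C2, C4) plane, y completing the right-handed triad.
# Returns list(origin, R) with R rows = (x, y, z) axes.
base_frame <- function(conf, resno) {
  o <- ring_center(conf, resno)
  a <- atom_xyz(conf, resno, "C2") - o
  b <- atom_xyz(conf, resno, "C4") - o
  x <- a / sqrt(sum(a^2))
  z <- cross3(x, b)
  z <- z / sqrt(sum(z^2))
  y <- cross3(z, x)
  list(origin = o, R = rbind(x, y, z))
}

# 4-component G-vectors for all ordered base pairs of one conformation.
# Rows indexed by ordered pair (a, b), a != b, in fixed enumeration order.
gvectors <- function(conf, resnos) {
  nb <- length(resnos)
  frames <- lapply(resnos, function(r) base_frame(conf, r))
  gamma <- pi / ERMSD_CUTOFF
  G <- matrix(0, nb * (nb - 1), 4)
  k <- 0
  for (a in seq_len(nb)) for (b in seq_len(nb)) {
    if (a == b) next
    k <- k + 1
    r <- frames[[b]]$origin - frames[[a]]$origin
    rloc <- as.vector(frames[[a]]$R %*% r) / ERMSD_SCALE
    rho <- sqrt(sum(rloc^2))
    if (rho < ERMSD_CUTOFF) {
      G[k, ] <- c(sin(gamma * rho) * rloc / rho,
                  1 + cos(gamma * rho)) / gamma
    }
  }
  G
}

#' eRMSD between two nucleic-acid conformations
#'
#' Dissimilarity between two base arrangements built from scaled base-to-base
#' relative position vectors expressed in base-fixed frames (G-vectors).
#' For each ordered base pair the inter-base vector is expressed in the first
#' base's frame, anisotropically scaled by (5, 5, 3) Angstrom, and mapped to a
#' smooth 4-vector that decays to zero at scaled distance 2.4.  The eRMSD is
#' the root mean square difference of these vectors over all ordered pairs,
#' normalized by the number of bases.  It is non-negative, symmetric, zero on
#' rigid copies, and requires no superposition.
#'
#' @param conf,ref `rw_conformation`s with the same number and order of
#'   nucleobases.
#' @return non-negative dimensionless value.
#' @export
ermsd <- function(conf, ref) {
  r1 <- sort(unique(conf$atoms$resno))
  r2 <- sort(unique(ref$atoms$resno))
  if (length(r1) != length(r2))
    stop("base-count mismatch: ", length(r1), " vs ", length(r2))
  g1 <- gvectors(conf, r1)
  g2 <- gvectors(ref, r2)
  sqrt(sum((g1 - g2)^2) / length(r1))
}

#' eRMSD of every frame of an ensemble from a reference conformation
#' @param ens an `rw_ensemble`.
#' @param ref an `rw_conformation`.
#' @return numeric vector of length `n_frames`.
#' @export
ermsd_traj <- function(ens, ref) {
  vapply(seq_len(ens$n_frames),
         function(f) ermsd(get_conformation(ens, f), ref), numeric(1))
}

# Atom quadruplets defining the seven standard nucleic-acid torsions.
# Each entry: list of (residue offset, atom name); chi depends on the
# glycosidic nitrogen (N9 for purines, N1 for pyrimidines).
TORSION_DEFS <- list(
  alpha   = list(c(-1, "O3'"), c(0, "P"),   c(0, "O5'"), c(0, "C5'")),
  beta    = list(c(0, "P"),    c(0, "O5'"), c(0, "C5'"), c(0, "C4'")),
  gamma   = list(c(0, "O5'"),  c(0, "C5'"), c(0, "C4'"), c(0, "C3'")),
  delta   = list(c(0, "C5'"),  c(0, "C4'"), c(0, "C3'"), c(0, "O3'")),
  epsilon = list(c(0, "C4'"),  c(0, "C3'"), c(0, "O3'"), c(1, "P")),
  zeta    = list(c(0, "C3'"),  c(0, "O3'"), c(1, "P"),   c(1, "O5'"))
)

#' Backbone and glycosidic torsion angles
#'
#' Computes alpha, beta, gamma, delta, epsilon, zeta and chi for every
#' residue, in degrees in (-180, 180].  chi uses O4'-C1'-N9-C4 for purines
#' (residues carrying an N9 atom) and O4'-C1'-N1-C2 for pyrimidines.
#' Torsions whose atoms are absent (chain termini) are returned as NA rather
#' than raising an error.
#'
#' @param conf an `rw_conformation`.
#' @return data.frame with columns `resno`, `alpha` ... `zeta`, `chi`.
#' @export
backbone_torsions <- function(conf) {
  resnos <- sort(unique(conf$atoms$resno))
  out <- data.frame(resno = resnos)
  for (tn in names(TORSION_DEFS)) out[[tn]] <- NA_real_
  out$chi <- NA_real_
  for (i in seq_along(resnos)) {
    r <- resnos[i]
    for (tn in names(TORSION_DEFS)) {
      quad <- TORSION_DEFS[[tn]]
      pts <- lapply(quad, function(q)
        atom_xyz(conf, r + as.integer(q[1]), q[2]))
      if (!any(vapply(pts, is.null, logical(1))))
        out[[tn]][i] <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    }
    purine <- !is.null(atom_xyz(conf, r, "N9"))
    quad <- if (purine) list("O4'", "C1'", "N9", "C4")
            else list("O4'", "C1'", "N1", "C2")
    pts <- lapply(quad, function(a) atom_xyz(conf, r, a))
    if (!any(vapply(pts, is.null, logical(1))))
      out$chi[i] <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  }
  out
}

#' Named torsion of one residue
#' @param conf an `rw_conformation`.
#' @param resno residue index.
#' @param name one of alpha, beta, gamma, delta, epsilon, zeta, chi.
#' @return angle in degrees, or NA if atoms are missing.
#' @export
residue_torsion <- function(conf, resno, name) {
  if (!name %in% c(names(TORSION_DEFS), "chi"))
    stop("unknown torsion name: ", name)
  tt <- backbone_torsions(conf)
  tt[[name]][match(resno, tt$resno)]
}

#' Assign frames to a two-state partition by eRMSD
#'
#' A frame belongs to the major state A when its eRMSD from the reference is
#' strictly below the threshold, and to state B otherwise (the boundary value
#' itself is state B).
#'
#' @param ermsd_values non-negative numeric vector.
#' @param threshold positive threshold, default 0.7.
#' @return factor with levels A, B and attribute `threshold`.
#' @export
assign_states <- function(ermsd_values, threshold = 0.7) {
  if (any(ermsd_values < 0)) stop("eRMSD values must be non-negative")
  if (threshold < 0) stop("threshold must be non-negative")
  lab <- factor(ifelse(ermsd_values < threshold, "A", "B"),
                levels = c("A", "B"))
  attr(lab, "threshold") <- threshold
  lab
}

#' Weighted population of state A
#'
#' @param labels factor from [assign_states()].
#' @param weights an `rw_weights` (or normalized numeric) vector, same
#'   length.
#' @param state which state's population to return (default "A").
#' @return fraction in \[0, 1\]; populations of A and B sum to one.
#' @export
population <- function(labels, weights, state = "A") {
  if (length(labels) != length(weights))
    stop("labels and weights lengths differ")
  sum(weights[labels == state]) / sum(weights)
}

#' Weighted two-dimensional free-energy surface
#'
#' Histogram of two collective variables under frame weights, reported as
#' -ln(p) in units of kB*T, anchored so the global minimum over occupied
#' bins is zero.  Empty bins are masked (NA).
#'
#' @param x,y numeric vectors (one value per frame).
#' @param weights frame weights.
#' @param bins number of bins per axis (scalar or length 2), or a list of
#'   two bin-edge vectors.
#' @return list of class `rw_fes`: `x_edges`, `y_edges`, `value` (matrix,
#'   kB*T), `mask` (TRUE where empty).
#' @export
weighted_fes_2d <- function(x, y, weights, bins = 25) {
  stopifnot(length(x) == length(y), length(x) == length(weights))
  if (is.list(bins)) {
    xe <- bins[[1]]; ye <- bins[[2]]
  } else {
    if (length(bins) == 1) bins <- c(bins, bins)
    xe <- seq(min(x), max(x), length.out = bins[1] + 1)
    ye <- seq(min(y), max(y), length.out = bins[2] + 1)
  }
  ix <- findInterval(x, xe, rightmost.closed = TRUE)
  iy <- findInterval(y, ye, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= length(xe) - 1 & iy >= 1 & iy <= length(ye) - 1
  if (!any(ok)) stop("all points fall outside the grid")
  p <- matrix(0, length(xe) - 1, length(ye) - 1)
  w <- weights / sum(weights)
  for (k in which(ok)) p[ix[k], iy[k]] <- p[ix[k], iy[k]] + w[k]
  mask <- p <= 0
  val <- matrix(NA_real_, nrow(p), ncol(p))
  val[!mask] <- -log(p[!mask])
  val <- val - min(val, na.rm = TRUE)
  structure(list(x_edges = xe, y_edges = ye, value = val, mask = mask),
            class = "rw_fes")
}

#' Block standard error of a weighted average
#'
#' Splits the frames into contiguous (time-ordered) blocks, recomputes the
#' weighted statistic within each block with renormalized block weights, and
#' returns the sample standard deviation across blocks divided by the square
#' root of the number of blocks.  Block boundaries are at equal frame
#' counts, with the remainder assigned to the last block.
#'
#' @param values per-frame quantity.
#' @param weights frame weights.
#' @param n_blocks number of blocks, default 4.
#' @param statistic function of (values, weights) computed per block;
#'   defaults to the weighted mean.
#' @return the standard error (scalar).
#' @export
block_standard_error <- function(values, weights, n_blocks = 4,
                                 statistic = stats::weighted.mean) {
  n <- length(values)
  stopifnot(length(weights) == n)
  if (n < n_blocks) stop("need at least as many frames as blocks")
  size <- n %/% n_blocks
  starts <- (seq_len(n_blocks) - 1) * size + 1
  ends <- c(starts[-1] - 1, n)
  est <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    idx <- starts[b]:ends[b]
    wb <- weights[idx]
    if (sum(wb) <= 0) stop("block ", b, " has zero total weight")
    est[b] <- statistic(values[idx], wb / sum(wb))
  }
  stats::sd(est) / sqrt(n_blocks)
}

#' Ring-center distance between two residues
#' @param conf an `rw_conformation`.
#' @param res1,res2 residue indices.
#' @return distance in Angstrom.
#' @export
ring_distance <- function(conf, res1, res2) {
  sqrt(sum((ring_center(conf, res1) - ring_center(conf, res2))^2))
}
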