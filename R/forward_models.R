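# Forward models: back-calculation of NOE effective distances, Karplus
# scalar couplings and residual dipolar couplings from ensemble coordinates.
#
# Every observable is exposed as an m x n matrix of per-frame values in the
# space where linear weight-averaging is exact: r^-6 for NOEs, the native
# (linear) space for couplings and RDCs.  The transform tag on the matrix
# records that space, and experimental values/uncertainties are transformed
# consistently so BME can treat all rows uniformly.

#' Observable matrix constructor
#'
#' @param F m x n matrix of per-frame back-calculated values F_i(x_j).
#' @param ids measurement ids (length m).
#' @param transform `"linear"` or `"r_minus_6"` — the space in which linear
#'   averaging over frames is exact.
#' @param fexp,sigma experimental values and uncertainties, already in the
#'   same space as `F`.
#' @return object of class `rw_obsmat`.
#' @export
observable_matrix <- function(F, ids, transform = c("linear", "r_minus_6"),
                              fexp = NULL, sigma = NULL) {
  transform <- match.arg(transform)
  F <- as.matrix(F)
  if (nrow(F) != length(ids)) stop("row count does not match ids")
  if (nrow(F) > 0 && !all(is.finite(F))) stop("non-finite observable values")
  structure(list(F = F, ids = as.character(ids), transform = transform,
                 fexp = fexp, sigma = sigma),
            class = "rw_obsmat")
}

#' Concatenate observable matrices row-wise
#' @param ... `rw_obsmat` objects over the same frames.
#' @return an `rw_obsmat` with transform `"linear"` rows stacked (all inputs
#'   must already be in a linear-averaging space, which both tags guarantee).
#' @export
rbind_obsmat <- function(...) {
  mats <- list(...)
  mats <- mats[vapply(mats, function(m) nrow(m$F) > 0, logical(1))]
  if (!length(mats)) stop("no rows to combine")
  ncols <- vapply(mats, function(m) ncol(m$F), integer(1))
  if (length(unique(ncols)) != 1) stop("frame counts differ")
  observable_matrix(do.call(rbind, lapply(mats, function(m) m$F)),
                    unlist(lapply(mats, function(m) m$ids)),
                    transform = "linear",
                    fexp = unlist(lapply(mats, function(m) m$fexp)),
                    sigma = unlist(lapply(mats, function(m) m$sigma)))
}

#' NOE effective distance under frame weights
#'
#' The r^-6 ensemble average `(sum_j w_j r_j^-6)^(-1/6)`, the standard
#' effective distance for NOE-derived restraints.  The result always lies
#' between the smallest and largest per-frame distance and never exceeds the
#' linear weighted mean.
#'
#' @param r per-frame distances in Angstrom (> 0).
#' @param weights normalized frame weights.
#' @return effective distance in Angstrom.
#' @export
noe_effective_distance <- function(r, weights) {
  if (any(r <= 0)) stop("distances must be positive")
  stopifnot(length(r) == length(weights))
  sum(weights * r^-6)^(-1 / 6)
}

#' Per-frame NOE rows in r^-6 space
#'
#' Entry (i, j) is r_ij^-6 (Angstrom^-6) for measurement i's atom pair in
#' frame j, so that a linear weighted average of a row equals the r^-6
#' ensemble average.  Experimental distances and sigmas are transformed to
#' the same space: `fexp' = fexp^-6`, `sigma' = 6 sigma fexp^-7`
#' (first-order propagation).
#'
#' @param ens an `rw_ensemble`.
#' @param measurements the `noe_distance` subset of an `rw_measurements`.
#' @param idx selector index matrix from [bind_selectors()] (same rows).
#' @return `rw_obsmat` with transform `"r_minus_6"`.
#' @export
noe_observable_rows <- function(ens, measurements, idx) {
  m <- nrow(measurements)
  F <- matrix(NA_real_, m, ens$n_frames)
  if (m > 0) for (i in seq_len(m)) {
    d <- ens$xyz[idx[i, 1], , ] - ens$xyz[idx[i, 2], , ]
    if (is.null(dim(d))) d <- matrix(d, ncol = 1)
    r2 <- colSums(d^2)
    if (any(r2 < 1e-6))  # below 1e-3 Angstrom: coincident atoms
      stop("zero-length atom pair for measurement ", measurements$id[i])
    F[i, ] <- r2^-3
  }
  observable_matrix(F, measurements$id, transform = "r_minus_6",
                    fexp = measurements$value^-6,
                    sigma = 6 * measurements$sigma * measurements$value^-7)
}

#' Default Karplus coefficient table
#'
#' Coefficients of `J = A cos^2(theta + phase) + B cos(theta + phase) + C`
#' keyed by coupling type.  Shipped as an editable TSV
#' (`extdata/karplus_defaults.tsv`): Karplus parameterizations are empirical
#' and revisable, so they are configuration, not code.
#'
#' @param path optional path to a user table (TSV columns: coupling_type, A,
#'   B, C, phase_deg).
#' @return data.frame with one row per coupling type.
#' @export
karplus_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "karplus_defaults.tsv",
                        package = "rnareweight")
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (anyDuplicated(tb$coupling_type))
    stop("duplicate coupling_type in Karplus table")
  tb
}

#' Three-bond scalar coupling from a torsion angle
#'
#' `J(theta) = A cos^2(theta + phase) + B cos(theta + phase) + C`.
#'
#' @param torsion_deg torsion angle(s) in degrees.
#' @param coupling_type key into the Karplus table.
#' @param table Karplus coefficient table from [karplus_table()].
#' @return coupling in Hz.
#' @export
karplus_coupling <- function(torsion_deg, coupling_type,
                             table = karplus_table()) {
  row <- table[table$coupling_type == coupling_type, ]
  if (nrow(row) != 1) stop("unknown coupling_type: ", coupling_type)
  th <- (torsion_deg + row$phase_deg) * pi / 180
  row$A * cos(th)^2 + row$B * cos(th) + row$C
}

#' Per-frame scalar-coupling rows
#'
#' For each measurement the torsion is taken either from its four bound
#' atoms or, when `torsion_name` is set, from the named backbone/glycosidic
#' torsion of `resid1`; the Karplus relation then gives per-frame J values
#' (transform `"linear"`).
#'
#' @inheritParams noe_observable_rows
#' @param table Karplus coefficient table.
#' @return `rw_obsmat` with transform `"linear"`.
#' @export
coupling_observable_rows <- function(ens, measurements, idx,
                                     table = karplus_table()) {
  m <- nrow(measurements)
  F <- matrix(NA_real_, m, ens$n_frames)
  if (m > 0) {
    bad <- setdiff(unique(measurements$coupling_type), table$coupling_type)
    if (length(bad)) stop("unknown coupling_type: ", bad[1])
    # torsion tables are computed once per frame and shared by all
    # torsion-named measurements
    need_table <- any(!is.na(measurements$torsion_name))
    for (f in seq_len(ens$n_frames)) {
      conf <- get_conformation(ens, f)
      tt <- if (need_table) backbone_torsions(conf) else NULL
      for (i in seq_len(m)) {
        tn <- measurements$torsion_name[i]
        th <- if (!is.na(tn)) {
          if (!tn %in% names(tt)) stop("unknown torsion name: ", tn)
          tt[[tn]][match(measurements$resid1[i], tt$resno)]
        } else {
          dihedral_angle(conf$xyz[idx[i, 1], ], conf$xyz[idx[i, 2], ],
                         conf$xyz[idx[i, 3], ], conf$xyz[idx[i, 4], ])
        }
        if (is.na(th))
          stop("unresolved torsion for measurement ", measurements$id[i])
        F[i, f] <- karplus_coupling(th, measurements$coupling_type[i], table)
      }
    }
  }
  observable_matrix(F, measurements$id, transform = "linear",
                    fexp = measurements$value, sigma = measurements$sigma)
}

# Design row of the 5-parameter Saupe tensor fit for a unit bond vector u:
# u'Su = s1 (ux^2 - uz^2) + s2 (uy^2 - uz^2) + 2 s3 ux uy + 2 s4 ux uz
#        + 2 s5 uy uz,  with S traceless symmetric,
# s = (Sxx, Syy, Sxy, Sxz, Syz), Szz = -Sxx - Syy.
saupe_design_row <- function(u) {
  c(u[1]^2 - u[3]^2, u[2]^2 - u[3]^2,
    2 * u[1] * u[2], 2 * u[1] * u[3], 2 * u[2] * u[3])
}

saupe_from_params <- function(s) {
  S <- matrix(c(s[1], s[3], s[4],
                s[3], s[2], s[5],
                s[4], s[5], -s[1] - s[2]), 3, 3)
  structure(S, class = c("rw_tensor", "matrix", "array"))
}

# Per-measurement unit bond vectors for every frame: list of 3 x n matrices.
rdc_unit_vectors <- function(ens, measurements, idx) {
  lapply(seq_len(nrow(measurements)), function(i) {
    d <- ens$xyz[idx[i, 1], , ] - ens$xyz[idx[i, 2], , ]
    if (is.null(dim(d))) d <- matrix(d, ncol = 1)
    nrm <- sqrt(colSums(d^2))
    if (any(nrm < 1e-3))
      stop("zero-length bond vector for measurement ", measurements$id[i])
    sweep(d, 2, nrm, "/")
  })
}

rdc_dmax_values <- function(measurements, dmax) {
  ct <- measurements$coupling_type
  if (is.null(dmax)) return(rep(1, nrow(measurements)))
  out <- dmax[ct]
  out[is.na(out)] <- 1
  unname(out)
}

#' Fit a global alignment (Saupe) tensor to RDC data
#'
#' Linear least-squares fit of the five independent components of a
#' symmetric traceless order matrix, minimizing
#' `sum_i (D_calc,i - D_exp,i)^2 / sigma_i^2` where `D_calc,i` is the
#' weighted ensemble average of `D_max,i u' S u` over the frames.  At least
#' five RDCs with non-degenerate bond orientations are required.
#'
#' @param ens an `rw_ensemble`.
#' @param weights frame weights used for the ensemble average.
#' @param measurements the `rdc` subset of an `rw_measurements`.
#' @param idx selector index matrix (same rows).
#' @param dmax named vector of per-coupling-type normalization constants in
#'   Hz (`NULL`: all 1, i.e. RDCs reported in units of D_max).
#' @return 3x3 symmetric traceless matrix of class `rw_tensor`.
#' @export
fit_alignment_tensor <- function(ens, weights, measurements, idx,
                                 dmax = NULL) {
  m <- nrow(measurements)
  if (m < 5) stop("underdetermined: need at least 5 RDCs, got ", m)
  uv <- rdc_unit_vectors(ens, measurements, idx)
  dm <- rdc_dmax_values(measurements, dmax)
  A <- t(vapply(seq_len(m), function(i) {
    rows <- apply(uv[[i]], 2, saupe_design_row)   # 5 x n
    dm[i] * as.vector(rows %*% weights)
  }, numeric(5)))
  wts <- 1 / measurements$sigma^2
  Aw <- A * sqrt(wts)
  bw <- measurements$value * sqrt(wts)
  qrA <- qr(Aw)
  if (qrA$rank < 5)
    stop("unidentifiable tensor: degenerate bond orientations ",
         "(design rank ", qrA$rank, " < 5)")
  s <- qr.coef(qrA, bw)
  saupe_from_params(s)
}

#' Per-frame RDC rows under a fixed alignment tensor
#'
#' Entry (i, j) is `D_max,i * u_ij' S u_ij` with `u_ij` the unit bond vector
#' of measurement i in frame j (transform `"linear"`).
#'
#' @inheritParams fit_alignment_tensor
#' @param tensor an `rw_tensor`.
#' @return `rw_obsmat` with transform `"linear"`.
#' @export
rdc_observable_rows <- function(ens, tensor, measurements, idx,
                                dmax = NULL) {
  m <- nrow(measurements)
  F <- matrix(NA_real_, m, ens$n_frames)
  if (m > 0) {
    uv <- rdc_unit_vectors(ens, measurements, idx)
    dm <- rdc_dmax_values(measurements, dmax)
    for (i in seq_len(m))
      F[i, ] <- dm[i] * colSums(uv[[i]] * (unclass(tensor) %*% uv[[i]]))
  }
  observable_matrix(F, measurements$id, transform = "linear",
                    fexp = measurements$value, sigma = measurements$sigma)
}

#' Build the full linear-space observable matrix for a measurement set
#'
#' Dispatches on observable class (NOE rows in r^-6 space, couplings and
#' RDCs linear), fits the alignment tensor on the prior weights when RDCs
#' are present and none is supplied, and stacks everything into one matrix
#' whose rows average linearly under frame weights.  Row order follows the
#' measurement table.
#'
#' @param ens an `rw_ensemble`.
#' @param measurements an `rw_measurements` table.
#' @param weights prior weights (used only for the tensor fit).
#' @param karplus Karplus coefficient table.
#' @param dmax RDC normalization constants (see [fit_alignment_tensor()]).
#' @param tensor optional pre-fitted `rw_tensor`.
#' @return `rw_obsmat` over all measurements (linear-averaging space), with
#'   the fitted tensor attached as attribute `tensor` when RDCs are present.
#' @export
build_observable_matrix <- function(ens, measurements,
                                    weights = uniform_weights(ens),
                                    karplus = karplus_table(),
                                    dmax = NULL, tensor = NULL) {
  idx <- bind_selectors(measurements, ens)
  parts <- list()
  cls <- measurements$class
  if (any(cls == "noe_distance"))
    parts$noe <- noe_observable_rows(ens, measurements[cls == "noe_distance", ],
                                     idx[cls == "noe_distance", , drop = FALSE])
  if (any(cls == "scalar_coupling"))
    parts$j <- coupling_observable_rows(
      ens, measurements[cls == "scalar_coupling", ],
      idx[cls == "scalar_coupling", , drop = FALSE], table = karplus)
  if (any(cls == "rdc")) {
    sub <- measurements[cls == "rdc", ]
    sidx <- idx[cls == "rdc", , drop = FALSE]
    if (is.null(tensor))
      tensor <- fit_alignment_tensor(ens, weights, sub, sidx, dmax = dmax)
    parts$rdc <- rdc_observable_rows(ens, tensor, sub, sidx, dmax = dmax)
  }
  out <- do.call(rbind_obsmat, unname(parts))
  # restore original measurement order
  ord <- match(measurements$id, out$ids)
  out <- observable_matrix(out$F[ord, , drop = FALSE], out$ids[ord],
                           transform = "linear",
                           fexp = out$fexp[ord], sigma = out$sigma[ord])
  attr(out, "tensor") <- tensor
  out
}

#' Back-transform a linear-space average to the reporting space
#'
#' NOE rows live in r^-6 space; their averages are mapped back to distances
#' by `x^(-1/6)`.  Other classes are identity.
#'
#' @param avg linear-space averages.
#' @param classes observable classes (same length).
#' @return values in reporting units (Angstrom / Hz).
#' @export
back_transform_average <- function(avg, classes) {
  ifelse(classes == "noe_distance", avg^(-1 / 6), avg)
}
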