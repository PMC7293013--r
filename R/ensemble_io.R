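# Ensemble containers and I/O.
#
# An ensemble is a shared topology (atom/residue table) plus n frames of
# Cartesian coordinates in Angstrom.  All downstream modules (forward models,
# eRMSD, torsions, BME) consume this data model.

#' Construct an ensemble
#'
#' @param atoms data.frame with columns `atom` (PDB atom name), `resname`
#'   (residue name, e.g. A/C/G/U), `resno` (1-based residue index, 5'->3'),
#'   `chain` (chain identifier).
#' @param xyz numeric array of dimension `c(n_atoms, 3, n_frames)`,
#'   coordinates in Angstrom.
#' @return object of class `rw_ensemble` with elements `atoms`, `xyz`,
#'   `n_frames`, `n_atoms`.
#' @export
ensemble <- function(atoms, xyz) {
  stopifnot(is.data.frame(atoms))
  req <- c("atom", "resname", "resno", "chain")
  if (!all(req %in% names(atoms)))
    stop("atoms table must have columns: ", paste(req, collapse = ", "))
  if (length(dim(xyz)) == 2) xyz <- array(xyz, dim = c(dim(xyz), 1))
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[2] == 3)
  if (dim(xyz)[1] != nrow(atoms))
    stop("xyz atom count (", dim(xyz)[1], ") does not match atoms table (",
         nrow(atoms), ")")
  if (dim(xyz)[3] < 1) stop("ensemble must contain at least one frame")
  if (nrow(atoms) == 0) stop("ensemble has zero atoms")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in ensemble")
  key <- paste(atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate (residue index, atom name) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  structure(list(atoms = atoms, xyz = xyz,
                 n_frames = dim(xyz)[3], n_atoms = nrow(atoms)),
            class = "rw_ensemble")
}

#' @export
print.rw_ensemble <- function(x, ...) {
  cat("<rw_ensemble> ", x$n_frames, " frame(s), ", x$n_atoms, " atoms, ",
      length(unique(x$atoms$resno)), " residues\n", sep = "")
  invisible(x)
}

#' Extract one frame as a conformation
#'
#' @param ens an `rw_ensemble`.
#' @param frame 1-based frame index.
#' @return object of class `rw_conformation`: list with `atoms` and an
#'   `n_atoms x 3` coordinate matrix `xyz`.
#' @export
get_conformation <- function(ens, frame = 1) {
  stopifnot(inherits(ens, "rw_ensemble"))
  if (frame < 1 || frame > ens$n_frames) stop("frame index out of range")
  structure(list(atoms = ens$atoms, xyz = ens$xyz[, , frame, drop = TRUE]),
            class = "rw_conformation")
}

#' Coordinates of a named atom
#' @param conf an `rw_conformation`.
#' @param resno residue index.
#' @param atom atom name.
#' @keywords internal
atom_xyz <- function(conf, resno, atom) {
  i <- which(conf$atoms$resno == resno & conf$atoms$atom == atom)
  if (length(i) != 1) return(NULL)
  conf$xyz[i, ]
}

#' Normalized per-frame weights
#'
#' @param w non-negative numeric vector; normalized to sum to one.
#' @param tag `"prior"` or `"refined"`.
#' @param provenance free-text note (`"uniform"`, `"metadynamics-bias"`,
#'   `"BME"`, ...).
#' @return numeric vector of class `rw_weights` summing to one.
#' @export
weight_set <- function(w, tag = c("prior", "refined"), provenance = "uniform") {
  tag <- match.arg(tag)
  if (!all(is.finite(w))) stop("non-finite weights")
  if (any(w < 0)) stop("negative weights")
  s <- sum(w)
  if (s <= 0) stop("weights sum to zero")
  structure(as.numeric(w / s), class = "rw_weights",
            tag = tag, provenance = provenance)
}

#' Uniform prior weights for an ensemble
#' @param n number of frames (or an `rw_ensemble`).
#' @export
uniform_weights <- function(n) {
  if (inherits(n, "rw_ensemble")) n <- n$n_frames
  weight_set(rep(1 / n, n), tag = "prior", provenance = "uniform")
}

#' Read a (possibly multi-model) PDB file as an ensemble
#'
#' Each MODEL record becomes one frame; a single-structure PDB yields a
#' one-frame ensemble.  The topology is taken from the first model; models
#' with a deviating atom count are rejected.  Parsing is delegated to
#' \code{bio3d::read.pdb}.
#'
#' @param path path to a PDB file.
#' @return an `rw_ensemble`.
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0) stop("PDB file contains zero atoms: ", path)
  n_at <- nrow(at)
  x <- pdb$xyz
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != 3 * n_at)
    stop("inconsistent models: coordinate records do not match the ",
         "first model's atom count")
  n_fr <- nrow(x)
  xyz <- array(NA_real_, dim = c(n_at, 3, n_fr))
  for (f in seq_len(n_fr))
    xyz[, , f] <- matrix(x[f, ], ncol = 3, byrow = TRUE)
  atoms <- data.frame(atom = at$elety, resname = at$resid,
                      resno = at$resno,
                      chain = ifelse(is.na(at$chain), "A", at$chain),
                      stringsAsFactors = FALSE)
  ensemble(atoms, xyz)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL record per frame, fixed-width PDB columns; readable back by
#' [read_multimodel_pdb()] with atom order and names preserved.
#'
#' @param ens an `rw_ensemble`.
#' @param path output file path.
#' @export
write_multimodel_pdb <- function(ens, path) {
  stopifnot(inherits(ens, "rw_ensemble"))
  at <- ens$atoms
  # PDB name field (cols 13-16): names up to 3 chars start in column 14
  fmt_name <- function(a) {
    ifelse(nchar(a) >= 4, substr(a, 1, 4), sprintf(" %-3s", a))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(ens$n_frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- ens$xyz[, , f, drop = TRUE]
    lines <- sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                     seq_len(nrow(at)), fmt_name(at$atom), at$resname,
                     substr(at$chain, 1, 1), at$resno,
                     xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory with a separate topology
#'
#' Supported trajectory formats: multi-model PDB (coordinates already in
#' Angstrom) and DCD (read via \code{bio3d::read.dcd}).  Coordinates are
#' converted to Angstrom on read: set `units = "nm"` for sources written in
#' nanometres.  Frame order is preserved.
#'
#' @param topology path to a PDB file defining the atom/residue tables.
#' @param trajectory path to a multi-model PDB or DCD file.
#' @param units `"angstrom"` (default) or `"nm"`.
#' @return an `rw_ensemble`.
#' @export
read_trajectory <- function(topology, trajectory, units = c("angstrom", "nm")) {
  units <- match.arg(units)
  if (!file.exists(topology)) stop("file not found: ", topology)
  if (!file.exists(trajectory)) stop("file not found: ", trajectory)
  top <- read_multimodel_pdb(topology)
  ext <- tolower(tools::file_ext(trajectory))
  if (ext == "dcd") {
    x <- bio3d::read.dcd(trajectory, verbose = FALSE)
  } else {
    tr <- read_multimodel_pdb(trajectory)
    x <- t(apply(tr$xyz, 3, function(m) as.vector(t(m))))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(x) == 0) stop("trajectory contains zero frames")
  if (ncol(x) != 3 * top$n_atoms)
    stop("atom-count mismatch: topology has ", top$n_atoms,
         " atoms, trajectory frames have ", ncol(x) / 3)
  if (units == "nm") x <- x * 10
  xyz <- array(NA_real_, dim = c(top$n_atoms, 3, nrow(x)))
  for (f in seq_len(nrow(x)))
    xyz[, , f] <- matrix(x[f, ], ncol = 3, byrow = TRUE)
  ensemble(top$atoms, xyz)
}

#' Prior weights from a metadynamics bias potential
#'
#' Final-bias reweighting: each frame's prior weight is proportional to
#' `exp(sign * V_j / (kB T))` with `V_j` the deposited bias energy at frame j
#' in kJ/mol.  The result is invariant to adding a constant to all bias
#' values.  Deposited files sometimes store the negative of the bias; flip
#' with `sign = -1`.
#'
#' @param bias_energies numeric vector, one finite value per frame (kJ/mol).
#' @param temperature simulation temperature in Kelvin.
#' @param sign `+1` (default) or `-1`.
#' @return an `rw_weights` prior weight set.
#' @export
bias_to_prior_weights <- function(bias_energies, temperature, sign = 1) {
  if (!all(is.finite(bias_energies))) stop("non-finite bias energies")
  if (temperature <= 0) stop("temperature must be positive")
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1")
  z <- sign * bias_energies / (KB_KJ_MOL * temperature)
  z <- z - max(z)  # shift-invariant, avoids overflow
  weight_set(exp(z), tag = "prior", provenance = "metadynamics-bias")
}

#' Read/write a 2-column TSV of per-frame values
#'
#' Format: frame-id then value, tab-separated, `#` comment lines allowed.
#' Frame ids in files are 0-based.
#'
#' @param path file path.
#' @return numeric vector ordered by frame id.
#' @export
read_frame_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         col.names = c("frame", "value"))
  d <- d[order(d$frame), ]
  d$value
}

#' @rdname read_frame_table
#' @param values numeric vector (frame order).
#' @export
write_frame_table <- function(values, path) {
  lines <- sprintf("%d\t%.12g", seq_along(values) - 1L, values)
  writeLines(c("# frame\tvalue", lines), path)
  invisible(path)
}
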