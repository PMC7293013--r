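# Synthetic two-state ensembles with known ground truth.
#
# The generator emulates the study design every downstream stage needs: a
# hairpin-like 14-mer of pseudo-nucleotides in which a major state A keeps
# two designated loop ring-ring contacts short (< 5 A) and a marker zeta
# torsion in the gauche+ well, while a minor state B opens those contacts
# (> 8 A) and flips the torsion to gauche-.  Frames are drawn from the two
# rigid templates with Gaussian coordinate jitter; "experimental" averages
# are computed under known true weights and perturbed with Gaussian noise.
# Pseudo-nucleotides use idealized hexagonal rings and a simplified
# backbone: every forward model and metric in the package depends only on
# named atoms and geometry, not on chemical realism.

# --- rigid pseudo-nucleotide unit (local coordinates, Angstrom) ----------
# Ring centroid at the origin; sugar/backbone hangs off N1 (all residues
# share the layout; purines carry an extra glycosidic N9 near C1').
UNIT_TEMPLATE <- local({
  m <- rbind(
    "N1"  = c( 0.000,  1.390,  0.000),
    "C2"  = c( 1.204,  0.695,  0.000),
    "N3"  = c( 1.204, -0.695,  0.000),
    "C4"  = c( 0.000, -1.390,  0.000),
    "C5"  = c(-1.204, -0.695,  0.000),
    "C6"  = c(-1.204,  0.695,  0.000),
    "H6"  = c(-2.140,  1.240,  0.000),
    "C1'" = c( 0.000,  2.850,  0.450),
    "H1'" = c( 0.850,  2.950, -0.250),
    "O4'" = c(-1.150,  3.450,  1.050),
    "C4'" = c(-0.950,  4.850,  1.350),
    "C3'" = c( 0.550,  5.150,  1.250),
    "O3'" = c( 0.850,  6.350,  1.950),
    "C5'" = c(-1.750,  5.350,  2.500),
    "N9"  = c( 0.600,  1.900,  0.200))
  colnames(m) <- c("x", "y", "z")
  m
})

# 5'-terminal phosphate group, placed from the unit itself (no predecessor)
TERMINAL_P <- rbind("P" = c(-4.30, 6.30, 3.60), "O5'" = c(-2.95, 5.75, 3.05))

DEFAULT_SEQUENCE <- c("G", "G", "C", "A", "C", "U", "U", "C", "G",
                      "G", "U", "G", "C", "C")
PURINES <- c("A", "G")

# Ring-center waypoints (Angstrom) for the two template conformers.  Stem
# residues form two antiparallel stacks; the loop (residues 6-9) is either
# closed (contacts 6-8 and 6-9 under 5 A) or swung open (over 8 A).
ring_center_layout <- function(state = c("A", "B"), loop_gap = 1) {
  state <- match.arg(state)
  p <- matrix(NA_real_, 14, 3)
  for (r in 1:5)   p[r, ] <- c(0.0, 0.0, 3.3 * (r - 1))
  for (r in 10:14) p[r, ] <- c(6.5, 0.0, 3.3 * (14 - r))
  p[6, ] <- c(1.5, 2.5, 15.5)
  p[7, ] <- c(1.0, 6.5, 17.5)
  p[8, ] <- c(4.3, 4.6, 16.3)
  p[9, ] <- c(5.3, 1.2, 15.2)
  if (state == "B") {
    # only the two designated contact partners move: residue 7 bridges the
    # open loop, so among residue-6 ring contacts exactly 6-8 and 6-9
    # discriminate the states
    open8 <- c(4.5, 10.5, 20.5)
    open9 <- c(9.5,  6.0, 18.0)
    p[8, ] <- p[8, ] + loop_gap * (open8 - p[8, ])
    p[9, ] <- p[9, ] + loop_gap * (open9 - p[9, ])
  }
  p
}

# Per-residue rigid rotations: helical twist in the stems, tilted loop bases.
unit_rotations <- function() {
  R <- vector("list", 14)
  for (r in 1:5)   R[[r]] <- rotation_matrix(c(0, 0, 1), 25 * (r - 1))
  for (r in 10:14) R[[r]] <- rotation_matrix(c(0, 0, 1), 180 + 25 * (14 - r))
  for (r in 6:9)
    R[[r]] <- rotation_matrix(c(0, 0, 1), 40 * r) %*%
      rotation_matrix(c(1, 0, 0), 65)
  R
}

# NeRF internal-coordinate placement: position D bonded to C with given
# bond length, angle B-C-D and torsion A-B-C-D (degrees).
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- cross3(ab, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + cbind(bc, m, n) %*% d2
}

# Build one template conformation.  zeta_targets: named numeric, degrees,
# zeta of residue r (defined between r and r+1); default +55 everywhere.
build_template <- function(state = "A", sequence = DEFAULT_SEQUENCE,
                           zeta = rep(55, 13), epsilon_fixed = -150,
                           loop_gap = 1) {
  centers <- ring_center_layout(state, loop_gap)
  rots <- unit_rotations()
  n_res <- length(sequence)
  atoms <- list(); coords <- list()
  placed <- vector("list", n_res)  # per-residue named coordinate rows
  for (r in seq_len(n_res)) {
    keep <- rownames(UNIT_TEMPLATE)
    if (!sequence[r] %in% PURINES) keep <- setdiff(keep, "N9")
    loc <- UNIT_TEMPLATE[keep, , drop = FALSE]
    glob <- t(rots[[r]] %*% t(loc)) +
      matrix(centers[r, ], nrow(loc), 3, byrow = TRUE)
    rownames(glob) <- keep
    placed[[r]] <- glob
  }
  # connect residues: P and O5' of residue r+1 are placed from residue r's
  # C4'-C3'-O3' with fixed epsilon and the residue-r zeta target, so the
  # marker torsion is controlled exactly.
  for (r in seq_len(n_res)) {
    if (r == 1) {
      extra <- t(rots[[1]] %*% t(TERMINAL_P)) +
        matrix(centers[1, ], 2, 3, byrow = TRUE)
      rownames(extra) <- rownames(TERMINAL_P)
    } else {
      prev <- placed[[r - 1]]
      P <- place_atom(prev["C4'", ], prev["C3'", ], prev["O3'", ],
                      1.60, 119, epsilon_fixed)
      O5 <- place_atom(prev["C3'", ], prev["O3'", ], as.vector(P),
                       1.59, 120, zeta[r - 1])
      extra <- rbind(as.vector(P), as.vector(O5))
      rownames(extra) <- c("P", "O5'")
    }
    placed[[r]] <- rbind(extra, placed[[r]])
  }
  tab <- do.call(rbind, lapply(seq_len(n_res), function(r)
    data.frame(atom = rownames(placed[[r]]), resname = sequence[r],
               resno = r, chain = "A", stringsAsFactors = FALSE)))
  xyz <- do.call(rbind, placed)
  rownames(xyz) <- NULL
  list(atoms = tab, xyz = xyz)
}

check_clashes <- function(xyz, min_dist = 0.5) {
  d <- stats::dist(xyz)
  if (any(d < min_dist))
    stop("geometry config produces atom clashes below ", min_dist, " A ",
         "(closest pair ", format(min(d), digits = 3), " A)")
  invisible(TRUE)
}

#' Generate a synthetic two-state ensemble with known truth
#'
#' Frames are drawn from two rigid hairpin templates: state A with the loop
#' closed (ring contacts 6-8 and 6-9 below 5 A, residue-8 zeta in the
#' gauche+ well) and state B with the loop open (contacts above 8 A, zeta in
#' gauche-), plus isotropic Gaussian coordinate jitter.  The fraction of
#' frames built from each template is `frame_fraction_a`; the *true* frame
#' weights are uniform within each state and scaled so that the true
#' population of state A is `population_a`.  A uniform prior over frames
#' therefore starts at population `frame_fraction_a` and reweighting must
#' recover `population_a`.
#'
#' @param n_frames number of frames (>= 10), default 200.
#' @param population_a true state-A population in (0, 1), default 0.6.
#' @param seed RNG seed (recorded in the truth).
#' @param frame_fraction_a fraction of frames from template A (default 0.5;
#'   rounded to the nearest count with at least one frame per state).
#' @param jitter_sd per-coordinate Gaussian jitter in Angstrom
#'   (default 0.15).
#' @param zeta_a,zeta_b residue-8 zeta targets (degrees) for the two
#'   templates (defaults +55 / -70).
#' @param loop_gap scale of the template-B loop opening (1 = default
#'   geometry; larger values open the loop further).
#' @return list: `ensemble` (`rw_ensemble`), `truth` (class `rw_truth`:
#'   `weights_true`, `labels`, `population_a`, `seed`, `params`),
#'   `template_a`, `template_b` (`rw_conformation`s).
#' @export
make_two_state_ensemble <- function(n_frames = 200, population_a = 0.6,
                                    seed = 1, frame_fraction_a = 0.5,
                                    jitter_sd = 0.15,
                                    zeta_a = 55, zeta_b = -70,
                                    loop_gap = 1) {
  if (n_frames < 10) stop("n_frames must be at least 10")
  if (population_a <= 0 || population_a >= 1)
    stop("population_a must be strictly inside (0, 1)")
  zeta <- rep(55, 13)
  za <- zb <- zeta
  za[8] <- zeta_a; zb[8] <- zeta_b
  tA <- build_template("A", zeta = za, loop_gap = loop_gap)
  tB <- build_template("B", zeta = zb, loop_gap = loop_gap)
  check_clashes(tA$xyz); check_clashes(tB$xyz)
  # nearest-count rounding, at least one frame per state
  n_a <- min(max(round(n_frames * frame_fraction_a), 1L), n_frames - 1L)
  labels <- factor(rep(c("A", "B"), c(n_a, n_frames - n_a)),
                   levels = c("A", "B"))
  n_at <- nrow(tA$atoms)
  xyz <- array(NA_real_, dim = c(n_at, 3, n_frames))
  with_seed(seed, {
    for (f in seq_len(n_frames)) {
      base <- if (labels[f] == "A") tA$xyz else tB$xyz
      xyz[, , f] <- base + matrix(stats::rnorm(n_at * 3, sd = jitter_sd),
                                  n_at, 3)
    }
  })
  ens <- ensemble(tA$atoms, xyz)
  w_true <- ifelse(labels == "A", population_a / n_a,
                   (1 - population_a) / (n_frames - n_a))
  truth <- structure(list(
    weights_true = weight_set(w_true, tag = "prior",
                              provenance = "synthetic-truth"),
    labels = labels,
    population_a = population_a,
    seed = seed,
    params = list(n_frames = n_frames, frame_fraction_a = frame_fraction_a,
                  jitter_sd = jitter_sd, zeta_a = zeta_a, zeta_b = zeta_b,
                  loop_gap = loop_gap)), class = "rw_truth")
  list(ensemble = ens,
       truth = truth,
       template_a = structure(list(atoms = tA$atoms, xyz = tA$xyz),
                              class = "rw_conformation"),
       template_b = structure(list(atoms = tB$atoms, xyz = tB$xyz),
                              class = "rw_conformation"))
}

# Deterministic measurement design over the 14-mer: sequential and loop
# NOE proton pairs, zeta couplings, C1'-H1' RDC bonds.
synthetic_measurement_design <- function() {
  noe_pairs <- list()
  for (r in 1:13) noe_pairs[[length(noe_pairs) + 1]] <-
    c(r, "H1'", r + 1, "H6")                       # 13 sequential
  for (r in 1:12) noe_pairs[[length(noe_pairs) + 1]] <-
    c(r, "H1'", r + 2, "H1'")                      # 12 next-nearest
  for (p in list(c(6, 8), c(6, 9), c(5, 10), c(4, 11), c(7, 9)))
    noe_pairs[[length(noe_pairs) + 1]] <- c(p[1], "H6", p[2], "H6")  # 5 contacts
  coupling_res <- 2:11                             # 10 zeta couplings
  rdc_res <- c(2, 3, 5, 6, 8, 9, 11, 13)           # 8 C1'-H1' bonds
  list(noe = noe_pairs, coupling = coupling_res, rdc = rdc_res)
}

# Fixed generator alignment tensor (dimensionless, RDCs in units of D_max)
GENERATOR_TENSOR <- local({
  saupe_from_params(c(-0.40, -0.10, 0.10, 0.05, -0.08))
})

# Per-class sigma scales: noise_scale is a relative level; reported sigma =
# noise_scale * class scale (1 A for NOE, 5 Hz couplings, 0.5 Hz RDC).
NOISE_CLASS_SCALE <- c(noe_distance = 1.0, scalar_coupling = 5.0, rdc = 0.5)

#' Generate noisy ensemble-averaged synthetic measurements
#'
#' NOE distances are generated as the r^-6 ensemble average under the true
#' weights plus Gaussian noise; scalar couplings as linear true-weight
#' averages of Karplus values; RDCs from a fixed generator tensor.  The
#' reported sigma equals the noise standard deviation (an "honest" error
#' model): `sigma_i = noise_scale * class_scale` with class scales 1 A
#' (NOE), 5 Hz (couplings), 0.5 Hz (RDC).  With `noise_scale = 0` the data
#' are exact averages and sigma falls back to a small positive floor.
#'
#' @param bundle output of [make_two_state_ensemble()].
#' @param noise_scale relative noise level (>= 0), default 0.05.
#' @param seed RNG seed for the noise draws.
#' @return an `rw_measurements` table (datasets labelled "synthetic").
#' @export
make_synthetic_measurements <- function(bundle, noise_scale = 0.05,
                                        seed = 1) {
  if (noise_scale < 0) stop("noise_scale must be non-negative")
  ens <- bundle$ensemble
  w <- as.numeric(bundle$truth$weights_true)
  des <- synthetic_measurement_design()
  rows <- list()
  for (k in seq_along(des$noe)) {
    p <- des$noe[[k]]
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("noe_%02d", k), class = "noe_distance",
      resid1 = as.integer(p[1]), atom1 = p[2],
      resid2 = as.integer(p[3]), atom2 = p[4],
      value = NA_real_, sigma = NA_real_, dataset = "synthetic",
      stringsAsFactors = FALSE)
  }
  for (r in des$coupling) {
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("j_zeta_%02d", r), class = "scalar_coupling",
      resid1 = r, atom1 = "C3'", resid2 = r, atom2 = "O3'",
      value = NA_real_, sigma = NA_real_, dataset = "synthetic",
      stringsAsFactors = FALSE)
  }
  for (r in des$rdc) {
    rows[[length(rows) + 1]] <- data.frame(
      id = sprintf("rdc_%02d", r), class = "rdc",
      resid1 = r, atom1 = "C1'", resid2 = r, atom2 = "H1'",
      value = NA_real_, sigma = NA_real_, dataset = "synthetic",
      stringsAsFactors = FALSE)
  }
  meas <- do.call(rbind, rows)
  meas$torsion_name <- ifelse(meas$class == "scalar_coupling", "zeta",
                              NA_character_)
  meas$coupling_type <- ifelse(meas$class == "scalar_coupling", "generic",
                               ifelse(meas$class == "rdc", "C1'H1'",
                                      NA_character_))
  meas$sense <- "equality"
  # placeholder values so validation passes before truth values are filled
  meas$value <- 1; meas$sigma <- 1
  meas <- as_measurements(meas)
  idx <- bind_selectors(meas, ens)
  cls <- meas$class
  # noiseless true averages via the package forward models
  noe <- noe_observable_rows(ens, meas[cls == "noe_distance", ],
                             idx[cls == "noe_distance", , drop = FALSE])
  true_noe <- (as.vector(noe$F %*% w))^(-1 / 6)
  cpl <- coupling_observable_rows(ens, meas[cls == "scalar_coupling", ],
                                  idx[cls == "scalar_coupling", , drop = FALSE])
  true_j <- as.vector(cpl$F %*% w)
  rdc <- rdc_observable_rows(ens, GENERATOR_TENSOR, meas[cls == "rdc", ],
                             idx[cls == "rdc", , drop = FALSE])
  true_d <- as.vector(rdc$F %*% w)
  sig <- NOISE_CLASS_SCALE[cls] * max(noise_scale, 1e-6)
  truevals <- numeric(nrow(meas))
  truevals[cls == "noe_distance"] <- true_noe
  truevals[cls == "scalar_coupling"] <- true_j
  truevals[cls == "rdc"] <- true_d
  noise <- with_seed(seed,
    stats::rnorm(nrow(meas), sd = NOISE_CLASS_SCALE[cls] * noise_scale))
  meas$value <- truevals + noise
  # a noise draw must not push an NOE distance non-positive
  bad <- cls == "noe_distance" & meas$value <= 0.5
  meas$value[bad] <- 0.5
  meas$sigma <- unname(sig)
  as_measurements(as.data.frame(meas))
}

#' Population-recovery experiment over a noise ladder
#'
#' For each noise level and seed: generate a two-state ensemble and noisy
#' measurements, refine a uniform prior by BME (theta chosen by k-fold
#' cross-validation), and compare the refined state-A population (frames
#' labelled by eRMSD to the state-A template) with the known truth.
#'
#' @param n_frames frames per ensemble.
#' @param population_a true population (scalar).
#' @param noise_ladder vector of noise scales.
#' @param seeds vector of generator seeds.
#' @param theta_grid candidate theta values for cross-validation.
#' @param ermsd_threshold state threshold (default 0.7).
#' @return list: `runs` (one row per noise x seed: populations, chi2 before
#'   and after, theta, phi_eff), `summary` (bias and RMSE per noise level).
#' @export
recovery_experiment <- function(n_frames = 200, population_a = 0.6,
                                noise_ladder = c(0.01, 0.05, 0.2),
                                seeds = 1:3,
                                theta_grid = 10^seq(-2, 4, length.out = 7),
                                ermsd_threshold = 0.7) {
  runs <- list()
  for (ns in noise_ladder) for (sd_ in seeds) {
    bundle <- make_two_state_ensemble(n_frames = n_frames,
                                      population_a = population_a,
                                      seed = sd_)
    meas <- make_synthetic_measurements(bundle, noise_scale = ns,
                                        seed = sd_ + 1000)
    ens <- bundle$ensemble
    w0 <- uniform_weights(ens)
    om <- build_observable_matrix(ens, meas, weights = w0)
    sel <- select_theta(om, w0, theta_grid = theta_grid, seed = sd_)
    prob <- bme_problem(om, w0, theta = sel$theta)
    res <- bme_solve(prob)
    ev <- ermsd_traj(ens, bundle$template_a)
    lab <- assign_states(ev, ermsd_threshold)
    runs[[length(runs) + 1]] <- data.frame(
      noise = ns, seed = sd_, theta = sel$theta,
      pop_true = bundle$truth$population_a,
      pop_prior = population(lab, w0),
      pop_recovered = population(lab, res$weights),
      chi2_before = res$chi2_before, chi2_after = res$chi2_after,
      phi_eff = res$phi_eff)
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$noise), function(d)
    data.frame(noise = d$noise[1],
               bias = mean(d$pop_recovered - d$pop_true),
               rmse = sqrt(mean((d$pop_recovered - d$pop_true)^2)))))
  rownames(summ) <- NULL
  list(runs = runs, summary = summ)
}

#' Write a synthetic bundle to disk
#'
#' Writes the ensemble (multi-model PDB), the measurement table (TSV), the
#' true weights (frame TSV) and a truth JSON; the same formats the pipeline
#' reads back.  Byte-identical for identical (seed, config).
#'
#' @param bundle output of [make_two_state_ensemble()].
#' @param measurements an `rw_measurements` table.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_synthetic_bundle <- function(bundle, measurements, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(ensemble = file.path(dir, "ensemble.pdb"),
             reference = file.path(dir, "template_a.pdb"),
             measurements = file.path(dir, "measurements.tsv"),
             weights = file.path(dir, "weights_true.tsv"),
             truth = file.path(dir, "truth.json"))
  write_multimodel_pdb(bundle$ensemble, files["ensemble"])
  ref <- bundle$template_a
  write_multimodel_pdb(ensemble(ref$atoms, array(ref$xyz,
                                                 dim = c(nrow(ref$xyz), 3, 1))),
                       files["reference"])
  write_measurements(measurements, files["measurements"])
  write_frame_table(as.numeric(bundle$truth$weights_true), files["weights"])
  truth <- bundle$truth
  jsonlite::write_json(
    list(population_a = truth$population_a, seed = truth$seed,
         labels = as.character(truth$labels),
         weights_true = as.numeric(truth$weights_true),
         params = truth$params),
    files["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(files)
}
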