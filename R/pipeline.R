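# Pipeline drivers: simulate / refine / classify, driven by a validated
# run configuration.  These functions are the package's batch interface; a
# thin command-line wrapper over them ships in inst/scripts/rnareweight.R.

#' Read and validate a run configuration
#'
#' YAML file with sections `inputs` (ensemble, reference, measurements,
#' optional bias/weights files), `refine` (theta_grid, cv_folds,
#' ermsd_threshold, train_dataset), `classify` (n_samples, max_depth,
#' cutoff, ring_pairs), `seeds` (named integer seeds) and `outdir`.
#' Referenced input files must exist at validation time; seeds must be
#' explicit.
#'
#' @param path YAML file path, or a list already in memory.
#' @return validated config list of class `rw_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(
    refine = list(theta_grid = 10^seq(-2, 4, length.out = 13),
                  cv_folds = 5, ermsd_threshold = 0.7,
                  train_dataset = NULL),
    classify = list(n_samples = 50000, max_depth = 2, cutoff = 0.2,
                    train_fraction = 0.8, n_trees = 100,
                    ring_pairs = NULL),
    simulate = list(n_frames = 200, population_a = 0.6,
                    frame_fraction_a = 0.5, noise_scale = 0.05),
    outdir = "rnareweight_out")
  for (sec in names(defaults)) {
    if (!sec %in% names(cfg)) cfg[[sec]] <- defaults[[sec]]
    else if (is.list(defaults[[sec]]))
      for (k in setdiff(names(defaults[[sec]]), names(cfg[[sec]])))
        cfg[[sec]][[k]] <- defaults[[sec]][[k]]
  }
  if (is.null(cfg$seeds) || is.null(cfg$seeds$master))
    stop("config must set an explicit seeds: master entry")
  for (f in unlist(cfg$inputs))
    if (!file.exists(f)) stop("configured input file not found: ", f)
  class(cfg) <- c("rw_config", "list")
  cfg
}

write_provenance <- function(cfg, outdir, extra = list()) {
  prov <- c(list(
    config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)),
                                      collapse = ""))),
    seeds = cfg$seeds,
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("rnareweight")),
    timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Generate and write a synthetic bundle
#'
#' @param cfg an `rw_config` (or path to one).
#' @return invisible file manifest (named character vector).
#' @export
run_simulate <- function(cfg) {
  if (!inherits(cfg, "rw_config")) cfg <- read_run_config(cfg)
  sc <- cfg$simulate
  bundle <- make_two_state_ensemble(
    n_frames = sc$n_frames, population_a = sc$population_a,
    seed = cfg$seeds$master, frame_fraction_a = sc$frame_fraction_a)
  meas <- make_synthetic_measurements(bundle, noise_scale = sc$noise_scale,
                                      seed = cfg$seeds$master + 1)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- write_synthetic_bundle(bundle, meas, cfg$outdir)
  write_provenance(cfg, cfg$outdir)
  message("wrote ", length(files), " files to ", cfg$outdir)
  invisible(files)
}

#' Refine an ensemble against its training dataset
#'
#' Loads the ensemble, reference and measurements named in the config,
#' builds the observable matrix, selects theta by cross-validation on the
#' training dataset, solves BME, and writes the refined weights, a
#' per-measurement report (prior/refined averages and Z-scores in both the
#' linear-averaging and the reporting space) and a JSON summary with
#' chi-squared per dataset (training flagged) and populations.
#'
#' @param cfg an `rw_config` (or path).
#' @return invisible list: `result` (`bme_result`), `theta`, `summary`.
#' @export
run_refine <- function(cfg) {
  if (!inherits(cfg, "rw_config")) cfg <- read_run_config(cfg)
  ens <- read_multimodel_pdb(cfg$inputs$ensemble)
  ref <- get_conformation(read_multimodel_pdb(cfg$inputs$reference), 1)
  meas <- parse_measurements(cfg$inputs$measurements)
  w0 <- if (!is.null(cfg$inputs$weights))
    weight_set(read_frame_table(cfg$inputs$weights), tag = "prior",
               provenance = "file")
  else if (!is.null(cfg$inputs$bias))
    bias_to_prior_weights(read_frame_table(cfg$inputs$bias),
                          temperature = cfg$inputs$temperature %||% 300)
  else uniform_weights(ens)
  train_ds <- cfg$refine$train_dataset
  if (is.null(train_ds)) train_ds <- unique(meas$dataset)[1]
  train <- meas$dataset == train_ds
  if (!any(train)) stop("no measurements in training dataset ", train_ds)
  if (all(train) && length(unique(meas$dataset)) > 1)
    warning("training dataset covers all measurements")
  om_all <- build_observable_matrix(ens, meas, weights = w0)
  om_tr <- observable_matrix(om_all$F[train, , drop = FALSE],
                             om_all$ids[train], transform = "linear",
                             fexp = om_all$fexp[train],
                             sigma = om_all$sigma[train])
  sel <- select_theta(om_tr, w0, theta_grid = cfg$refine$theta_grid,
                      k = cfg$refine$cv_folds, seed = cfg$seeds$master)
  res <- bme_solve(bme_problem(om_tr, w0, theta = sel$theta))
  ev <- ermsd_traj(ens, ref)
  lab <- assign_states(ev, cfg$refine$ermsd_threshold)
  avg0 <- average_observables(om_all, w0)
  avg1 <- average_observables(om_all, res$weights)
  rep_space0 <- back_transform_average(avg0, meas$class)
  rep_space1 <- back_transform_average(avg1, meas$class)
  report <- data.frame(
    id = meas$id, dataset = meas$dataset, class = meas$class,
    training = train, fexp = meas$value, sigma = meas$sigma,
    prior_avg = rep_space0, refined_avg = rep_space1,
    z_prior = zscore(rep_space0, meas$value, meas$sigma),
    z_refined = zscore(rep_space1, meas$value, meas$sigma))
  per_ds <- lapply(split(seq_len(nrow(meas)), meas$dataset), function(i)
    list(chi2_before = chi2(avg0[i], om_all$fexp[i], om_all$sigma[i]),
         chi2_after = chi2(avg1[i], om_all$fexp[i], om_all$sigma[i]),
         training = all(train[i])))
  summary <- list(theta = sel$theta, cv_seed = sel$seed,
                  chi2_by_dataset = per_ds,
                  phi_eff = res$phi_eff,
                  population_a_prior = population(lab, w0),
                  population_a_refined = population(lab, res$weights),
                  ermsd_threshold = cfg$refine$ermsd_threshold)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report, file.path(cfg$outdir, "refinement_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_frame_table(as.numeric(res$weights),
                    file.path(cfg$outdir, "weights_refined.tsv"))
  jsonlite::write_json(summary, file.path(cfg$outdir, "refine_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(cfg, cfg$outdir, list(stage = "refine"))
  invisible(list(result = res, theta = sel$theta, summary = summary,
                 report = report, labels = lab, weights0 = w0,
                 ensemble = ens, measurements = meas, obsmat = om_all))
}

#' Rank state-discriminating features and measurements
#'
#' Runs the bootstrap -> label -> features -> train -> rank -> select chain
#' on the refined ensemble: once on structural features (torsions and ring
#' distances) and once per dataset on back-calculated measurements.
#' Writes importance tables and the paired Z-score table comparing prior
#' and refined predictions.
#'
#' @param cfg an `rw_config` (or path).
#' @param refined output of [run_refine()] (re-run when NULL).
#' @return invisible list with `structural`, `measurement` importance
#'   tables, held-out accuracies, selected feature names and the Z pair
#'   table.
#' @export
run_classify <- function(cfg, refined = NULL) {
  if (!inherits(cfg, "rw_config")) cfg <- read_run_config(cfg)
  if (is.null(refined)) refined <- run_refine(cfg)
  cc <- cfg$classify
  ens <- refined$ensemble
  w_star <- refined$result$weights
  idx <- bootstrap_samples(ens$n_frames, w_star,
                           n_samples = cc$n_samples,
                           seed = cfg$seeds$master + 2)
  lab <- refined$labels[idx]
  ring_pairs <- cc$ring_pairs
  if (is.null(ring_pairs)) {
    rr <- sort(unique(ens$atoms$resno))
    ring_pairs <- list()
    for (a in rr) for (b in rr) if (b > a + 1)
      ring_pairs[[length(ring_pairs) + 1]] <- c(a, b)
  }
  fs <- structural_features(ens, idx, ring_pairs = ring_pairs)
  clf_s <- train_state_classifier(fs, lab, max_depth = cc$max_depth,
                                  train_fraction = cc$train_fraction,
                                  n_trees = cc$n_trees,
                                  seed = cfg$seeds$master + 3)
  imp_s <- rank_importance(clf_s)
  fm <- measurement_features(ens, idx, refined$measurements,
                             weights = refined$weights0)
  clf_m <- train_state_classifier(fm, lab, max_depth = cc$max_depth,
                                  train_fraction = cc$train_fraction,
                                  n_trees = cc$n_trees,
                                  seed = cfg$seeds$master + 4)
  imp_m <- rank_importance(clf_m)
  sel <- select_sensitive_measurements(imp_m, cc$cutoff)
  meas <- refined$measurements
  pa <- stats::setNames(
    back_transform_average(average_observables(refined$obsmat,
                                               refined$weights0),
                           meas$class), meas$id)
  pb <- stats::setNames(
    back_transform_average(average_observables(refined$obsmat, w_star),
                           meas$class), meas$id)
  zcmp <- compare_zscores(pa, pb, meas)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(imp_s, file.path(cfg$outdir, "importance_structural.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(imp_m, file.path(cfg$outdir, "importance_measurements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(zcmp$table, file.path(cfg$outdir, "zscore_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(accuracy_structural = clf_s$accuracy,
         accuracy_measurements = clf_m$accuracy,
         selected = sel, n_above = zcmp$n_above, n_below = zcmp$n_below),
    file.path(cfg$outdir, "classify_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_provenance(cfg, cfg$outdir, list(stage = "classify"))
  invisible(list(structural = imp_s, measurement = imp_m,
                 accuracy_structural = clf_s$accuracy,
                 accuracy_measurements = clf_m$accuracy,
                 selected = sel, zscores = zcmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
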