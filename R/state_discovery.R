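# Random-forest identification of state-discriminating features.
#
# Procedure: (1) bootstrap samples from the ensemble with probability equal
# to the (refined) frame weights; (2) label each sample A/B by eRMSD from
# the reference; (3) compute features per sample — torsion angles, ring
# center distances, or back-calculated experimental data; (4) train a
# random forest with maximum tree depth 2 on 80% of the samples, checking
# accuracy on the held-out 20%; (5) rank features by impurity importance
# and keep those above a cutoff.  The forest is never used as a predictor
# of interest — only its importance ranking matters.

#' Weighted bootstrap of frame indices
#'
#' Draws `n_samples` frame indices with replacement, with probability equal
#' to the frame weights; reproducible per seed.
#'
#' @param n_frames number of frames available.
#' @param weights frame weights (normalized).
#' @param n_samples number of draws, default 50000.
#' @param seed RNG seed.
#' @return integer vector of frame indices (1-based).
#' @export
bootstrap_samples <- function(n_frames, weights, n_samples = 50000,
                              seed = 1) {
  stopifnot(length(weights) == n_frames)
  if (sum(weights) <= 0) stop("all-zero weights")
  with_seed(seed,
    sample.int(n_frames, n_samples, replace = TRUE,
               prob = as.numeric(weights)))
}

#' Structural feature table for a set of samples
#'
#' Torsion angles (as sin/cos pairs, see Details) and/or ring-center
#' distances evaluated on the frames underlying each bootstrap sample.
#' Torsions are circular: encoding each angle as (sin, cos) avoids
#' wrap-around artifacts in axis-aligned tree splits; the importance of a
#' pair is summed back under the torsion's name by [rank_importance()].
#' With `torsion_encoding = "degrees"` the raw angle is used instead.
#' Torsions undefined on any frame (chain termini) are dropped, with a
#' message recording which.
#'
#' @param ens an `rw_ensemble`.
#' @param sample_idx frame index per sample (from [bootstrap_samples()]).
#' @param torsions character vector of torsion names to include (default
#'   all seven), or NULL for none.
#' @param ring_pairs list of residue index pairs for ring-center distances,
#'   or NULL.
#' @param torsion_encoding `"sincos"` (default) or `"degrees"`.
#' @return data.frame (class `rw_features`) of samples x features, with
#'   attribute `feature_kind` naming each column's kind and `group`
#'   mapping encoded columns to their parent feature.
#' @export
structural_features <- function(ens, sample_idx,
                                torsions = c("alpha", "beta", "gamma",
                                             "delta", "epsilon", "zeta",
                                             "chi"),
                                ring_pairs = NULL,
                                torsion_encoding = c("sincos", "degrees")) {
  torsion_encoding <- match.arg(torsion_encoding)
  frames <- sort(unique(sample_idx))
  per_frame <- list(); kind <- character(); group <- character()
  if (!is.null(torsions)) {
    tt <- lapply(frames, function(f)
      backbone_torsions(get_conformation(ens, f)))
    resnos <- tt[[1]]$resno
    for (tn in torsions) {
      vals <- vapply(tt, function(d) d[[tn]], numeric(length(resnos)))
      if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
      for (k in seq_along(resnos)) {
        v <- vals[k, ]
        name <- sprintf("%s_%d", tn, resnos[k])
        if (anyNA(v)) {
          message("dropping undefined torsion feature ", name)
          next
        }
        if (torsion_encoding == "sincos") {
          th <- v * pi / 180
          per_frame[[paste0(name, ".sin")]] <- sin(th)
          per_frame[[paste0(name, ".cos")]] <- cos(th)
          kind <- c(kind, "torsion_deg", "torsion_deg")
          group <- c(group, name, name)
        } else {
          per_frame[[name]] <- v
          kind <- c(kind, "torsion_deg")
          group <- c(group, name)
        }
      }
    }
  }
  if (!is.null(ring_pairs)) {
    for (p in ring_pairs) {
      name <- sprintf("ring_%d_%d", p[1], p[2])
      per_frame[[name]] <- vapply(frames, function(f)
        ring_distance(get_conformation(ens, f), p[1], p[2]), numeric(1))
      kind <- c(kind, "ring_distance_A")
      group <- c(group, name)
    }
  }
  if (!length(per_frame)) stop("no features requested")
  tab <- as.data.frame(per_frame, check.names = FALSE)
  out <- tab[match(sample_idx, frames), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("rw_features", "data.frame"),
            feature_kind = stats::setNames(kind, names(per_frame)),
            group = stats::setNames(group, names(per_frame)))
}

#' Back-calculated-observable feature table
#'
#' Single-frame forward-model values of each measurement as features: NOE
#' distances are per-frame distances in Angstrom (not r^-6 values, for
#' interpretability), couplings per-frame J values, RDCs per-frame values
#' under a fixed tensor (per-sample tensor fitting is ill-posed).
#'
#' @param ens an `rw_ensemble`.
#' @param sample_idx frame index per sample.
#' @param measurements an `rw_measurements` table.
#' @param tensor fixed `rw_tensor` for RDC rows (fitted on the prior
#'   ensemble when NULL and RDCs are present).
#' @param weights prior weights for the tensor fit.
#' @return data.frame of class `rw_features` (one column per measurement).
#' @export
measurement_features <- function(ens, sample_idx, measurements,
                                 tensor = NULL,
                                 weights = uniform_weights(ens)) {
  om <- build_observable_matrix(ens, measurements, weights = weights,
                                tensor = tensor)
  F <- om$F
  noe <- measurements$class == "noe_distance"
  F[noe, ] <- F[noe, , drop = FALSE]^(-1 / 6)
  tab <- as.data.frame(t(F[, sample_idx, drop = FALSE]))
  names(tab) <- om$ids
  kind <- rep("backcalc_observable", nrow(measurements))
  structure(tab, class = c("rw_features", "data.frame"),
            feature_kind = stats::setNames(kind, om$ids),
            group = stats::setNames(om$ids, om$ids))
}

#' Train the two-state random-forest classifier
#'
#' An ensemble of 100 randomized depth-2 decision trees (via
#' \pkg{ranger}); 80% of the samples are used for training and the held-out
#' accuracy on the remaining 20% is returned.  Deterministic per seed.
#'
#' @param features an `rw_features` (or plain) data.frame.
#' @param labels factor of per-sample state labels (two classes present).
#' @param max_depth maximum tree depth, default 2.
#' @param train_fraction fraction used for training, default 0.8.
#' @param n_trees number of trees, default 100.
#' @param seed RNG seed (train/test shuffle and forest).
#' @return list of class `rw_classifier`: `model` (ranger fit), `accuracy`
#'   (held-out), `feature_kind`, `group`, `seed`.
#' @export
train_state_classifier <- function(features, labels, max_depth = 2,
                                   train_fraction = 0.8, n_trees = 100,
                                   seed = 1) {
  stopifnot(nrow(features) == length(labels))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2)
    stop("need samples from both classes")
  if (min(table(labels)) < 2)
    stop("need at least 2 samples per class")
  n <- nrow(features)
  idx <- with_seed(seed, sample.int(n))
  n_tr <- max(2, floor(train_fraction * n))
  tr <- idx[seq_len(n_tr)]
  te <- idx[-seq_len(n_tr)]
  df <- as.data.frame(features)
  names(df) <- make.names(names(df))
  df$.state <- labels
  fit <- ranger::ranger(dependent.variable.name = ".state",
                        data = df[tr, , drop = FALSE],
                        num.trees = n_trees, max.depth = max_depth,
                        importance = "impurity", seed = seed,
                        num.threads = 1)
  pred <- stats::predict(fit, df[te, , drop = FALSE],
                         num.threads = 1)$predictions
  acc <- mean(pred == labels[te])
  structure(list(model = fit, accuracy = acc,
                 feature_names = names(features),
                 safe_names = setdiff(names(df), ".state"),
                 feature_kind = attr(features, "feature_kind"),
                 group = attr(features, "group"), seed = seed),
            class = "rw_classifier")
}

#' Rank features by impurity importance
#'
#' Importances are normalized to sum to one and sorted in descending order.
#' Columns that encode the same circular feature (sin/cos pairs) are summed
#' under the parent feature's name.
#'
#' @param classifier an `rw_classifier`.
#' @return data.frame of class `rw_importance`: `feature`, `kind`,
#'   `importance` (descending).
#' @export
rank_importance <- function(classifier) {
  if (!inherits(classifier, "rw_classifier")) stop("untrained handle")
  imp <- ranger::importance(classifier$model)
  # map mangled column names back to original, then to parent group
  orig <- classifier$feature_names[match(names(imp),
                                         classifier$safe_names)]
  group <- classifier$group
  kind <- classifier$feature_kind
  parent <- if (is.null(group)) orig else unname(group[orig])
  agg <- tapply(imp, parent, sum)
  k <- if (is.null(kind)) rep(NA_character_, length(agg))
       else unname(kind[match(names(agg), orig)])
  # a parent's kind: take the kind of any of its columns
  if (!is.null(kind)) {
    k <- vapply(names(agg), function(p)
      unname(kind[which(group == p)[1]]), character(1))
  }
  total <- sum(agg)
  score <- if (total > 0) agg / total else agg
  out <- data.frame(feature = names(agg), kind = k,
                    importance = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  class(out) <- c("rw_importance", "data.frame")
  out
}

#' Features above an importance cutoff
#'
#' @param ranking an `rw_importance` table.
#' @param cutoff strict lower bound on importance, default 0.2.
#' @return character vector of feature names, ranking order preserved.
#' @export
select_sensitive_measurements <- function(ranking, cutoff = 0.2) {
  ranking$feature[ranking$importance > cutoff]
}

#' Paired Z-score comparison of two ensembles
#'
#' For each measurement, |Z| of ensemble a's prediction versus |Z| of
#' ensemble b's, plus the counts of measurements strictly above and below
#' the diagonal (b worse, resp. a worse).
#'
#' @param predictions_a,predictions_b named numeric vectors of
#'   back-calculated averages (same measurement ids, reporting units).
#' @param measurements the `rw_measurements` table (for fexp, sigma).
#' @return list: `table` (id, z_a, z_b), `n_above` (z_b > z_a),
#'   `n_below` (z_b < z_a).
#' @export
compare_zscores <- function(predictions_a, predictions_b, measurements) {
  ids <- measurements$id
  if (!setequal(names(predictions_a), ids) ||
      !setequal(names(predictions_b), ids))
    stop("measurement id mismatch between predictions and table")
  a <- predictions_a[ids]; b <- predictions_b[ids]
  za <- zscore(a, measurements$value, measurements$sigma)
  zb <- zscore(b, measurements$value, measurements$sigma)
  tab <- data.frame(id = ids, z_a = unname(za), z_b = unname(zb),
                    stringsAsFactors = FALSE)
  list(table = tab,
       n_above = sum(tab$z_b > tab$z_a),
       n_below = sum(tab$z_b < tab$z_a))
}
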