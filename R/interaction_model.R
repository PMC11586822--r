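# Ligand-residue pair formation, ensemble training against
# configuration-level Coulomb + van der Waals labels, prediction, and the
# linear rescaling of predicted energies into interaction strengths.

#' Form ligand-residue pairs for a posed cluster
#'
#' One row per (ligand head, C-alpha) pair whose centroid distance does not
#' exceed the formation distance.
#'
#' @param graph `protein_graph` with WL attributes.
#' @param cluster featurized `cluster_model`.
#' @param pose rigid pose (`R`, `t`) applied to the cluster about its COM;
#'   NULL for the identity.
#' @param formation_distance pair formation cutoff in Angstrom (default 10).
#' @return a `pair_batch`: list with `pairs` (ligand, node index matrix),
#'   `features`, `distances` and optional labels.
#' @export
form_pairs <- function(graph, cluster, pose = NULL,
                       formation_distance = 10.0) {
  heads <- cluster$head_centroids
  if (!is.null(pose)) heads <- apply_pose(heads, pose, cluster$com)
  d <- cross_dist(heads, graph$ca)
  sel <- which(d <= formation_distance, arr.ind = TRUE)
  sel <- sel[order(sel[, 1], sel[, 2]), , drop = FALSE]
  batch <- list(
    pairs = unname(sel),
    distances = d[sel],
    features = if (nrow(sel) > 0)
      pair_feature_matrix(graph, cluster, sel)
    else matrix(0, 0, length(cluster$global_features) +
                  ncol(cluster$ligand_features) + ncol(graph$node_attr_wl)))
  class(batch) <- "pair_batch"
  batch
}

assemble_training <- function(batches) {
  keep <- vapply(batches, function(b) nrow(b$features) > 0, TRUE)
  X <- do.call(rbind, lapply(batches[keep], `[[`, "features"))
  cfg <- rep(seq_along(batches)[keep],
             vapply(batches[keep], function(b) nrow(b$features), 0L))
  Y <- cbind(vapply(batches, function(b) b$e_coul, 0),
             vapply(batches, function(b) b$e_vdw, 0))
  if (any(!is.finite(Y))) stop("non-finite configuration labels")
  list(X = X, cfg = cfg, Y = Y)
}

scale_inputs <- function(X, lo, hi) {
  rng <- hi - lo
  const <- rng < 1e-12
  if (any(const)) rng[const] <- 1
  Xs <- sweep(sweep(X, 2, lo), 2, rng, "/")
  Xs[, const] <- 0
  Xs
}

#' Train the five-fold interaction-energy ensemble
#'
#' Five feed-forward regressors (hidden layers 128, 64, 32; ReLU; Adam,
#' learning rate 0.001; batches of 32 configurations; 150 epochs) map a
#' pair-feature row to a (Coulomb, van der Waals) contribution. Supervision
#' is configuration-level only: the mean absolute error between the summed
#' per-pair contributions and the configuration's Coulomb + van der Waals
#' energy. Inputs are min-max scaled to [0,1]; outputs are scaled into
#' [-1,1] with a zero-preserving per-channel max-abs factor so that
#' pair-level predictions invert exactly. Folds are distinct seeded 80%
#' splits of the configurations; predictions average the five folds.
#'
#' @param batches list of `pair_batch` objects, each with `e_coul`,
#'   `e_vdw` configuration labels.
#' @param seed master seed driving fold splits, weight init and shuffling.
#' @param epochs,folds,hidden,lr,batch_size training configuration.
#' @param verbose print per-fold progress.
#' @return an `interaction_ensemble`.
#' @export
train_interaction_model <- function(batches, seed, epochs = 150, folds = 5,
                                    hidden = c(128, 64, 32), lr = 0.001,
                                    batch_size = 32, verbose = FALSE) {
  if (length(batches) < folds)
    stop("need at least ", folds, " configurations for ", folds, "-fold CV")
  tr <- assemble_training(batches)
  lo <- apply(tr$X, 2, min)
  hi <- apply(tr$X, 2, max)
  if (any(hi - lo < 1e-12))
    nd_warn("%d constant input feature(s) mapped to 0",
            sum(hi - lo < 1e-12))
  Xs <- scale_inputs(tr$X, lo, hi)
  # one common max-abs factor for both channels: with sum-only supervision
  # the Coulomb/vdW split of a pair output is not identified, so per-channel
  # factors would corrupt the unscaled sum
  y_scale <- max(abs(tr$Y), 1e-12)
  Ys <- tr$Y / y_scale
  n_cfg <- length(batches)
  set.seed(seed)
  fold_id <- sample(rep_len(seq_len(folds), n_cfg))
  members <- vector("list", folds)
  for (k in seq_len(folds)) {
    nd_msg(verbose, "fold %d/%d", k, folds)
    set.seed(seed + k)
    members[[k]] <- train_fold(Xs, tr$cfg, Ys,
                               cfg_train = which(fold_id != k),
                               hidden = hidden, epochs = epochs, lr = lr,
                               batch_size = batch_size, verbose = verbose)
  }
  structure(list(
    folds = lapply(members, `[[`, "net"),
    history = lapply(members, `[[`, "history"),
    fold_id = fold_id,
    x_lo = lo, x_hi = hi, y_scale = y_scale,
    hidden = hidden, seed = seed,
    config = list(epochs = epochs, lr = lr, batch_size = batch_size,
                  folds = folds)),
    class = "interaction_ensemble")
}

#' @export
print.interaction_ensemble <- function(x, ...) {
  cat("Interaction-energy ensemble:", length(x$folds), "folds, hidden (",
      paste(x$hidden, collapse = ", "), "), input dim",
      length(x$x_lo), "\n")
  invisible(x)
}

#' Predict per-pair interaction energies
#'
#' Per-pair (Coulomb, vdW) contributions are the mean over the five folds,
#' mapped back to energy units; the configuration total is their sum.
#'
#' @param model an `interaction_ensemble`.
#' @param batch a `pair_batch` or a raw feature matrix.
#' @param per_fold also return the per-fold prediction array.
#' @return list with `pair_energies` (rows x 2), `pair_total` (their row
#'   sum), `total` (summed configuration energy) and optionally `fold_pred`.
#' @export
predict_interactions <- function(model, batch, per_fold = FALSE) {
  X <- if (inherits(batch, "pair_batch")) batch$features else as.matrix(batch)
  if (nrow(X) == 0) {
    out <- list(pair_energies = matrix(0, 0, 2), pair_total = numeric(0),
                total = 0)
    if (per_fold) out$fold_pred <- array(0, c(0, 2, length(model$folds)))
    return(out)
  }
  if (ncol(X) != length(model$x_lo))
    stop("feature dimension ", ncol(X), " does not match model (",
         length(model$x_lo), ")")
  Xs <- scale_inputs(X, model$x_lo, model$x_hi)
  preds <- lapply(model$folds, function(net)
    mlp_forward(net, Xs) * model$y_scale)
  arr <- array(unlist(preds), c(nrow(X), 2, length(preds)))
  pe <- apply(arr, c(1, 2), mean)
  out <- list(pair_energies = pe,
              pair_total = pe[, 1] + pe[, 2],
              total = sum(pe))
  if (per_fold) out$fold_pred <- arr
  out
}

#' Rescale predicted energies into interaction strengths
#'
#' Affine map phi(E) = (median - E) / (median - E_min): the strongest
#' (most negative) energy maps to exactly 1, the median to exactly 0, and
#' everything else linearly. Degenerate input (all energies equal) maps to
#' 0 everywhere with a warning.
#'
#' @param energies numeric vector or matrix of raw predicted energies.
#' @return object of the same shape with scaled strengths.
#' @export
scale_interactions <- function(energies) {
  e <- as.numeric(energies)
  if (length(e) < 1) stop("empty energy table")
  med <- stats::median(e)
  emin <- min(e)
  if (abs(med - emin) < 1e-12) {
    nd_warn("all energies equal; scaled strengths set to 0")
    phi <- rep(0, length(e))
  } else {
    phi <- (med - e) / (med - emin)
  }
  if (is.matrix(energies)) {
    phi <- matrix(phi, nrow(energies), ncol(energies))
    dimnames(phi) <- dimnames(energies)
  }
  phi
}

#' Cross-validation report on held-out configurations
#'
#' @param model an `interaction_ensemble`.
#' @param batches held-out `pair_batch` list with labels.
#' @return list with `rmse` (population RMSE of summed-energy predictions),
#'   `pair_std` (mean across pairs of the between-fold standard deviation),
#'   and per-configuration predictions.
#' @export
evaluate_cv <- function(model, batches) {
  labels <- vapply(batches, function(b) b$e_coul + b$e_vdw, 0)
  preds <- numeric(length(batches))
  stds <- c()
  for (i in seq_along(batches)) {
    p <- predict_interactions(model, batches[[i]], per_fold = TRUE)
    preds[i] <- p$total
    if (nrow(p$pair_energies) > 0) {
      fold_tot <- apply(p$fold_pred, c(1, 3), sum)   # pair x fold sums
      stds <- c(stds, apply(fold_tot, 1, stats::sd))
    }
  }
  list(rmse = sqrt(mean((preds - labels)^2)),
       pair_std = if (length(stds)) mean(stds) else 0,
       predicted = preds, labels = labels)
}

#' Predicted interaction table for every ligand-residue combination
#'
#' Pair features are pose-independent, so the full table is computed once
#' per protein-cluster combination and reused across annealing poses.
#'
#' @param model an `interaction_ensemble`.
#' @param graph `protein_graph` with WL attributes.
#' @param cluster featurized `cluster_model`.
#' @return list with `energy` (ligand x residue matrix of raw predicted
#'   pair energies) and `phi` (the rescaled strengths).
#' @export
interaction_table <- function(model, graph, cluster) {
  nl <- nrow(cluster$ligand_features)
  nn <- nrow(graph$node_attr_wl)
  pairs <- cbind(rep(seq_len(nl), each = nn), rep(seq_len(nn), nl))
  X <- pair_feature_matrix(graph, cluster, pairs)
  p <- predict_interactions(model, X)
  E <- matrix(p$pair_total, nl, nn, byrow = TRUE)
  list(energy = E, phi = scale_interactions(E))
}
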