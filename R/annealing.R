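# Rigid-body Metropolis simulated annealing of the cluster pose over the
# protein surface. The loss combines (i) a geometric well steering every
# ligand head towards a target distance d0 from the nearest C-alpha,
# (ii) a steep inverse-quartic barrier keeping the cluster from penetrating
# the protein, and (iii) the (negative) sum of scaled interaction strengths
# phi over ligand-residue pairs in contact.

#' Loss-function parameters for annealing
#'
#' @param d0 target ligand-head-to-C-alpha distance (Angstrom); 5.0 for the
#'   coarse-grained stage, 4.0 for all-atom refinement.
#' @param sigma Gaussian well width (Angstrom^2).
#' @param k weight of the interaction-strength sum (default 1).
#' @param close_margin C-alphas with (t_j - c) below this enter the barrier
#'   sum (Angstrom).
#' @param pair_cutoff pairs within this distance enter the phi sum
#'   (Angstrom).
#' @param barrier_cap finite cap for the barrier at penetration.
#' @param c minimum centre-to-head distance; computed from the cluster when
#'   NULL.
#' @return a `loss_params` list; `theta` is derived as d0^4 / 3 so the well
#'   minimum value is 1/3 - 1.
#' @export
loss_params <- function(d0 = 5.0, sigma = 2.0, k = 1, close_margin = 5.5,
                        pair_cutoff = 5.5, barrier_cap = 1e6, c = NULL) {
  stopifnot(d0 > 0, sigma > 0, k >= 0)
  structure(list(d0 = d0, sigma = sigma, k = k, theta = d0^4 / 3,
                 close_margin = close_margin, pair_cutoff = pair_cutoff,
                 barrier_cap = barrier_cap, c = c),
            class = "loss_params")
}

params_with_c <- function(params, cluster) {
  if (is.null(params$c)) {
    d <- sqrt(rowSums(sweep(cluster$head_centroids, 2, cluster$com)^2))
    params$c <- min(d)
  }
  params
}

# geometric well: inverse-quartic repulsion + Gaussian well at d0, -> 0 at
# long range
well_g <- function(d, params) {
  params$theta / d^4 - exp(-(d - params$d0)^2 / params$sigma)
}

#' Annealing loss of a posed cluster
#'
#' @param heads posed ligand-head coordinates (L x 3).
#' @param center posed cluster centre of mass.
#' @param ca protein C-alpha coordinates (or a `coarse_protein`).
#' @param phi ligand x residue matrix of scaled interaction strengths.
#' @param params a `loss_params` with `c` set.
#' @return scalar loss (finite; penetration is capped).
#' @export
placement_loss <- function(heads, center, ca, phi, params) {
  loss_with_dist(heads, center, ca, phi, params)$loss
}

loss_with_dist <- function(heads, center, ca, phi, params) {
  if (inherits(ca, "coarse_protein")) ca <- ca$ca
  D <- cross_dist(heads, ca)
  dj <- apply(D, 1, min)
  geo <- sum(well_g(dj, params))
  t_j <- sqrt(rowSums(sweep(ca, 2, as.numeric(center))^2))
  x <- t_j - params$c
  sel <- x < params$close_margin
  barrier <- if (any(sel)) {
    xx <- x[sel]
    sum(ifelse(xx <= 0, params$barrier_cap,
               pmin(1 / xx^4, params$barrier_cap)))
  } else 0
  inter <- if (params$k > 0) params$k * sum(phi[D <= params$pair_cutoff]) else 0
  list(loss = geo + barrier - inter, dmin = min(dj))
}

#' Metropolis acceptance decision
#'
#' P = min(1, exp(-dL / T)) in reduced units (k_B = 1).
#'
#' @param delta loss change of the proposed move.
#' @param temperature simulation temperature (> 0).
#' @return logical: accept the move (consumes one uniform variate).
#' @export
metropolis_accept <- function(delta, temperature) {
  stopifnot(temperature > 0)
  delta <= 0 || stats::runif(1) < exp(-delta / temperature)
}

#' Adaptive step-size controller
#'
#' Keeps the acceptance fraction inside the 40-60% band: above 0.6 both
#' step sizes grow by 10%, below 0.4 they shrink by 10%; clamped to
#' [1e-3, 20] Angstrom and [1e-3, pi] radians.
#'
#' @param acceptance acceptance fraction over the recent proposal window.
#' @param steps list with `translation` and `rotation` maxima.
#' @return updated steps.
#' @export
adapt_steps <- function(acceptance, steps) {
  f <- if (acceptance > 0.6) 1.1 else if (acceptance < 0.4) 0.9 else 1
  list(translation = min(max(steps$translation * f, 1e-3), 20),
       rotation = min(max(steps$rotation * f, 1e-3), pi))
}

#' Cooling schedule description
#'
#' Geometric cooling T_k = T0 * alpha^(k %/% block). `t0 = NULL` triggers
#' calibration so that initial uphill acceptance is about 0.8 on a 200-step
#' probe. `constant = TRUE` holds the temperature fixed (used e.g. to probe
#' the step controller at a mid-schedule temperature).
#'
#' @param n_steps proposals per run.
#' @param t0 initial temperature in loss units (NULL: calibrated).
#' @param alpha per-block cooling factor.
#' @param block steps per temperature block.
#' @param constant hold T = t0 throughout.
#' @export
anneal_schedule <- function(n_steps = 5000, t0 = NULL, alpha = 0.95,
                            block = 100, constant = FALSE) {
  list(n_steps = n_steps, t0 = t0, alpha = alpha, block = block,
       constant = constant)
}

random_rotation <- function(max_angle = pi) {
  axis <- stats::rnorm(3)
  rotation_matrix(axis, stats::runif(1, 0, max_angle))
}

# Deterministic approach: slide the cluster from far away along -dir until
# the closest head-to-Calpha distance reaches about d0 + 2 (or the centre
# would pass the protein centroid).
approach_pose <- function(ca, cluster, dir, R0, d0) {
  pc <- colMeans(ca)
  r_prot <- max(sqrt(rowSums(sweep(ca, 2, pc)^2)))
  r_clus <- max(sqrt(rowSums(sweep(cluster$head_centroids, 2,
                                   cluster$com)^2)))
  start <- r_prot + r_clus + 2
  heads0 <- sweep(cluster$head_centroids, 2, cluster$com) %*% t(R0)
  for (s in seq(start, 0, by = -0.5)) {
    ctr <- pc + dir * s
    heads <- sweep(heads0, 2, ctr, "+")
    if (min(cross_dist(heads, ca)) <= d0 + 2 || s <= 0.5)
      return(new_pose(R0, ctr - cluster$com))
  }
  new_pose(R0, pc + dir * start - cluster$com)
}

calibrate_t0 <- function(ca, cluster, phi, params, pose, n_probe = 200,
                         target = 0.8) {
  heads0 <- cluster$head_centroids
  com0 <- cluster$com
  cur <- pose
  L <- placement_loss(apply_pose(heads0, cur, com0), com0 + cur$t, ca, phi,
                      params)
  ups <- c()
  for (i in seq_len(n_probe)) {
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    prop <- new_pose(random_rotation(0.3) %*% cur$R,
                     cur$t + dirv * stats::runif(1, 0, 2))
    lw <- loss_with_dist(apply_pose(heads0, prop, com0), com0 + prop$t, ca,
                         phi, params)
    dL <- lw$loss - L
    if (is.finite(dL) && dL > 0) ups <- c(ups, dL)
    # greedy walk: stay on the surface, do not climb barriers during probing
    if (dL <= 0 && lw$dmin < 15) {
      cur <- prop
      L <- lw$loss
    }
  }
  if (length(ups) == 0) return(0.5)
  # median is robust against barrier-scale spikes from penetrating proposals
  max(stats::median(ups) / -log(target), 0.05)
}

anneal_one <- function(ca, cluster, phi, params, schedule, pose0, t0,
                       domain_max = 12) {
  heads0 <- cluster$head_centroids
  com0 <- cluster$com
  cur <- pose0
  L <- placement_loss(apply_pose(heads0, cur, com0), com0 + cur$t, ca, phi,
                      params)
  steps <- list(translation = 2.0, rotation = 0.3)
  temp <- t0
  n <- schedule$n_steps
  trace <- matrix(NA_real_, n, 3)
  loss_trace <- numeric(n)
  accepted <- logical(n)
  win <- 50
  for (i in seq_len(n)) {
    if (!schedule$constant && i > 1 && (i - 1) %% schedule$block == 0)
      temp <- temp * schedule$alpha
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    prop <- new_pose(random_rotation(steps$rotation) %*% cur$R,
                     cur$t + dirv * stats::runif(1, 0, steps$translation))
    lw <- loss_with_dist(apply_pose(heads0, prop, com0), com0 + prop$t, ca,
                         phi, params)
    # reflecting wall: the search domain ends where every ligand head is
    # farther than domain_max from the protein (flat far field)
    if (lw$dmin <= domain_max && metropolis_accept(lw$loss - L, temp)) {
      cur <- prop
      L <- lw$loss
      accepted[i] <- TRUE
    }
    trace[i, ] <- com0 + cur$t
    loss_trace[i] <- L
    if (i %% win == 0)
      steps <- adapt_steps(mean(accepted[(i - win + 1):i]), steps)
  }
  terminal <- accepted[max(1, n - 999):n]
  list(pose = cur, loss = L, com = com0 + cur$t, com_trace = trace,
       loss_trace = loss_trace,
       acceptance_terminal = mean(terminal), steps = steps,
       temperature_final = temp)
}

#' Coarse-grained annealing placement
#'
#' Runs `n_runs` independent Metropolis simulated-annealing chains. Run i
#' approaches the protein from direction i of a Fibonacci-sphere set with a
#' random initial orientation; cooling is geometric; step sizes adapt to
#' hold acceptance in the 40-60% band. T0 is calibrated once (probe run)
#' unless given in the schedule.
#'
#' @param cp `coarse_protein` (or C-alpha matrix).
#' @param cluster featurized `cluster_model`.
#' @param phi ligand x residue scaled-strength matrix.
#' @param params `loss_params`.
#' @param schedule from [anneal_schedule()].
#' @param n_runs number of independent runs (default 64).
#' @param seed master seed; run i uses seed + i.
#' @param domain_max search-domain wall: proposals with every ligand head
#'   farther than this from the protein are rejected (Angstrom).
#' @param verbose print progress.
#' @return list of per-run results (pose, loss, COM trace, terminal
#'   acceptance), plus the calibrated `t0` as an attribute.
#' @export
anneal <- function(cp, cluster, phi, params = loss_params(),
                   schedule = anneal_schedule(), n_runs = 64, seed = 1,
                   domain_max = 12, verbose = FALSE) {
  ca <- if (inherits(cp, "coarse_protein")) cp$ca else as.matrix(cp)
  stopifnot(n_runs >= 1)
  params <- params_with_c(params, cluster)
  dirs <- fibonacci_sphere(n_runs)
  t0 <- schedule$t0
  if (is.null(t0)) {
    set.seed(seed)
    pose_probe <- approach_pose(ca, cluster, dirs[1, ], random_rotation(),
                                params$d0)
    t0 <- calibrate_t0(ca, cluster, phi, params, pose_probe)
    nd_msg(verbose, "calibrated T0 = %.3f", t0)
  }
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    set.seed(seed + i)
    pose0 <- approach_pose(ca, cluster, dirs[i, ], random_rotation(),
                           params$d0)
    runs[[i]] <- anneal_one(ca, cluster, phi, params, schedule, pose0, t0,
                            domain_max = domain_max)
    nd_msg(verbose, "run %d/%d: loss %.3f acc %.2f", i, n_runs,
           runs[[i]]$loss, runs[[i]]$acceptance_terminal)
  }
  attr(runs, "t0") <- t0
  attr(runs, "params") <- params
  runs
}

pose_energy <- function(pose, cluster, ca, energy, pair_cutoff) {
  heads <- apply_pose(cluster$head_centroids, pose, cluster$com)
  D <- cross_dist(heads, ca)
  sum(energy[D <= pair_cutoff])
}

#' Cluster sampled placements into ranked candidate sites
#'
#' Complete-linkage agglomerative clustering of the final centre-of-mass
#' points, cut at `threshold`; clusters are ranked by member count and the
#' representative pose of each top cluster is its member with the lowest
#' predicted total interaction energy.
#'
#' @param runs result list from [anneal()].
#' @param cp protein (`coarse_protein` or C-alpha matrix).
#' @param cluster `cluster_model`.
#' @param energy ligand x residue raw predicted energy matrix.
#' @param n number of sites to return (default 3).
#' @param threshold clustering distance threshold (Angstrom, default 10).
#' @param pair_cutoff contact cutoff for the energy sum.
#' @return object of class `site_ranking`.
#' @export
select_sites <- function(runs, cp, cluster, energy, n = 3, threshold = 10,
                         pair_cutoff = 5.5) {
  ca <- if (inherits(cp, "coarse_protein")) cp$ca else as.matrix(cp)
  pts <- do.call(rbind, lapply(runs, `[[`, "com"))
  if (nrow(pts) < 2 * n)
    nd_warn("only %d sampled points for n = %d sites", nrow(pts), n)
  assign <- if (nrow(pts) == 1) 1 else
    stats::cutree(stats::hclust(stats::dist(pts), method = "complete"),
                  h = threshold)
  sizes <- sort(table(assign), decreasing = TRUE)
  if (length(sizes) < n)
    nd_warn("found %d cluster(s) < n = %d; returning all", length(sizes), n)
  top <- utils::head(names(sizes), n)
  sites <- lapply(top, function(cl) {
    members <- which(assign == as.integer(cl))
    en <- vapply(members, function(m)
      pose_energy(runs[[m]]$pose, cluster, ca, energy, pair_cutoff), 0)
    best <- members[which.min(en)]
    list(members = members, count = length(members),
         representative = best, pose = runs[[best]]$pose,
         com = runs[[best]]$com, energy = min(en))
  })
  structure(list(sites = sites, assignments = assign, points = pts,
                 threshold = threshold), class = "site_ranking")
}

#' @export
print.site_ranking <- function(x, ...) {
  cat("Candidate interaction sites (", length(x$sites), "):\n", sep = "")
  for (i in seq_along(x$sites)) {
    s <- x$sites[[i]]
    cat(sprintf("  site %d: %d members, E = %.3f, COM (%.1f, %.1f, %.1f)\n",
                i, s$count, s$energy, s$com[1], s$com[2], s$com[3]))
  }
  invisible(x)
}

# all-atom loss for restricted refinement: minimum interatomic distances
# define d_j and pair membership.
refine_loss <- function(cl_xyz, center, prot_xyz, atom_res, atom_lig, phi,
                        params) {
  D <- cross_dist(cl_xyz, prot_xyz)
  nl <- max(atom_lig)
  dj <- vapply(seq_len(nl), function(j)
    min(D[atom_lig == j, , drop = FALSE]), 0)
  geo <- sum(well_g(dj, params))
  # penetration is prevented by the hard steric floor instead of the
  # soft coarse-grained barrier
  hit <- which(D <= params$pair_cutoff, arr.ind = TRUE)
  inter <- 0
  if (nrow(hit) > 0 && params$k > 0) {
    pr <- unique(cbind(atom_lig[hit[, 1]], atom_res[hit[, 2]]))
    inter <- params$k * sum(phi[pr])
  }
  list(loss = geo - inter, min_dist = min(D))
}

#' Restricted all-atom refinement of a site pose
#'
#' Same Metropolis engine at the all-atom level: d_j and pair membership use
#' minimum interatomic distances (any atom within 5.5 Angstrom), the target
#' distance d0 drops to the all-atom contact scale, proposals are rejected
#' outright when the centre of mass leaves `restrict_radius` of the site or
#' any interatomic distance falls below the 1.5 Angstrom steric floor.
#'
#' @param protein_atoms heavy-atom records aligned with the graph residues.
#' @param graph the `protein_graph` (defines residue order for `phi`).
#' @param cluster `cluster_model` with all-atom coordinates.
#' @param site_pose pose from [select_sites()].
#' @param phi scaled-strength matrix.
#' @param params `loss_params`; default d0 4.0 Angstrom.
#' @param restrict_radius maximum COM excursion (Angstrom, default 8).
#' @param steric_floor minimum allowed interatomic distance (Angstrom).
#' @param n_steps proposals (default 2000).
#' @param seed RNG seed.
#' @return list with refined `pose`, final `loss`, `min_dist`, `com`,
#'   and a `feasible` flag (FALSE when a clash could not be resolved).
#' @export
refine_pose <- function(protein_atoms, graph, cluster, site_pose, phi,
                        params = loss_params(d0 = 4.0),
                        restrict_radius = 8, steric_floor = 1.5,
                        n_steps = 2000, seed = 1) {
  params <- params_with_c(params, cluster)
  heavy <- protein_atoms[protein_atoms$element != "H", , drop = FALSE]
  prot_xyz <- as.matrix(heavy[, c("x", "y", "z")])
  node_key <- paste(graph$labels$chain_id, graph$labels$residue_id)
  atom_res <- match(paste(heavy$chain_id, heavy$residue_id), node_key)
  keep <- !is.na(atom_res)
  prot_xyz <- prot_xyz[keep, , drop = FALSE]
  atom_res <- atom_res[keep]
  cl_xyz0 <- as.matrix(cluster$atoms[, c("x", "y", "z")])
  atom_lig <- integer(nrow(cl_xyz0))
  for (j in seq_along(cluster$ligands)) {
    lg <- cluster$ligands[[j]]
    atom_lig[c(lg$head_atoms, lg$ring_atoms,
               if (!is.na(lg$sulfur)) lg$sulfur)] <- j
  }
  core <- atom_lig == 0          # metal core atoms belong to no ligand
  atom_lig_full <- atom_lig
  lig_xyz_rows <- !core
  com0 <- cluster$com
  site_com <- com0 + site_pose$t
  set.seed(seed)
  cur <- site_pose
  eval_pose <- function(pose) {
    xyz <- apply_pose(cl_xyz0, pose, com0)
    r <- refine_loss(xyz[lig_xyz_rows, , drop = FALSE],
                     com0 + pose$t, prot_xyz,
                     atom_res, atom_lig_full[lig_xyz_rows], phi, params)
    # core atoms also count for the steric floor
    if (any(core))
      r$min_dist <- min(r$min_dist,
                        min(cross_dist(xyz[core, , drop = FALSE], prot_xyz)))
    r
  }
  ev <- eval_pose(cur)
  L <- ev$loss
  best <- list(pose = cur, loss = L, min_dist = ev$min_dist)
  steps <- list(translation = 0.8, rotation = 0.15)
  # calibrate a modest starting temperature from uphill probes
  temp <- local({
    ups <- c()
    p <- cur; Lp0 <- L
    for (i in seq_len(100)) {
      dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
      q <- new_pose(random_rotation(steps$rotation) %*% p$R,
                    p$t + dirv * stats::runif(1, 0, steps$translation))
      e <- eval_pose(q)
      d <- e$loss - Lp0
      if (is.finite(d) && d > 0 && d < params$barrier_cap / 2)
        ups <- c(ups, d)
      p <- q; Lp0 <- e$loss
    }
    if (length(ups) == 0) 0.2 else max(mean(ups) / -log(0.5), 0.02)
  })
  accepted <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    if (i > 1 && (i - 1) %% 100 == 0) temp <- temp * 0.9
    dirv <- stats::rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    prop <- new_pose(random_rotation(steps$rotation) %*% cur$R,
                     cur$t + dirv * stats::runif(1, 0, steps$translation))
    if (sqrt(sum((com0 + prop$t - site_com)^2)) > restrict_radius) next
    e <- eval_pose(prop)
    if (e$min_dist < steric_floor) next
    if (metropolis_accept(e$loss - L, temp)) {
      cur <- prop
      L <- e$loss
      accepted[i] <- TRUE
      if (L < best$loss || best$min_dist < steric_floor)
        best <- list(pose = cur, loss = L, min_dist = e$min_dist)
    }
    if (i %% 50 == 0)
      steps <- adapt_steps(mean(accepted[(i - 49):i]), steps)
  }
  feasible <- best$min_dist >= steric_floor
  if (!feasible)
    nd_warn("refinement could not resolve steric clash (min dist %.2f A)",
            best$min_dist)
  list(pose = best$pose, loss = best$loss, min_dist = best$min_dist,
       com = com0 + best$pose$t, feasible = feasible)
}
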