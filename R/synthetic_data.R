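# Synthetic coarse-grained complexes with a closed-form, exactly
# pair-decomposable energy oracle. These stand in for molecular-dynamics
# training data: a self-avoiding C-alpha chain with charged/hydrophobic
# bead types and a rigid cluster whose charged ligand heads interact with
# residue beads through reduced-unit Coulomb and Lennard-Jones terms.

#' Oracle energy parameters (reduced units)
#'
#' @param coulomb_k Coulomb prefactor (reduced; absorbs 1/(4 pi eps0)).
#' @param eps_r relative dielectric.
#' @param lj_eps,lj_sigma Lennard-Jones well depth and size (Angstrom).
#' @param cutoff interaction truncation (Angstrom). Both terms are
#'   truncated at the pair-formation distance so that every configuration
#'   label decomposes exactly over the pairs the regressor is shown -- the
#'   property the sum-aggregated architecture assumes.
#' @export
oracle_params <- function(coulomb_k = 10, eps_r = 1, lj_eps = 0.5,
                          lj_sigma = 4.0, cutoff = 10) {
  list(coulomb_k = coulomb_k, eps_r = eps_r, lj_eps = lj_eps,
       lj_sigma = lj_sigma, cutoff = cutoff)
}

# per-pair oracle energies between posed heads and residue beads
oracle_pair_energies <- function(heads, head_charges, ca, res_charges,
                                 params = oracle_params()) {
  D <- cross_dist(heads, ca)
  Q <- outer(head_charges, res_charges)
  e_coul <- params$coulomb_k * Q / (params$eps_r * D)
  sr6 <- (params$lj_sigma / D)^6
  e_vdw <- 4 * params$lj_eps * (sr6^2 - sr6)
  out_of_range <- D > params$cutoff
  e_coul[out_of_range] <- 0
  e_vdw[out_of_range] <- 0
  list(coul = e_coul, vdw = e_vdw, dist = D)
}

# residue palette for the synthetic chain: names drawn with realistic-ish
# frequencies; charges follow the residue identity. Positively charged
# residues are reserved for the planted patch so that the patch is the
# unique attractive region by construction.
SYNTH_BACKGROUND <- c(ALA = 0.18, LEU = 0.14, SER = 0.13, GLY = 0.10,
                      THR = 0.09, VAL = 0.09, ASN = 0.06, GLN = 0.05,
                      ASP = 0.08, GLU = 0.08)

#' Generate a synthetic coarse-grained protein
#'
#' Self-avoiding random walk with 3.8 Angstrom C-alpha steps and a 4.0
#' Angstrom excluded-volume radius between non-consecutive beads. Residues
#' in the planted patch(es) are lysines (charge +1); background residues are
#' drawn from a fixed composition. Each residue is decorated with
#' pseudo-atoms whose element counts match its claimed type, so the
#' featurizer can be exercised on the synthetic structure.
#'
#' @param n_residues chain length (>= 10).
#' @param patches list of integer vectors: residue indices of each planted
#'   positively charged patch. The default (NULL) plants one spatially
#'   compact 6-residue patch: the mid-chain residue and its five nearest
#'   C-alpha neighbours, so the patch forms a contiguous surface blob.
#' @param n_patches with `patches = NULL`, the number of spatially compact
#'   patches to plant (seeds spread along the chain).
#' @param patch_size residues per auto-planted patch.
#' @param seed RNG seed (full determinism).
#' @param step,excluded walk geometry in Angstrom.
#' @return list with `cp` (coarse_protein), `atoms` (pseudo-atom records),
#'   `charges` (per residue), `patches`, and the generating arguments.
#' @export
make_protein <- function(n_residues = 100, patches = NULL, n_patches = 1,
                         patch_size = 6, seed = 1, step = 3.8,
                         excluded = 4.0) {
  stopifnot(n_residues >= 10)
  set.seed(seed)
  for (attempt in 1:50) {
    ca <- matrix(NA_real_, n_residues, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- c(1, 0, 0)
    ok <- TRUE
    for (i in 2:n_residues) {
      placed <- FALSE
      for (try in 1:60) {
        # persistent direction keeps the chain extended enough to have
        # surface; fresh random component avoids knots
        cand <- dir + stats::rnorm(3, sd = 0.9)
        cand <- cand / sqrt(sum(cand^2))
        p <- ca[i - 1, ] + cand * step
        if (i > 2) {
          d <- sqrt(rowSums(sweep(ca[1:(i - 2), , drop = FALSE], 2, p)^2))
          if (min(d) < excluded) next
        }
        ca[i, ] <- p
        dir <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) stop("self-avoiding walk failed after maximum retries")
  if (is.null(patches)) {
    # spatially compact patches around seeds spread along the chain
    seeds <- round(seq(0, 1, length.out = n_patches + 2)[2:(n_patches + 1)] *
                     n_residues)
    d <- as.matrix(stats::dist(ca))
    patches <- lapply(seeds, function(s)
      sort(order(d[s, ])[seq_len(patch_size)]))
  }
  patch_idx <- sort(unique(unlist(patches)))
  stopifnot(all(patch_idx >= 1), all(patch_idx <= n_residues))
  resnames <- sample(names(SYNTH_BACKGROUND), n_residues, replace = TRUE,
                     prob = SYNTH_BACKGROUND)
  resnames[patch_idx] <- "LYS"
  charges <- unname(residue_charge(resnames))
  # pseudo-atom decoration consistent with the claimed residue types
  atoms <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
    cnt <- RESIDUE_ELEMENT_COUNTS[resnames[i], ]
    el <- c("C", rep("C", cnt["C"] - 1), rep("N", cnt["N"]),
            rep("O", cnt["O"]), rep("S", cnt["S"]))
    nm <- c("CA", paste0(el[-1], seq_along(el[-1])))
    off <- matrix(stats::rnorm(3 * length(el), sd = 0.9), ncol = 3)
    off[1, ] <- 0
    nrm <- sqrt(rowSums(off^2))
    off[-1, ] <- off[-1, ] * (stats::runif(length(el) - 1, 1.2, 2.4) /
                                pmax(nrm[-1], 1e-9))
    data.frame(element = el,
               x = ca[i, 1] + off[, 1], y = ca[i, 2] + off[, 2],
               z = ca[i, 3] + off[, 3],
               chain_id = "A", residue_id = i, insert = "",
               residue_name = resnames[i], atom_name = nm,
               occupancy = 1, stringsAsFactors = FALSE)
  }))
  atoms$residue_key <- paste(atoms$chain_id, atoms$residue_id, atoms$insert,
                             sep = "|")
  cp <- structure(list(ca = ca,
                       labels = data.frame(chain_id = "A",
                                           residue_id = seq_len(n_residues),
                                           residue_name = resnames,
                                           stringsAsFactors = FALSE)),
                  class = "coarse_protein")
  list(cp = cp, atoms = atoms, charges = charges, patches = patches,
       args = list(n_residues = n_residues, seed = seed, step = step,
                   excluded = excluded))
}

#' Generate a synthetic rigid nanocluster
#'
#' Ligand heads sit on a sphere of radius `radius` around a small metallic
#' core (centred icosahedron of gold atoms). For even `n_ligands` the head
#' directions are antipodal pairs, which makes the centre of mass coincide
#' exactly with the sphere centre. Each ligand carries a sulfur anchor, a
#' six-carbon ring and a carboxylate-like head (one C, two O).
#'
#' @param n_ligands number of ligands (>= 2).
#' @param radius head-sphere radius (Angstrom).
#' @param charges per-head charge (recycled; default -1, carboxylate-like).
#' @param seed RNG seed (orientation of ring planes).
#' @param core_radius icosahedron radius (default 0.45 * radius).
#' @return a featurized `cluster_model` with `head_charges` set.
#' @export
make_cluster <- function(n_ligands = 18, radius = 8, charges = -1, seed = 1,
                         core_radius = NULL) {
  stopifnot(n_ligands >= 2)
  set.seed(seed)
  core_radius <- core_radius %||% (0.45 * radius)
  # centred icosahedron core
  gr <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, gr), c(0, -1, gr), c(0, 1, -gr), c(0, -1, -gr),
               c(1, gr, 0), c(-1, gr, 0), c(1, -gr, 0), c(-1, -gr, 0),
               c(gr, 0, 1), c(-gr, 0, 1), c(gr, 0, -1), c(-gr, 0, -1))
  ico <- ico / sqrt(1 + gr^2) * core_radius
  core <- rbind(c(0, 0, 0), ico)
  dirs <- if (n_ligands %% 2 == 0) {
    half <- fibonacci_sphere(n_ligands)      # take alternating z>0-ish set
    half <- half[order(-half[, 3]), ][seq_len(n_ligands / 2), , drop = FALSE]
    rbind(half, -half)
  } else fibonacci_sphere(n_ligands)
  atoms <- data.frame(element = rep("AU", nrow(core)),
                      x = core[, 1], y = core[, 2], z = core[, 3],
                      stringsAsFactors = FALSE)
  ligands <- list()
  for (j in seq_len(n_ligands)) {
    u <- dirs[j, ]
    # orthonormal frame around u for the ring plane
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v1 <- a - sum(a * u) * u; v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
            u[1] * v1[2] - u[2] * v1[1])
    s_pos <- u * (core_radius + 1.8)
    ring_c <- u * (core_radius + (radius - core_radius) * 0.55)
    ring <- t(vapply(0:5, function(t)
      ring_c + 1.39 * (cos(pi * t / 3) * v1 + sin(pi * t / 3) * v2),
      numeric(3)))
    # carboxylate-like head: C at the centroid, two O symmetric about it,
    # so both the plain and the mass-weighted head centroid sit exactly at
    # radius * u (keeps the cluster COM at the sphere centre for antipodal
    # ligand pairs)
    hc <- u * radius
    head <- rbind(hc, hc + 0.60 * v1 + 1.05 * v2, hc - 0.60 * v1 - 1.05 * v2)
    i0 <- nrow(atoms)
    atoms <- rbind(atoms,
                   data.frame(element = c("S", rep("C", 6), "C", "O", "O"),
                              x = c(s_pos[1], ring[, 1], head[, 1]),
                              y = c(s_pos[2], ring[, 2], head[, 2]),
                              z = c(s_pos[3], ring[, 3], head[, 3]),
                              stringsAsFactors = FALSE))
    ligands[[j]] <- list(head_atoms = i0 + 8:10, ring_atoms = i0 + 2:7,
                         sulfur = i0 + 1L, ligand_type = "synthetic-COO",
                         unit_position = if (j %% 2 == 0) "end" else "middle")
  }
  cl <- new_cluster_model(atoms, ligands,
                          head_charges = rep_len(charges, n_ligands))
  featurize_cluster(cl)
}

#' Write a cluster and its topology sidecar to disk
#'
#' Emits the structure as XYZ and the ligand topology as the JSON sidecar
#' schema consumed by [read_cluster()].
#'
#' @param cluster a `cluster_model`.
#' @param structure_path,topology_path output paths.
#' @export
write_cluster <- function(cluster, structure_path, topology_path) {
  write_xyz(list(elements = cluster$atoms$element,
                 coords = as.matrix(cluster$atoms[, c("x", "y", "z")])),
            structure_path, comment = "synthetic nanocluster")
  jsonlite::write_json(
    list(ligands = lapply(cluster$ligands, function(lg)
      list(head_atoms = lg$head_atoms, ring_atoms = lg$ring_atoms,
           sulfur = lg$sulfur, ligand_type = lg$ligand_type,
           unit_position = lg$unit_position))),
    topology_path, auto_unbox = TRUE)
  invisible(structure_path)
}

#' Sample training configurations with oracle energy labels
#'
#' Poses span contact to `max_separation` extra Angstrom of head-to-bead
#' separation with random orientations. Labels are the oracle Coulomb and
#' van der Waals sums plus optional Gaussian noise (sigma = `noise_frac`
#' times the label standard deviation); exact per-pair energies are
#' retained for diagnostics.
#'
#' @param graph featurized, WL-updated `protein_graph` of the synthetic
#'   protein.
#' @param protein the [make_protein()] output (provides bead charges).
#' @param cluster [make_cluster()] output.
#' @param n_configs number of configurations.
#' @param seed RNG seed.
#' @param formation_distance pair formation cutoff for features (Angstrom).
#' @param noise_frac label noise level (fraction of label SD).
#' @param max_separation largest extra separation beyond contact (Angstrom).
#' @param oracle [oracle_params()].
#' @return list of `pair_batch` objects with `e_coul`, `e_vdw` labels,
#'   `pose`, and `truth` (exact per-pair energy matrices).
#' @export
sample_configurations <- function(graph, protein, cluster, n_configs,
                                  seed = 1, formation_distance = 10,
                                  noise_frac = 0.05, max_separation = 15,
                                  oracle = oracle_params()) {
  stopifnot(n_configs >= 1)
  ca <- graph$ca
  set.seed(seed)
  out <- vector("list", n_configs)
  raw <- matrix(0, n_configs, 2)
  for (i in seq_len(n_configs)) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    R0 <- random_rotation(pi)
    # closest head-to-bead distance ~ 3.5 A (contact) + target separation;
    # approach_pose stops once the minimum distance reaches d0 + 2
    target <- stats::runif(1, 0, max_separation)
    pose <- approach_pose(ca, cluster, u, R0, d0 = 1.5 + target)
    heads <- apply_pose(cluster$head_centroids, pose, cluster$com)
    en <- oracle_pair_energies(heads, cluster$head_charges, ca,
                               protein$charges, oracle)
    b <- form_pairs(graph, cluster, pose, formation_distance)
    b$pose <- pose
    b$truth <- en
    raw[i, ] <- c(sum(en$coul), sum(en$vdw))
    out[[i]] <- b
  }
  sds <- apply(raw, 2, stats::sd)
  noise <- matrix(stats::rnorm(2 * n_configs), n_configs, 2) *
    matrix(noise_frac * sds, n_configs, 2, byrow = TRUE)
  for (i in seq_len(n_configs)) {
    out[[i]]$e_coul <- raw[i, 1] + noise[i, 1]
    out[[i]]$e_vdw <- raw[i, 2] + noise[i, 2]
    out[[i]]$e_coul_exact <- raw[i, 1]
    out[[i]]$e_vdw_exact <- raw[i, 2]
  }
  out
}

#' Generate a scripted synthetic trajectory of the cluster
#'
#' The cluster visits the given poses for the given fractions of frames
#' (in order), with an optional per-frame random-walk jitter of scale
#' `drift`; contact patterns are therefore known by construction.
#'
#' @param cluster a `cluster_model`.
#' @param poses list of rigid poses.
#' @param fractions residence fraction per pose (normalised; recycled to
#'   match `poses`).
#' @param n_frames number of frames (>= 2).
#' @param drift per-frame translation jitter SD (Angstrom).
#' @param seed RNG seed.
#' @return list of frames (`elements`, `coords`) of the cluster atoms.
#' @export
make_trajectory <- function(cluster, poses, fractions = 1, n_frames = 100,
                            drift = 0, seed = 1) {
  stopifnot(n_frames >= 2)
  fractions <- rep_len(fractions, length(poses))
  fractions <- fractions / sum(fractions)
  counts <- diff(round(cumsum(c(0, fractions)) * n_frames))
  set.seed(seed)
  xyz0 <- as.matrix(cluster$atoms[, c("x", "y", "z")])
  frames <- list()
  for (p in seq_along(poses)) {
    base <- apply_pose(xyz0, poses[[p]], cluster$com)
    offset <- c(0, 0, 0)
    for (f in seq_len(counts[p])) {
      offset <- offset + stats::rnorm(3, sd = drift)
      frames[[length(frames) + 1]] <-
        list(elements = cluster$atoms$element,
             coords = sweep(base, 2, offset, "+"))
    }
  }
  frames
}
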