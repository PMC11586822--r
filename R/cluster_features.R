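# Nanocluster descriptors: nine global shape/composition features and a
# 7-dimensional (8 with bridge ligands) local descriptor per protecting
# ligand. All descriptors are rigid-motion invariant.

#' Global nanocluster descriptors
#'
#' Nine values: heavy-atom fraction, gold fraction, sulfur per ligand,
#' gold/carbon bounding-sphere radius, area and volume ratios, and the
#' three sorted principal moments of inertia normalised to sum to one.
#' Bounding spheres are centred on the subset centroid with radius equal to
#' the maximal centroid distance (only the ratios enter the descriptor).
#'
#' @param cluster a `cluster_model`.
#' @return named numeric vector of length 9.
#' @export
global_descriptors <- function(cluster) {
  stopifnot(inherits(cluster, "cluster_model"))
  atoms <- cluster$atoms
  el <- toupper(atoms$element)
  n <- nrow(atoms)
  n_lig <- length(cluster$ligands)
  if (n_lig == 0) stop("cluster has no ligands")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  subset_radius <- function(mask) {
    if (!any(mask)) stop("cluster lacks required element subset")
    pts <- xyz[mask, , drop = FALSE]
    ctr <- colMeans(pts)
    max(sqrt(rowSums(sweep(pts, 2, ctr)^2)))
  }
  r_au <- subset_radius(el == "AU")
  r_c <- subset_radius(el == "C")
  mass <- atomic_mass(el)
  com <- colSums(xyz * mass) / sum(mass)
  cen <- sweep(xyz, 2, com)
  inert <- matrix(0, 3, 3)
  r2 <- rowSums(cen^2)
  for (a in 1:3) for (b in 1:3)
    inert[a, b] <- sum(mass * ((a == b) * r2 - cen[, a] * cen[, b]))
  ev <- sort(eigen(inert, symmetric = TRUE, only.values = TRUE)$values)
  jhat <- ev / sum(ev)
  c(n_nonH_frac = sum(el != "H") / n,
    n_au_frac = sum(el == "AU") / n,
    n_s_per_ligand = sum(el == "S") / n_lig,
    r_ratio = r_au / r_c,
    a_ratio = (r_au / r_c)^2,
    v_ratio = (r_au / r_c)^3,
    j1 = jhat[1], j2 = jhat[2], j3 = jhat[3])
}

# pi-pi stacking detection from ring geometry: centre distance within
# `dist_max` and near-parallel ring normals (angle <= ang_max or >= 180 -
# ang_max degrees). The flag is symmetric by construction.
detect_pi_stacking <- function(cluster, dist_max = 5.0, ang_max = 30) {
  nl <- length(cluster$ligands)
  xyz <- as.matrix(cluster$atoms[, c("x", "y", "z")])
  normals <- lapply(cluster$ligands, function(lg) {
    if (length(lg$ring_atoms) < 3) return(NULL)
    pts <- xyz[lg$ring_atoms, , drop = FALSE]
    sv <- svd(sweep(pts, 2, colMeans(pts)))
    sv$v[, 3]
  })
  flag <- rep(0, nl)
  if (nl < 2) return(flag)
  for (i in seq_len(nl - 1)) for (j in (i + 1):nl) {
    if (is.null(normals[[i]]) || is.null(normals[[j]])) next
    ci <- cluster$ring_centroids[i, ]; cj <- cluster$ring_centroids[j, ]
    if (any(is.na(ci)) || any(is.na(cj))) next
    if (sqrt(sum((ci - cj)^2)) > dist_max) next
    ang <- acos(pmin(1, abs(sum(normals[[i]] * normals[[j]])))) * 180 / pi
    if (ang <= ang_max) flag[i] <- flag[j] <- 1
  }
  flag
}

#' Per-ligand local descriptors
#'
#' For each protecting ligand: minimum head-to-head centroid distance,
#' minimum ring-centre distance, pi-pi stacking flag, mean minimum
#' inaccessible radius over all ligand atoms and over its oxygens, and a
#' one-hot of the ligand's position on its protecting unit (middle/end, plus
#' a bridge class only when any bridge ligand is present). Undefined
#' neighbour distances (single-ligand clusters) are set to the sentinel
#' 999.0.
#'
#' @param cluster a `cluster_model`.
#' @param pi_dist_max,pi_ang_max pi-stacking geometric thresholds
#'   (Angstrom / degrees).
#' @return matrix with one row per ligand (7 or 8 columns).
#' @export
ligand_descriptors <- function(cluster, pi_dist_max = 5.0, pi_ang_max = 30) {
  stopifnot(inherits(cluster, "cluster_model"))
  nl <- length(cluster$ligands)
  sentinel <- 999.0
  min_off_diag <- function(pts) {
    if (nrow(pts) < 2 || any(is.na(pts))) return(rep(sentinel, nrow(pts)))
    d <- as.matrix(stats::dist(pts))
    diag(d) <- Inf
    apply(d, 1, function(r) {
      r <- r[is.finite(r)]
      if (length(r) == 0) sentinel else min(r)
    })
  }
  d_heads <- min_off_diag(cluster$head_centroids)
  ring_ok <- stats::complete.cases(cluster$ring_centroids)
  d_rings <- rep(sentinel, nl)
  if (sum(ring_ok) >= 2) {
    d <- as.matrix(stats::dist(cluster$ring_centroids[ring_ok, , drop = FALSE]))
    diag(d) <- Inf
    d_rings[ring_ok] <- apply(d, 1, min)
  }
  if (nl < 2) nd_warn("single-ligand cluster: neighbour distances set to sentinel")
  pipi <- detect_pi_stacking(cluster, pi_dist_max, pi_ang_max)
  xyz <- as.matrix(cluster$atoms[, c("x", "y", "z")])
  el <- toupper(cluster$atoms$element)
  r_lig <- numeric(nl); r_oxy <- numeric(nl)
  for (i in seq_len(nl)) {
    lg <- cluster$ligands[[i]]
    own <- c(lg$head_atoms, lg$ring_atoms,
             if (!is.na(lg$sulfur)) lg$sulfur)
    obs <- xyz[-own, , drop = FALSE]
    b <- ray_buriedness(xyz[own, , drop = FALSE], obs)
    r_lig[i] <- mean(b$r_inacc)
    oxy <- own[el[own] == "O"]
    r_oxy[i] <- if (length(oxy) == 0) mean(b$r_inacc) else
      mean(b$r_inacc[match(oxy, own)])
  }
  pos <- vapply(cluster$ligands, function(l) l$unit_position, "")
  classes <- if (any(pos == "bridge")) c("middle", "end", "bridge") else
    c("middle", "end")
  out <- cbind(min_d_heads = d_heads, min_d_rings = d_rings, pi_pi = pipi,
               r_inacc_ligand = r_lig, r_inacc_oxygen = r_oxy,
               one_hot(pos, classes))
  colnames(out)[6:ncol(out)] <- paste0("pos_", classes)
  out
}

#' Featurize a cluster model
#'
#' Attaches `global_features` and `ligand_features` to the cluster.
#'
#' @param cluster a `cluster_model`.
#' @param ... passed to [ligand_descriptors()].
#' @return the cluster with feature fields filled.
#' @export
featurize_cluster <- function(cluster, ...) {
  cluster$global_features <- global_descriptors(cluster)
  cluster$ligand_features <- ligand_descriptors(cluster, ...)
  cluster
}

#' Concatenated ligand-residue pair feature vector
#'
#' `[global (9); ligand (7 or 8); WL-expanded node attributes]` -- with the
#' default two WL updates the node block has 117 entries and the full vector
#' 133 (134 with a bridge class).
#'
#' @param graph a `protein_graph` with `node_attr_wl` computed.
#' @param cluster a featurized `cluster_model`.
#' @param ligand_index,node_index 1-based indices.
#' @return numeric feature vector.
#' @export
pair_features <- function(graph, cluster, ligand_index, node_index) {
  if (is.null(graph$node_attr_wl)) stop("run wl_update() first")
  if (is.null(cluster$ligand_features)) stop("run featurize_cluster() first")
  nl <- nrow(cluster$ligand_features)
  nn <- nrow(graph$node_attr_wl)
  if (ligand_index < 1 || ligand_index > nl) stop("ligand index out of range")
  if (node_index < 1 || node_index > nn) stop("node index out of range")
  c(unname(cluster$global_features),
    unname(cluster$ligand_features[ligand_index, ]),
    unname(graph$node_attr_wl[node_index, ]))
}

# full pair-feature matrix, rows in (ligand, node) order for the given index
# pairs (2-column matrix)
pair_feature_matrix <- function(graph, cluster, pairs) {
  g <- matrix(unname(cluster$global_features), nrow(pairs),
              length(cluster$global_features), byrow = TRUE)
  l <- cluster$ligand_features[pairs[, 1], , drop = FALSE]
  n <- graph$node_attr_wl[pairs[, 2], , drop = FALSE]
  unname(cbind(g, l, n))
}
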