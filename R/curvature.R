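# Graph-theoretical node descriptors: Ricci curvatures, box-counting
# (multifractal) dimension, Gaussian-network-model mobility, and the
# Osipov-Pickup-Dunmur chirality index.

# Exact 1-Wasserstein distance between two uniform measures on node sets,
# with ground metric = shortest-path hop distance. Solved as a
# transportation LP (simplex method from the boot package).
wasserstein_uniform <- function(dists, set_a, set_b) {
  m <- length(set_a); n <- length(set_b)
  if (m == 0 || n == 0) return(NA_real_)
  cost <- dists[set_a, set_b, drop = FALSE]
  if (m == 1 || n == 1) return(sum(cost) / (m * n))
  # variables x_ij >= 0 (row-major); rows sum to 1/m, cols to 1/n.
  nv <- m * n
  A3 <- matrix(0, m + n - 1, nv)       # drop one redundant constraint
  for (i in seq_len(m)) A3[i, ((i - 1) * n + 1):(i * n)] <- 1
  for (j in seq_len(n - 1)) A3[m + j, seq(j, nv, by = n)] <- 1
  b3 <- c(rep(1 / m, m), rep(1 / n, n - 1))
  sol <- boot::simplex(a = as.numeric(t(cost)), A3 = A3, b3 = b3,
                       maxi = FALSE)
  as.numeric(sol$value)
}

#' Ollivier-Ricci curvature of a residue-graph node
#'
#' Edge curvature kappa(u,v) = 1 - W1(mu_u, mu_v) / d(u,v) with mu_x the
#' uniform probability measure on the neighbours of x and d the hop metric;
#' the node value is the mean over incident edges. Isolated nodes get 0.
#'
#' @param graph a `protein_graph`.
#' @param node node index, or NULL for all nodes.
#' @return numeric vector of node curvatures.
#' @export
ricci_ollivier <- function(graph, node = NULL) {
  adj <- graph$adjacency
  n <- nrow(adj)
  g <- as_igraph(graph)
  dists <- igraph::distances(g)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  edge_k <- new.env(parent = emptyenv())
  edge_curv <- function(u, v) {
    key <- paste(min(u, v), max(u, v))
    if (!is.null(edge_k[[key]])) return(edge_k[[key]])
    w1 <- wasserstein_uniform(dists, nbrs[[u]], nbrs[[v]])
    k <- 1 - w1 / dists[u, v]
    edge_k[[key]] <- k
    k
  }
  node_val <- function(i) {
    nb <- nbrs[[i]]
    if (length(nb) == 0) return(0)
    mean(vapply(nb, function(j) edge_curv(i, j), 0))
  }
  idx <- node %||% seq_len(n)
  vapply(idx, node_val, 0)
}

#' Forman-Ricci curvature of a residue-graph node
#'
#' Combinatorial Forman curvature of an unweighted edge (u,v) is
#' 4 - deg(u) - deg(v); the node value is the mean over incident edges
#' (0 for isolated nodes).
#'
#' @inheritParams ricci_ollivier
#' @return numeric vector of node curvatures.
#' @export
ricci_forman <- function(graph, node = NULL) {
  adj <- graph$adjacency
  deg <- rowSums(adj)
  idx <- node %||% seq_len(nrow(adj))
  vapply(idx, function(i) {
    nb <- which(adj[i, ])
    if (length(nb) == 0) return(0)
    mean(4 - deg[i] - deg[nb])
  }, 0)
}

#' Box-counting (multifractal) dimension of the residue graph
#'
#' Greedy covering of the graph by shortest-path balls of radius r for
#' r = 1..diameter; the dimension is minus the least-squares slope of
#' log N(r) against log r. Graphs of diameter < 2 return 0.
#'
#' @param graph a `protein_graph`.
#' @return a single scalar (broadcast to all nodes by the featurizer).
#' @export
graph_mfd <- function(graph) {
  g <- as_igraph(graph)
  dists <- igraph::distances(g)
  finite <- dists[is.finite(dists)]
  diam <- max(finite)
  if (diam < 2) return(0)
  radii <- seq_len(diam)
  nboxes <- vapply(radii, function(r) {
    uncovered <- rep(TRUE, nrow(dists))
    nb <- 0
    while (any(uncovered)) {
      cover <- rowSums(dists[, uncovered, drop = FALSE] <= r)
      c0 <- which.max(cover)
      uncovered[dists[c0, ] <= r] <- FALSE
      nb <- nb + 1
    }
    nb
  }, 0)
  keep <- nboxes >= 1
  if (sum(keep) < 2 || length(unique(nboxes[keep])) == 1) return(0)
  fit <- stats::lm.fit(cbind(1, log(radii[keep])), log(nboxes[keep]))
  -unname(fit$coefficients[2])
}

#' Gaussian-network-model mobility feature
#'
#' Per-node mean-square-fluctuation proxy: the diagonal of the Moore-Penrose
#' pseudoinverse of the contact-graph Laplacian, min-max scaled to [0,1]
#' within the protein. Depends only on the graph, so it is invariant under
#' rigid-body motion of the structure.
#'
#' @param graph a `protein_graph`.
#' @param node node index, or NULL for all nodes.
#' @return numeric vector in [0,1].
#' @export
gnm_feature <- function(graph, node = NULL) {
  adj <- graph$adjacency * 1
  lap <- diag(rowSums(adj)) - adj
  ginv <- MASS::ginv(lap)
  v <- diag(ginv)
  rng <- range(v)
  v <- if (diff(rng) < 1e-12) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  if (is.null(node)) v else v[node]
}

# OPD chirality kernel over a point set (rows of `pts`): rotation-invariant
# and antisymmetric under reflection. Sum over ordered quadruples of
# distinct points of
#   [ (r_ij x r_kl) . r_il ] (r_ij . r_jk)(r_jk . r_kl)
#   / ( (|r_ij||r_jk||r_kl|)^2 |r_il| )
# normalised by 4!/(3 m^4).
opd_kernel <- function(pts) {
  m <- nrow(pts)
  if (m < 4) return(0)
  idx <- seq_len(m)
  total <- 0
  for (i in idx) for (j in idx) {
    if (j == i) next
    rij <- pts[j, ] - pts[i, ]
    nij <- sqrt(sum(rij^2))
    for (k in idx) {
      if (k == i || k == j) next
      rjk <- pts[k, ] - pts[j, ]
      njk <- sqrt(sum(rjk^2))
      dot1 <- sum(rij * rjk)
      for (l in idx) {
        if (l == i || l == j || l == k) next
        rkl <- pts[l, ] - pts[k, ]
        ril <- pts[l, ] - pts[i, ]
        nkl <- sqrt(sum(rkl^2))
        nil <- sqrt(sum(ril^2))
        cr <- c(rij[2] * rkl[3] - rij[3] * rkl[2],
                rij[3] * rkl[1] - rij[1] * rkl[3],
                rij[1] * rkl[2] - rij[2] * rkl[1])
        total <- total + sum(cr * ril) * dot1 * sum(rjk * rkl) /
          ((nij * njk * nkl)^2 * nil)
      }
    }
  }
  total * factorial(4) / (3 * m^4)
}

#' Osipov-Pickup-Dunmur chirality index of a residue's local environment
#'
#' Evaluated over the residue's C-alpha and its k nearest C-alpha
#' neighbours. The index is rotation-invariant and changes sign under
#' mirror reflection; achiral (e.g. planar) configurations score 0.
#'
#' @param cp a `coarse_protein` (or a `protein_graph`, whose C-alpha
#'   coordinates are used).
#' @param node node index, or NULL for all nodes.
#' @param k number of nearest neighbours (5 or 7 in the default registry).
#' @return numeric vector of chirality indices.
#' @export
opd_chirality <- function(cp, node = NULL, k = 5) {
  ca <- if (inherits(cp, "coarse_protein")) cp$ca else cp$ca
  n <- nrow(ca)
  if (n < k + 1) stop("need at least k+1 = ", k + 1, " residues")
  d <- as.matrix(stats::dist(ca))
  idx <- node %||% seq_len(n)
  vapply(idx, function(i) {
    nb <- order(d[i, ])[2:(k + 1)]
    opd_kernel(ca[c(i, nb), , drop = FALSE])
  }, 0)
}
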