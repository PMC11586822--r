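#' Build the residue contact graph of a coarse-grained protein
#'
#' Residues are nodes; an undirected, unweighted edge connects two residues
#' whenever their C-alpha atoms lie within `cutoff` of each other. Edge
#' weights are all one.
#'
#' @param cp a `coarse_protein`.
#' @param cutoff contact distance in Angstrom (default 4.5).
#' @return object of class `protein_graph`: labels, adjacency matrix, edge
#'   list, C-alpha coordinates and (after [compute_node_features()] /
#'   [wl_update()]) node attribute matrices.
#' @export
build_graph <- function(cp, cutoff = 4.5) {
  stopifnot(inherits(cp, "coarse_protein"))
  n <- nrow(cp$ca)
  if (n < 2) stop("graph construction needs at least 2 residues")
  d <- as.matrix(stats::dist(cp$ca))
  adj <- d <= cutoff
  diag(adj) <- FALSE
  edges <- which(adj & upper.tri(adj), arr.ind = TRUE)
  structure(list(
    labels = cp$labels,
    ca = cp$ca,
    cutoff = cutoff,
    adjacency = adj,
    edges = unname(edges),
    degree = rowSums(adj),
    node_attr_raw = NULL,
    node_attr_wl = NULL),
    class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("Residue graph:", nrow(x$adjacency), "nodes,", nrow(x$edges),
      "edges (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

#' Continuous Weisfeiler-Lehman attribute propagation
#'
#' Each update averages a node's attribute vector with the mean attribute of
#' its neighbours:
#' a^(i+1)(v) = 1/2 * ( a^i(v) + (1/deg v) * sum_u w(v,u) a^i(u) ),
#' with all edge weights one and the neighbour term defined as zero for
#' isolated nodes. The final representation concatenates the raw attributes
#' with each update, so its width is `ncol(raw) * (n_updates + 1)`.
#'
#' @param graph a `protein_graph` with `node_attr_raw` computed (or an
#'   explicit `attr` matrix).
#' @param n_updates number of WL updates (default 2).
#' @param attr optional attribute matrix overriding `graph$node_attr_raw`.
#' @return the graph with `node_attr_wl` filled (or, when `graph` is a plain
#'   matrix, the concatenated attribute matrix).
#' @export
wl_update <- function(graph, n_updates = 2, attr = NULL) {
  plain <- !inherits(graph, "protein_graph")
  a <- if (plain) as.matrix(attr %||% graph) else
    attr %||% graph$node_attr_raw
  if (is.null(a)) stop("node attributes not computed yet")
  a <- as.matrix(a)
  adj <- if (plain) {
    stopifnot(!is.null(attr))        # plain call: graph is the adjacency
    as.matrix(graph) > 0
  } else graph$adjacency
  deg <- rowSums(adj)
  out <- a
  cur <- a
  if (n_updates > 0) for (i in seq_len(n_updates)) {
    nb <- (adj %*% cur) / pmax(deg, 1)   # deg 0: neighbour sum is 0 anyway
    cur <- 0.5 * (cur + nb)
    out <- cbind(out, cur)
  }
  if (plain) return(out)
  graph$node_attr_wl <- out
  graph$n_wl <- n_updates
  graph
}
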