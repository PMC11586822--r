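# Per-residue node attribute providers. The default registry reproduces the
# 39-dimensional attribute vector: element counts (4), molecular mass (1),
# amino-acid type (5), hydrophobicity (5), secondary structure (8),
# relative ASA (1), SASA (1), accessible shell (1), pocketness (1+5),
# minimum inaccessible radius (1), OPD chirality at 5 and 7 neighbours (2),
# Ollivier-Ricci (1), Forman-Ricci (1), box-counting dimension (1), GNM (1).

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param coords n x 3 heavy-atom coordinates (Angstrom).
#' @param elements element symbols (sets van der Waals radii).
#' @param probe probe radius, default 1.4 Angstrom (water).
#' @param n_points sphere test points per atom.
#' @return per-atom SASA in Angstrom^2.
#' @export
shrake_rupley <- function(coords, elements, probe = 1.4, n_points = 92) {
  coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  radii <- vdw_radius(elements) + probe
  sphere <- fibonacci_sphere(n_points)
  d <- cross_dist(coords, coords)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < radii[i] + max(radii) & seq_len(n) != i)
    nb <- nb[d[i, nb] < radii[i] + radii[nb]]
    pts <- sphere * radii[i] + matrix(coords[i, ], n_points, 3, byrow = TRUE)
    if (length(nb) > 0) {
      dd <- cross_dist(pts, coords[nb, , drop = FALSE])
      free <- rowSums(dd < matrix(radii[nb], n_points, length(nb),
                                  byrow = TRUE)) == 0
    } else free <- rep(TRUE, n_points)
    out[i] <- 4 * pi * radii[i]^2 * mean(free)
  }
  out
}

# Ray-probe buriedness of origin points against obstacle atoms.
# For each origin, rays are cast along n_dir evenly spread directions and
# marched outward in 1-A steps up to rmax; a ray is blocked at the first
# sample point within `clash` of an obstacle. Returns per-origin summaries.
ray_buriedness <- function(origins, obstacles, rmax = 10, n_dir = 26,
                           clash = 2.0) {
  origins <- matrix(origins, ncol = 3)
  dirs <- fibonacci_sphere(n_dir)
  radii <- seq(1, rmax, by = 1)
  nor <- nrow(origins)
  first_block <- matrix(Inf, nor, n_dir)
  has_obs <- !is.null(obstacles) && nrow(obstacles) > 0
  for (o in seq_len(nor)) {
    if (!has_obs) next
    # sample points: n_dir x length(radii)
    for (ri in seq_along(radii)) {
      open <- !is.finite(first_block[o, ])
      if (!any(open)) break
      pts <- dirs[open, , drop = FALSE] * radii[ri] +
        matrix(origins[o, ], sum(open), 3, byrow = TRUE)
      dd <- cross_dist(pts, obstacles)
      hit <- apply(dd, 1, min) < clash
      first_block[o, which(open)[hit]] <- radii[ri]
    }
  }
  fb <- pmin(first_block, rmax + 1)
  list(
    pocketness = rowMeans(is.finite(first_block)),
    acc_shell = rowMeans((pmin(fb, rmax) - 1) / (rmax - 1)),
    r_inacc = apply(fb, 1, min),
    banded = sapply(c(2, 4, 6, 8, 10), function(b)
      rowMeans(first_block <= b)))
}

# Simplified C-alpha-geometry secondary-structure assignment (distance
# windows in the style of P-SEA), used by the internal provider; external
# mode reads true 8-class labels from an annotation table.
ca_secondary_structure <- function(ca) {
  n <- nrow(ca)
  cls <- rep("C", n)
  dk <- function(k) {
    v <- rep(NA_real_, n)
    if (n > k) v[seq_len(n - k)] <-
      sqrt(rowSums((ca[seq_len(n - k) + k, , drop = FALSE] -
                    ca[seq_len(n - k), , drop = FALSE])^2))
    v
  }
  d2 <- dk(2); d3 <- dk(3); d4 <- dk(4)
  for (i in seq_len(n)) {
    if (!is.na(d3[i]) && !is.na(d4[i]) &&
        d3[i] >= 4.5 && d3[i] <= 6.5 && d4[i] >= 4.2 && d4[i] <= 6.9) {
      cls[i:min(n, i + 3)] <- "H"
    } else if (!is.na(d2[i]) && !is.na(d3[i]) &&
               d2[i] >= 6.3 && d2[i] <= 7.3 && d3[i] >= 9.0 && d3[i] <= 11.0) {
      if (cls[i] == "C") cls[i:min(n, i + 2)] <- "E"
    } else if (!is.na(d3[i]) && d3[i] < 4.5 && cls[i] == "C") {
      cls[i] <- "T"
    }
  }
  cls
}

one_hot <- function(values, classes) {
  m <- matrix(0, length(values), length(classes))
  idx <- match(values, classes)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  # unknown labels fall into the last (catch-all) class
  if (any(!ok)) m[cbind(which(!ok), length(classes))] <- 1
  m
}

annotation_lookup <- function(annotations, labels, cols) {
  if (is.null(annotations)) stop("provider in external mode but no annotation table given")
  key_a <- paste(annotations$chain_id, annotations$residue_id)
  key_n <- paste(labels$chain_id, labels$residue_id)
  idx <- match(key_n, key_a)
  if (anyNA(idx))
    stop("annotation table missing residue(s): ",
         paste(utils::head(key_n[is.na(idx)], 5), collapse = ", "))
  as.matrix(annotations[idx, cols, drop = FALSE])
}

residue_atom_groups <- function(atoms, labels) {
  if (is.null(atoms)) return(NULL)
  key_a <- paste(atoms$chain_id, atoms$residue_id)
  key_n <- paste(labels$chain_id, labels$residue_id)
  lapply(key_n, function(k) which(key_a == k & atoms$element != "H"))
}

#' Default node-feature provider registry
#'
#' Returns the ordered list of providers whose dimensions sum to 39.
#' Surface/pocket providers run in `"internal"` mode (built-in geometric
#' estimators) or `"external"` mode (values read from an annotation CSV with
#' columns chain_id, residue_id, dssp_class, rel_asa, sasa, acc_shell,
#' pocketness, pocketness_c1..c5, r_inacc).
#'
#' @param mode `"internal"` or `"external"` for the pluggable providers.
#' @param hydrophobicity optional replacement 21 x 5 scale table.
#' @return named list of providers (each with `dim` and `fn`).
#' @export
default_feature_registry <- function(mode = "internal",
                                     hydrophobicity = NULL) {
  mode <- match.arg(mode, c("internal", "external"))
  hyd <- hydrophobicity %||% HYDROPHOBICITY_SCALES
  list(
    elements = list(dim = 4, fn = function(ctx) {
      if (!is.null(ctx$groups)) {
        t(vapply(seq_along(ctx$groups), function(i) {
          g <- ctx$groups[[i]]
          if (length(g) == 0)
            return(as.numeric(RESIDUE_ELEMENT_COUNTS[ctx$resnames[i], ]))
          el <- ctx$atoms$element[g]
          c(sum(el == "C"), sum(el == "N"), sum(el == "O"), sum(el == "S"))
        }, numeric(4)))
      } else {
        rn <- ifelse(ctx$resnames %in% rownames(RESIDUE_ELEMENT_COUNTS),
                     ctx$resnames, "ALA")
        RESIDUE_ELEMENT_COUNTS[rn, , drop = FALSE]
      }
    }),
    mass = list(dim = 1, fn = function(ctx) {
      if (!is.null(ctx$groups)) {
        cbind(vapply(seq_along(ctx$groups), function(i) {
          g <- ctx$groups[[i]]
          if (length(g) == 0)
            return(unname(RESIDUE_MASS[ctx$resnames[i]]))
          sum(atomic_mass(ctx$atoms$element[g]))
        }, 0))
      } else {
        rn <- ifelse(ctx$resnames %in% names(RESIDUE_MASS), ctx$resnames, "ALA")
        cbind(unname(RESIDUE_MASS[rn]))
      }
    }),
    aa_type = list(dim = 5, fn = function(ctx) {
      cls <- vapply(ctx$resnames, function(r) {
        i <- aa_class_index(r)
        if (is.na(i)) "special" else names(AA_CLASSES)[i]
      }, "")
      one_hot(cls, names(AA_CLASSES))
    }),
    hydrophobicity = list(dim = 5, fn = function(ctx) {
      rn <- ifelse(ctx$resnames %in% rownames(hyd), ctx$resnames, "ALA")
      unname(hyd[rn, , drop = FALSE])
    }),
    dssp = list(dim = 8, fn = function(ctx) {
      cls <- if (mode == "external")
        as.character(annotation_lookup(ctx$annotations, ctx$labels,
                                       "dssp_class"))
      else ca_secondary_structure(ctx$ca)
      one_hot(cls, DSSP_CLASSES)
    }),
    rel_asa = list(dim = 1, fn = function(ctx) {
      if (mode == "external")
        return(annotation_lookup(ctx$annotations, ctx$labels, "rel_asa"))
      mx <- MAX_ASA[ifelse(ctx$resnames %in% names(MAX_ASA),
                           ctx$resnames, "ALA")]
      cbind(pmin(ctx$sasa / unname(mx), 1.5))
    }),
    sasa = list(dim = 1, fn = function(ctx) {
      if (mode == "external")
        return(annotation_lookup(ctx$annotations, ctx$labels, "sasa"))
      cbind(ctx$sasa)
    }),
    acc_shell = list(dim = 1, fn = function(ctx) {
      if (mode == "external")
        return(annotation_lookup(ctx$annotations, ctx$labels, "acc_shell"))
      cbind(ctx$probe$acc_shell)
    }),
    pocketness = list(dim = 1, fn = function(ctx) {
      if (mode == "external")
        return(annotation_lookup(ctx$annotations, ctx$labels, "pocketness"))
      cbind(ctx$probe$pocketness)
    }),
    pocketness_clust = list(dim = 5, fn = function(ctx) {
      if (mode == "external")
        return(annotation_lookup(ctx$annotations, ctx$labels,
                                 paste0("pocketness_c", 1:5)))
      ctx$probe$banded
    }),
    r_inacc = list(dim = 1, fn = function(ctx) {
      if (mode == "external")
        return(annotation_lookup(ctx$annotations, ctx$labels, "r_inacc"))
      cbind(ctx$probe$r_inacc)
    }),
    opd = list(dim = 2, fn = function(ctx) {
      n <- nrow(ctx$ca)
      k5 <- if (n >= 6) opd_chirality(ctx$cp, k = 5) else numeric(n)
      k7 <- if (n >= 8) opd_chirality(ctx$cp, k = 7) else numeric(n)
      cbind(k5, k7)
    }),
    ollivier = list(dim = 1, fn = function(ctx) cbind(ricci_ollivier(ctx$graph))),
    forman = list(dim = 1, fn = function(ctx) cbind(ricci_forman(ctx$graph))),
    mfd = list(dim = 1, fn = function(ctx)
      cbind(rep(graph_mfd(ctx$graph), nrow(ctx$ca)))),
    gnm = list(dim = 1, fn = function(ctx) cbind(gnm_feature(ctx$graph)))
  )
}

#' Compute raw node attributes for a residue graph
#'
#' Runs every provider of the registry in order and column-binds the blocks;
#' with the default registry the result has exactly 39 columns per node.
#'
#' @param graph a `protein_graph`.
#' @param atoms optional atom records (enables atom-count, mass and surface
#'   features to be measured from the structure rather than looked up).
#' @param registry provider list from [default_feature_registry()].
#' @param annotations optional annotation data.frame for external-mode
#'   providers.
#' @return the graph with `node_attr_raw` filled.
#' @export
compute_node_features <- function(graph, atoms = NULL,
                                  registry = default_feature_registry(),
                                  annotations = NULL) {
  stopifnot(inherits(graph, "protein_graph"))
  labels <- graph$labels
  cp <- structure(list(ca = graph$ca, labels = labels),
                  class = "coarse_protein")
  groups <- residue_atom_groups(atoms, labels)
  # shared geometric context, computed once
  sasa <- NULL
  probe <- NULL
  needs_geo <- any(names(registry) %in%
                     c("rel_asa", "sasa", "acc_shell", "pocketness",
                       "pocketness_clust", "r_inacc"))
  if (needs_geo) {
    heavy_xyz <- if (!is.null(atoms)) {
      hv <- atoms[atoms$element != "H", , drop = FALSE]
      as.matrix(hv[, c("x", "y", "z")])
    } else graph$ca
    heavy_el <- if (!is.null(atoms)) atoms$element[atoms$element != "H"]
      else rep("C", nrow(graph$ca))
    per_atom <- shrake_rupley(heavy_xyz, heavy_el)
    sasa <- if (!is.null(atoms)) {
      hv_key <- paste(atoms$chain_id[atoms$element != "H"],
                      atoms$residue_id[atoms$element != "H"])
      nk <- paste(labels$chain_id, labels$residue_id)
      vapply(nk, function(k) sum(per_atom[hv_key == k]), 0)
    } else per_atom
    # obstacles for a residue: every heavy atom of the *other* residues
    probe <- local({
      n <- nrow(graph$ca)
      res <- list(pocketness = numeric(n), acc_shell = numeric(n),
                  r_inacc = numeric(n), banded = matrix(0, n, 5))
      hv_key <- if (!is.null(atoms))
        paste(atoms$chain_id[atoms$element != "H"],
              atoms$residue_id[atoms$element != "H"])
      else paste(labels$chain_id, labels$residue_id)
      nk <- paste(labels$chain_id, labels$residue_id)
      for (i in seq_len(n)) {
        obs <- heavy_xyz[hv_key != nk[i], , drop = FALSE]
        b <- ray_buriedness(graph$ca[i, , drop = FALSE], obs)
        res$pocketness[i] <- b$pocketness
        res$acc_shell[i] <- b$acc_shell
        res$r_inacc[i] <- b$r_inacc
        res$banded[i, ] <- b$banded
      }
      res
    })
  }
  ctx <- list(graph = graph, cp = cp, ca = graph$ca, labels = labels,
              resnames = labels$residue_name, atoms = atoms, groups = groups,
              annotations = annotations, sasa = sasa, probe = probe)
  blocks <- lapply(names(registry), function(nm) {
    b <- as.matrix(registry[[nm]]$fn(ctx))
    if (ncol(b) != registry[[nm]]$dim)
      stop("provider '", nm, "' returned ", ncol(b),
           " columns, declared ", registry[[nm]]$dim)
    if (nrow(b) != nrow(graph$ca))
      stop("provider '", nm, "' returned wrong number of rows")
    if (any(!is.finite(b)))
      stop("provider '", nm, "' produced non-finite values")
    b
  })
  attrmat <- do.call(cbind, blocks)
  colnames(attrmat) <- unlist(lapply(names(registry), function(nm)
    paste0(nm, "_", seq_len(registry[[nm]]$dim))))
  graph$node_attr_raw <- attrmat
  graph
}
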