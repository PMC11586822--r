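# Atomic masses (Da) for centre-of-mass and inertia computations.
ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 SE = 78.97, P = 30.974, AU = 196.967)

atomic_mass <- function(element) {
  m <- ATOMIC_MASS[toupper(element)]
  ifelse(is.na(m), 12.011, m)
}

WATER_RESNAMES <- c("HOH", "WAT", "TIP", "SOL", "DOD")
ION_RESNAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "SO4", "PO4")

#' Read a protein structure from a PDB file
#'
#' Parses all ATOM/HETATM records of the requested model. Waters and common
#' monatomic ions are dropped; alternate locations are resolved by keeping
#' the highest-occupancy copy of each atom (ties: first encountered).
#' Insertion codes are preserved and take part in residue identity.
#'
#' @param path path to a PDB file.
#' @param model_index 1-based model number for multi-model files.
#' @return data.frame of atom records with columns `element`, `x`, `y`, `z`,
#'   `chain_id`, `residue_id`, `insert`, `residue_name`, `atom_name`,
#'   `occupancy` and a `residue_key` uniquely identifying each residue.
#' @export
read_protein <- function(path, model_index = 1) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                         verbose = FALSE)
  n_models <- nrow(pdb$xyz)
  if (model_index < 1 || model_index > n_models)
    stop("model_index ", model_index, " out of range (file has ",
         n_models, " model(s))")
  xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  at <- pdb$atom
  elem <- toupper(trimws(at$elesy))
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- substr(gsub("[0-9']", "", at$elety[bad]), 1, 1)
  atoms <- data.frame(
    element = elem,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    residue_id = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    residue_name = toupper(trimws(at$resid)),
    atom_name = trimws(at$elety),
    occupancy = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  atoms <- atoms[!(atoms$residue_name %in% c(WATER_RESNAMES, ION_RESNAMES)), ,
                 drop = FALSE]
  if (nrow(atoms) == 0) stop("no usable atom records in ", path)
  atoms$residue_key <- paste(atoms$chain_id, atoms$residue_id, atoms$insert,
                             sep = "|")
  # altloc resolution: keep highest occupancy per (residue, atom name)
  key <- paste(atoms$residue_key, atoms$atom_name, sep = "@")
  ord <- order(key, -atoms$occupancy, seq_len(nrow(atoms)))
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$residue_key, atoms$atom_name,
                                   sep = "@")), , drop = FALSE]
  atoms <- atoms[order(atoms$chain_id, atoms$residue_id, atoms$insert,
                       atoms$atom_name), , drop = FALSE]
  rownames(atoms) <- NULL
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  atoms
}

#' Reduce atom records to an alpha-carbon coarse-grained protein
#'
#' Keeps one C-alpha coordinate per residue, ordered by chain then residue
#' number. Residues lacking a CA atom are excluded with a warning.
#'
#' @param atoms atom record data.frame from [read_protein()].
#' @return an object of class `coarse_protein`: list with `ca` (n x 3 matrix,
#'   Angstrom) and `labels` (data.frame `chain_id`, `residue_id`,
#'   `residue_name`).
#' @export
extract_coarse_protein <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  res_keys <- unique(atoms$residue_key)
  ca <- atoms[atoms$atom_name == "CA" & atoms$element != "CA", , drop = FALSE]
  if (nrow(ca) == 0) ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no C-alpha atoms present")
  missing <- setdiff(res_keys, ca$residue_key)
  if (length(missing) > 0)
    nd_warn("%d residue(s) lack a CA atom and were excluded: %s",
            length(missing), paste(utils::head(missing, 5), collapse = ", "))
  ord <- order(ca$chain_id, ca$residue_id, ca$insert)
  ca <- ca[ord, , drop = FALSE]
  cp <- structure(list(
    ca = unname(as.matrix(ca[, c("x", "y", "z")])),
    labels = data.frame(chain_id = ca$chain_id,
                        residue_id = ca$residue_id,
                        residue_name = ca$residue_name,
                        stringsAsFactors = FALSE)),
    class = "coarse_protein")
  d <- as.matrix(stats::dist(cp$ca))
  diag(d) <- Inf
  if (any(d < 0.1))
    nd_warn("C-alpha atoms closer than 0.1 A detected; check altloc handling")
  cp
}

#' @export
print.coarse_protein <- function(x, ...) {
  cat("Coarse-grained protein:", nrow(x$ca), "residues,",
      length(unique(x$labels$chain_id)), "chain(s)\n")
  invisible(x)
}

#' Read an XYZ file (single- or multi-frame)
#'
#' @param path path to an XYZ file.
#' @return list of frames; each frame is a list with `elements` (character)
#'   and `coords` (n x 3 matrix, Angstrom).
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1) stop("malformed XYZ atom count at line ", i)
    if (i + 1 + n > length(lines)) stop("truncated XYZ frame at line ", i)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    frames[[length(frames) + 1]] <- list(
      elements = toupper(vapply(parts, `[`, "", 1)),
      coords = matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                      ncol = 3, byrow = TRUE))
    i <- i + 2 + n
  }
  frames
}

#' Write coordinates as a (multi-frame) XYZ file
#'
#' @param frames list of frames as returned by [read_xyz()], or a single
#'   frame list.
#' @param path output path.
#' @param comment per-frame comment line(s).
#' @export
write_xyz <- function(frames, path, comment = "") {
  if (!is.null(frames$coords)) frames <- list(frames)
  comment <- rep_len(comment, length(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    writeLines(c(as.character(nrow(fr$coords)), comment[k]), con)
    writeLines(sprintf("%-2s %12.6f %12.6f %12.6f", fr$elements,
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Read a rigid nanocluster with its ligand topology
#'
#' The structure may be an XYZ or PDB file; the topology sidecar is a JSON
#' file describing each protecting ligand:
#' \preformatted{
#' {"ligands": [
#'    {"head_atoms": [1-based indices of the charged head group],
#'     "ring_atoms": [indices of the aromatic ring, may be empty],
#'     "sulfur": index of the anchoring sulfur (optional),
#'     "ligand_type": "pMBA",
#'     "unit_position": "middle" | "end" | "bridge"}, ...]}
#' }
#'
#' @param structure_path XYZ or PDB file with all cluster atoms.
#' @param topology_path JSON ligand-topology sidecar.
#' @return object of class `cluster_model`: atoms, ligand topology, head and
#'   ring centroids (Angstrom) and the mass-weighted centre of mass.
#' @export
read_cluster <- function(structure_path, topology_path) {
  ext <- tolower(tools::file_ext(structure_path))
  if (ext == "xyz") {
    fr <- read_xyz(structure_path)[[1]]
    atoms <- data.frame(element = fr$elements, x = fr$coords[, 1],
                        y = fr$coords[, 2], z = fr$coords[, 3],
                        stringsAsFactors = FALSE)
  } else {
    rec <- read_protein(structure_path)
    atoms <- rec[, c("element", "x", "y", "z")]
  }
  topo <- jsonlite::fromJSON(topology_path, simplifyVector = FALSE)
  if (is.null(topo$ligands) || length(topo$ligands) == 0)
    stop("topology sidecar contains no ligands")
  ligands <- lapply(topo$ligands, function(lg) {
    lg$head_atoms <- as.integer(unlist(lg$head_atoms))
    lg$ring_atoms <- as.integer(unlist(lg$ring_atoms %||% integer()))
    lg$sulfur <- if (!is.null(lg$sulfur)) as.integer(lg$sulfur) else NA_integer_
    lg$ligand_type <- lg$ligand_type %||% "generic"
    lg$unit_position <- match.arg(lg$unit_position %||% "middle",
                                  c("middle", "end", "bridge"))
    lg
  })
  new_cluster_model(atoms, ligands)
}

new_cluster_model <- function(atoms, ligands, head_charges = NULL) {
  n <- nrow(atoms)
  for (lg in ligands) {
    idx <- c(lg$head_atoms, lg$ring_atoms,
             if (!is.na(lg$sulfur)) lg$sulfur)
    if (length(lg$head_atoms) < 1) stop("ligand without head atoms")
    if (any(idx < 1 | idx > n))
      stop("topology references atom index outside structure (n = ", n, ")")
    if (anyDuplicated(c(lg$head_atoms, lg$ring_atoms)))
      stop("head and ring atom sets overlap within a ligand")
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  mass <- atomic_mass(atoms$element)
  com <- colSums(coords * mass) / sum(mass)
  centroid <- function(idx) if (length(idx)) colMeans(coords[idx, , drop = FALSE]) else rep(NA_real_, 3)
  structure(list(
    atoms = atoms,
    ligands = ligands,
    head_centroids = do.call(rbind, lapply(ligands, function(l) centroid(l$head_atoms))),
    ring_centroids = do.call(rbind, lapply(ligands, function(l) centroid(l$ring_atoms))),
    com = as.numeric(com),
    head_charges = head_charges),
    class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Nanocluster model:", nrow(x$atoms), "atoms,",
      length(x$ligands), "ligands\n")
  invisible(x)
}

#' Write a posed nanocluster-protein complex as PDB
#'
#' Protein chains are written as ATOM records, the cluster (transformed by
#' `pose`, a rigid rotation about its centre of mass plus a translation) as
#' HETATM records in chain "X".
#'
#' @param protein_atoms atom records from [read_protein()].
#' @param cluster cluster_model (or a data.frame of cluster atoms).
#' @param pose list with rotation matrix `R` (orthonormal, det +1) and
#'   translation `t` (Angstrom).
#' @param path output PDB path.
#' @export
write_complex <- function(protein_atoms, cluster, pose, path) {
  if (!is_rotation(pose$R)) stop("pose rotation is not orthonormal with det +1")
  if (inherits(cluster, "cluster_model")) {
    cl_atoms <- cluster$atoms
    com <- cluster$com
  } else {
    cl_atoms <- cluster
    cc <- as.matrix(cl_atoms[, c("x", "y", "z")])
    com <- colSums(cc * atomic_mass(cl_atoms$element)) / sum(atomic_mass(cl_atoms$element))
  }
  moved <- apply_pose(as.matrix(cl_atoms[, c("x", "y", "z")]), pose, com)
  np <- nrow(protein_atoms)
  nc <- nrow(cl_atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(rbind(as.matrix(protein_atoms[, c("x", "y", "z")]),
                             moved))),
    type = c(rep("ATOM", np), rep("HETATM", nc)),
    resno = c(protein_atoms$residue_id, rep(1L, nc)),
    resid = c(protein_atoms$residue_name, rep("NC", nc)),
    eleno = seq_len(np + nc),
    elety = c(protein_atoms$atom_name,
              make.unique(cl_atoms$element, sep = "")),
    chain = c(protein_atoms$chain_id, rep("X", nc)),
    elesy = c(protein_atoms$element, cl_atoms$element),
    o = rep(1, np + nc), b = rep(0, np + nc))
  invisible(path)
}

#' Read a trajectory as a list of coordinate frames
#'
#' Multi-frame XYZ or multi-model PDB; every frame must contain the same
#' atoms in the same order.
#'
#' @param path trajectory file.
#' @return list of frames with `elements` and `coords`.
#' @export
read_trajectory <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xyz") return(read_xyz(path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  elem <- toupper(trimws(pdb$atom$elesy))
  lapply(seq_len(nrow(pdb$xyz)), function(i)
    list(elements = elem,
         coords = matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)))
}
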