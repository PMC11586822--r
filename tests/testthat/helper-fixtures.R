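# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; no binary data.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- build()
  .fx_cache[[name]]
}

# benchmark system: 60-residue chain with one compact planted patch and a
# compact 8-ligand cluster (see the methods vignette for the size choice)
fx_protein <- function() fx("protein", function() make_protein(60, seed = 3))
fx_cluster <- function() fx("cluster", function()
  make_cluster(8, radius = 3.5, seed = 2))

fx_graph <- function() fx("graph", function() {
  p <- fx_protein()
  g <- build_graph(p$cp)
  g <- compute_node_features(g, atoms = p$atoms)
  wl_update(g, 2)
})

fx_training <- function() fx("training", function()
  sample_configurations(fx_graph(), fx_protein(), fx_cluster(), 240,
                        seed = 5))

fx_model <- function() fx("model", function()
  suppressWarnings(train_interaction_model(fx_training()[1:200], seed = 7,
                                           epochs = 150, folds = 5)))

fx_table <- function() fx("table", function()
  interaction_table(fx_model(), fx_graph(), fx_cluster()))

# --- tiny hand-written PDB fixtures ---------------------------------------

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, rec = "ATOM", elem = substr(name, 1, 1),
                     alt = " ") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, name, alt, resname, chain, resno, x, y, z, occ, 0,
          elem)
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}

# 3 residues, one CA each, consecutive CA spacing 3.8 A
toy_pdb_3res <- function(path = tempfile(fileext = ".pdb")) {
  write_toy_pdb(path, c(
    pdb_line(1, "N", "ALA", "A", 1, -1.2, 0.5, 0),
    pdb_line(2, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(3, "C", "ALA", "A", 1, 1.2, 0.6, 0),
    pdb_line(4, "O", "ALA", "A", 1, 1.3, 1.8, 0),
    pdb_line(5, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_line(6, "N", "GLY", "A", 2, 3.0, 1.0, 0),
    pdb_line(7, "C", "GLY", "A", 2, 5.0, 0.8, 0),
    pdb_line(8, "O", "GLY", "A", 2, 5.1, 2.0, 0),
    pdb_line(9, "CA", "SER", "A", 3, 7.6, 0, 0)))
}

fx_synthetic_complex_paths <- function() fx("synth_paths", function() {
  cl <- fx_cluster()
  xyz <- tempfile(fileext = ".xyz")
  topo <- tempfile(fileext = ".json")
  write_cluster(cl, xyz, topo)
  list(xyz = xyz, topology = topo)
})
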