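test_that("a toy PDB parses into one CA per residue", {
  atoms <- read_protein(toy_pdb_3res())
  cp <- extract_coarse_protein(atoms)
  expect_equal(nrow(cp$ca), 3)
  expect_equal(cp$labels$residue_name, c("ALA", "GLY", "SER"))
  expect_equal(unname(cp$ca[2, ] - cp$ca[1, ]), c(3.8, 0, 0))
})

test_that("multi-model PDB returns the requested model's coordinates", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line(1, "CA", "ALA", "A", 1, 10, 0, 0),
    pdb_line(2, "CA", "GLY", "A", 2, 13.8, 0, 0),
    "ENDMDL",
    "END"), path)
  a1 <- read_protein(path, model_index = 1)
  a2 <- read_protein(path, model_index = 2)
  expect_equal(a1$x[a1$atom_name == "CA"][1], 0)
  expect_equal(a2$x[a2$atom_name == "CA"][1], 10)
  expect_error(read_protein(path, model_index = 3), "out of range")
})

test_that("residues without a CA are excluded with a warning", {
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_line(2, "N", "GLY", "A", 2, 3.8, 0, 0),   # no CA in residue 2
    pdb_line(3, "CA", "SER", "A", 3, 7.6, 0, 0)))
  atoms <- read_protein(path)
  expect_warning(cp <- extract_coarse_protein(atoms), "lack a CA")
  expect_equal(nrow(cp$ca), 2)
  expect_false("GLY" %in% cp$labels$residue_name)
})

test_that("chains are ordered chain-major then residue-major", {
  lines <- c(
    lapply(5:1, function(i)
      pdb_line(i, "CA", "ALA", "B", i, 50 + 3.8 * i, 0, 0)),
    lapply(1:5, function(i)
      pdb_line(10 + i, "CA", "GLY", "A", i, 3.8 * i, 0, 0)))
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), unlist(lines))
  cp <- extract_coarse_protein(read_protein(path))
  expect_equal(cp$labels$chain_id, rep(c("A", "B"), each = 5))
  expect_equal(cp$labels$residue_id, rep(1:5, 2))
})

test_that("alternate locations resolve to the highest occupancy", {
  path <- write_toy_pdb(tempfile(fileext = ".pdb"), c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 9, 9, 9, occ = 0.6, alt = "B"),
    pdb_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0)))
  atoms <- read_protein(path)
  ca1 <- atoms[atoms$residue_id == 1 & atoms$atom_name == "CA", ]
  expect_equal(nrow(ca1), 1)
  expect_equal(ca1$x, 9)
})

test_that("cluster reading computes head centroids and validates topology", {
  paths <- fx_synthetic_complex_paths()
  cl <- read_cluster(paths$xyz, paths$topology)
  ref <- fx_cluster()
  expect_equal(length(cl$ligands), length(ref$ligands))
  expect_equal(cl$head_centroids, ref$head_centroids, tolerance = 1e-5)
  # dangling topology index
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(ligands = list(list(
    head_atoms = c(9999L), ring_atoms = list(), unit_position = "middle"))),
    bad, auto_unbox = TRUE)
  expect_error(read_cluster(paths$xyz, bad), "outside structure")
})

test_that("posed complex writing applies the rigid transform exactly", {
  atoms <- read_protein(toy_pdb_3res())
  cl <- fx_cluster()
  # identity pose: cluster coordinates unchanged (PDB precision)
  f1 <- tempfile(fileext = ".pdb")
  write_complex(atoms, cl, list(R = diag(3), t = c(0, 0, 0)), f1)
  back <- bio3d::read.pdb(f1, verbose = FALSE)
  het <- back$atom[back$atom$type == "HETATM", ]
  expect_equal(het$x, cl$atoms$x, tolerance = 1e-3)
  # pure translation shifts x by exactly 1
  f2 <- tempfile(fileext = ".pdb")
  write_complex(atoms, cl, list(R = diag(3), t = c(1, 0, 0)), f2)
  het2 <- bio3d::read.pdb(f2, verbose = FALSE)$atom
  het2 <- het2[het2$type == "HETATM", ]
  expect_equal(het2$x, cl$atoms$x + 1, tolerance = 1e-3)
  # 90 degree rotation about z maps (1,0,0) offsets to (0,1,0)
  Rz <- rotation_matrix(c(0, 0, 1), pi / 2)
  expect_equal(as.numeric(Rz %*% c(1, 0, 0)), c(0, 1, 0), tolerance = 1e-12)
  expect_error(
    write_complex(atoms, cl, list(R = diag(3) * 2, t = c(0, 0, 0)),
                  tempfile()), "orthonormal")
})

test_that("PDB write/read round-trips coordinates to PDB precision", {
  p <- fx_protein()
  f <- tempfile(fileext = ".pdb")
  write_complex(p$atoms, fx_cluster(), list(R = diag(3), t = c(0, 0, 0)), f)
  again <- read_protein(f)
  prot <- again[again$residue_name != "NC", ]
  expect_equal(nrow(prot), nrow(p$atoms))
  cp0 <- extract_coarse_protein(p$atoms)
  cp1 <- extract_coarse_protein(prot)
  expect_equal(cp1$ca, cp0$ca, tolerance = 2e-3)
})

test_that("coarse extraction is invariant to atom order within residues", {
  p <- fx_protein()
  shuffled <- p$atoms[sample(nrow(p$atoms)), ]
  expect_equal(extract_coarse_protein(shuffled)$ca,
               extract_coarse_protein(p$atoms)$ca)
})

test_that("XYZ files round-trip including multiple frames", {
  fr <- list(
    list(elements = c("C", "O"), coords = rbind(c(0, 0, 0), c(1.2, 0, 0))),
    list(elements = c("C", "O"), coords = rbind(c(0, 0, 1), c(1.2, 0, 1))))
  f <- tempfile(fileext = ".xyz")
  write_xyz(fr, f)
  back <- read_xyz(f)
  expect_length(back, 2)
  expect_equal(back[[2]]$coords, fr[[2]]$coords, tolerance = 1e-6)
  expect_equal(back[[1]]$elements, c("C", "O"))
})
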