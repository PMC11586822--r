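chain_cp <- function(ca, resnames = NULL) {
  n <- nrow(ca)
  structure(list(ca = ca,
                 labels = data.frame(chain_id = "A", residue_id = seq_len(n),
                                     residue_name = resnames %||%
                                       rep("ALA", n),
                                     stringsAsFactors = FALSE)),
            class = "coarse_protein")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("edges follow the 4.5 A cutoff inclusively", {
  two <- function(d) chain_cp(rbind(c(0, 0, 0), c(d, 0, 0)))
  expect_equal(nrow(build_graph(two(4.4))$edges), 1)
  expect_equal(nrow(build_graph(two(4.6))$edges), 0)
})

test_that("an extended chain yields a path graph (brute-force check)", {
  n <- 12
  ca <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  g <- build_graph(chain_cp(ca))
  # independent oracle: brute-force pairwise distances
  d <- as.matrix(dist(ca))
  expected <- sum(d <= 4.5 & upper.tri(d))
  expect_equal(nrow(g$edges), expected)
  expect_equal(expected, n - 1)
  expect_equal(unname(g$degree[c(1, n)]), c(1, 1))
  expect_true(all(g$degree[2:(n - 1)] == 2))
})

test_that("WL update matches the hand-computed two-node example", {
  adj <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2, 2)
  a0 <- matrix(c(1, 3), 2, 1)
  out <- wl_update(adj, n_updates = 1, attr = a0)
  # a1(v) = (1 + (1/1)*3)/2 = 2 for both nodes
  expect_equal(out, cbind(a0, c(2, 2)))
})

test_that("isolated nodes halve their attribute each WL update", {
  adj <- matrix(FALSE, 1, 1)
  out <- wl_update(adj, n_updates = 2, attr = matrix(4, 1, 1))
  expect_equal(as.numeric(out), c(4, 2, 1))
})

test_that("constant attributes are a fixed point of the WL update", {
  g <- build_graph(chain_cp(cbind(3.8 * (0:7), 0, 0)))
  a0 <- matrix(2.5, 8, 3)
  out <- wl_update(g, n_updates = 3, attr = a0)
  expect_equal(unname(out$node_attr_wl), matrix(2.5, 8, 12))
})

test_that("zero WL updates return raw attributes; widths scale as 39(N+1)", {
  g <- fx_graph()
  raw <- g$node_attr_raw
  expect_identical(ncol(raw), 39L)
  g0 <- wl_update(g, 0)
  expect_equal(unname(g0$node_attr_wl), unname(raw))
  expect_equal(ncol(g$node_attr_wl), 39 * 3)
  expect_true(all(is.finite(g$node_attr_wl)))
})

test_that("one-hot blocks each sum to exactly one per node", {
  raw <- fx_graph()$node_attr_raw
  aa_block <- raw[, grep("^aa_type_", colnames(raw))]
  ss_block <- raw[, grep("^dssp_", colnames(raw))]
  expect_true(all(rowSums(aa_block) == 1))
  expect_true(all(rowSums(ss_block) == 1))
})

test_that("element counts and classes match residue chemistry", {
  p <- fx_protein()
  raw <- fx_graph()$node_attr_raw
  gly <- which(p$cp$labels$residue_name == "GLY")
  expect_gt(length(gly), 0)
  # glycine heavy atoms: 2 C (CA + C), 1 N, 1 O, 0 S; class "special"
  expect_true(all(raw[gly, 1] == 2 & raw[gly, 2] == 1 &
                  raw[gly, 3] == 1 & raw[gly, 4] == 0))
  cls <- names(nanodock:::AA_CLASSES)
  expect_equal(unname(raw[gly[1], 6:10]),
               as.numeric(cls == "special"))
  # charged-positive class for arginine, via the provider directly
  reg <- default_feature_registry()
  ctx <- list(resnames = c("ALA", "ARG"))
  oh <- reg$aa_type$fn(ctx)
  expect_equal(oh[2, ], as.numeric(cls == "positive"))
  expect_equal(oh[1, ], as.numeric(cls == "hydrophobic"))
})

test_that("node features are invariant to input record order", {
  # shuffling the raw atom records must not change any node feature:
  # extraction canonicalises to chain/residue order
  p <- fx_protein()
  g <- fx_graph()
  set.seed(6)
  shuffled <- p$atoms[sample(nrow(p$atoms)), ]
  cp2 <- extract_coarse_protein(shuffled)
  g2 <- compute_node_features(build_graph(cp2), atoms = shuffled)
  expect_equal(unname(g2$node_attr_raw), unname(g$node_attr_raw),
               tolerance = 1e-9)
})

test_that("external annotation mode reads per-residue values from a table", {
  p <- fx_protein()
  n <- nrow(p$cp$ca)
  ann <- data.frame(chain_id = "A", residue_id = seq_len(n),
                    dssp_class = rep(c("H", "E"), length.out = n),
                    rel_asa = seq_len(n) / n, sasa = 2 * seq_len(n),
                    acc_shell = 0.5, pocketness = 0.25,
                    pocketness_c1 = 0.1, pocketness_c2 = 0.2,
                    pocketness_c3 = 0.3, pocketness_c4 = 0.4,
                    pocketness_c5 = 0.5, r_inacc = 3)
  g <- build_graph(p$cp)
  g <- compute_node_features(g, atoms = p$atoms,
                             registry = default_feature_registry("external"),
                             annotations = ann)
  raw <- g$node_attr_raw
  expect_equal(unname(raw[, "sasa_1"]), 2 * seq_len(n))
  expect_equal(unname(raw[, "dssp_1"]), rep(c(1, 0), length.out = n))
  # a missing residue is an error
  expect_error(
    compute_node_features(build_graph(p$cp), atoms = p$atoms,
                          registry = default_feature_registry("external"),
                          annotations = ann[-3, ]),
    "missing residue")
})
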