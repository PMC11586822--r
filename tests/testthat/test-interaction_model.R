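zero_model <- function(d_in = 133) {
  net <- nanodock:::mlp_init(d_in, c(4, 4, 4), 2)
  for (l in seq_along(net$W)) {
    net$W[[l]] <- net$W[[l]] * 0
    net$b[[l]] <- net$b[[l]] * 0
  }
  structure(list(folds = rep(list(net), 5),
                 x_lo = rep(0, d_in), x_hi = rep(1, d_in),
                 y_scale = 1, hidden = c(4, 4, 4)),
            class = "interaction_ensemble")
}

test_that("pair formation respects the 10 A boundary and counts", {
  g <- fx_graph()
  cl <- fx_cluster()
  b <- form_pairs(g, cl, NULL, 10)
  d <- nanodock:::cross_dist(cl$head_centroids, g$ca)
  expect_equal(nrow(b$pairs), sum(d <= 10))
  expect_true(all(b$distances <= 10))
  # boundary: shrink the cutoff just below/above an existing distance
  dd <- sort(d[d <= 10])
  mid <- dd[length(dd)]
  expect_equal(nrow(form_pairs(g, cl, NULL, mid - 1e-6)$pairs),
               length(dd) - 1)
  # far pose: empty batch, zero total prediction
  far <- form_pairs(g, cl, list(R = diag(3), t = c(500, 0, 0)), 10)
  expect_equal(nrow(far$features), 0)
  expect_equal(predict_interactions(zero_model(), far)$total, 0)
})

test_that("2 ligands x 3 residues all in range yield 6 rows", {
  ca <- rbind(c(6, 0, 0), c(6, 3.8, 0), c(6, -3.8, 0))
  cp <- structure(list(ca = ca,
                       labels = data.frame(chain_id = "A", residue_id = 1:3,
                                           residue_name = "ALA")),
                  class = "coarse_protein")
  g <- build_graph(cp)
  g$node_attr_wl <- matrix(0, 3, 117)
  cl2 <- make_cluster(2, radius = 3, seed = 1)
  b <- form_pairs(g, cl2, NULL, 10)
  expect_equal(nrow(b$pairs), 6)
})

test_that("interaction strengths rescale affinely with the stated anchors", {
  e <- c(-10, -4, -2, 0)
  phi <- scale_interactions(e)
  expect_identical(phi[1], 1.0)
  expect_equal(phi[4], -3 / 7)
  # the value at the median energy is exactly zero
  expect_equal(scale_interactions(c(e, median(e)))[5], 0)
  # ordering is preserved (monotone decreasing in energy)
  expect_true(all(diff(phi[order(e)]) <= 0))
  expect_warning(phi0 <- scale_interactions(c(2, 2, 2)), "equal")
  expect_equal(phi0, rep(0, 3))
  # matrix in, matrix out
  m <- matrix(e, 2, 2)
  expect_equal(dim(scale_interactions(m)), c(2, 2))
})

test_that("training is deterministic under the master seed", {
  tr <- fx_training()[1:20]
  m1 <- suppressWarnings(train_interaction_model(tr, seed = 3, epochs = 2))
  m2 <- suppressWarnings(train_interaction_model(tr, seed = 3, epochs = 2))
  expect_identical(m1$fold_id, m2$fold_id)
  p1 <- predict_interactions(m1, tr[[1]])
  p2 <- predict_interactions(m2, tr[[1]])
  expect_identical(p1$pair_energies, p2$pair_energies)
})

test_that("null labels train to near-null summed predictions", {
  tr <- fx_training()[1:40]
  for (i in seq_along(tr)) {
    tr[[i]]$e_coul <- 0
    tr[[i]]$e_vdw <- 0
  }
  m <- suppressWarnings(train_interaction_model(tr, seed = 4, epochs = 30))
  tot <- vapply(tr, function(b) predict_interactions(m, b)$total, 0)
  expect_true(all(abs(tot) < 0.05))
})

test_that("prediction is additive and averages the folds", {
  m <- fx_model()
  b <- Filter(function(x) nrow(x$features) > 2, fx_training())[[1]]
  p <- predict_interactions(m, b, per_fold = TRUE)
  # ensemble = mean over folds
  expect_equal(p$pair_energies, apply(p$fold_pred, c(1, 2), mean))
  # duplicated row doubles its contribution
  b2 <- b
  b2$features <- rbind(b$features, b$features[1, , drop = FALSE])
  p2 <- predict_interactions(m, b2)
  expect_equal(p2$total, p$total + p$pair_total[1], tolerance = 1e-9)
  # additive over disjoint subsets
  half <- seq_len(floor(nrow(b$features) / 2))
  pa <- predict_interactions(m, b$features[half, , drop = FALSE])
  pb <- predict_interactions(m, b$features[-half, , drop = FALSE])
  expect_equal(pa$total + pb$total, p$total, tolerance = 1e-9)
  expect_error(predict_interactions(m, matrix(0, 2, 5)), "dimension")
})

test_that("cross-validation report has the stated closed forms", {
  tr <- fx_training()[1:10]
  zm <- zero_model()
  ev <- evaluate_cv(zm, tr)
  labels <- vapply(tr, function(b) b$e_coul + b$e_vdw, 0)
  # constant-zero predictor: RMSE equals the population SD about zero
  expect_equal(ev$rmse, sqrt(mean(labels^2)), tolerance = 1e-12)
  # identical folds: zero between-fold spread
  expect_equal(ev$pair_std, 0)
  # a perfect predictor has zero RMSE
  perfect <- tr
  for (i in seq_along(perfect)) {
    perfect[[i]]$e_coul <- 0
    perfect[[i]]$e_vdw <- 0
  }
  expect_equal(evaluate_cv(zm, perfect)$rmse, 0)
})

test_that("network gradients match numerical differentiation", {
  set.seed(42)
  net <- nanodock:::mlp_init(4, c(5, 3), 2)
  X <- matrix(runif(12 * 4), 12, 4)
  cfg <- rep(1:3, each = 4)
  y <- c(1.0, -0.5, 2.0)
  loss_fn <- function(nn) {
    out <- nanodock:::mlp_forward(nn, X)
    mean(abs(rowsum(out[, 1] + out[, 2], cfg)[, 1] - y))
  }
  fw <- nanodock:::mlp_forward(net, X, keep = TRUE)
  pred <- rowsum(fw$out[, 1] + fw$out[, 2], cfg)[, 1]
  drow <- (sign(pred - y) / 3)[cfg]
  gr <- nanodock:::mlp_backward(net, fw, cbind(drow, drow))
  eps <- 1e-6
  for (l in 1:3) for (i in 1:2) {
    w0 <- net$W[[l]][i, 1]
    net$W[[l]][i, 1] <- w0 + eps; up <- loss_fn(net)
    net$W[[l]][i, 1] <- w0 - eps; dn <- loss_fn(net)
    net$W[[l]][i, 1] <- w0
    expect_lt(abs(gr$gW[[l]][i, 1] - (up - dn) / (2 * eps)), 1e-6)
  }
})

test_that("the full interaction table is pose-independent and complete", {
  tab <- fx_table()
  expect_equal(dim(tab$energy), c(8, 60))
  expect_equal(dim(tab$phi), dim(tab$energy))
  expect_identical(max(tab$phi), 1.0)
  expect_equal(stats::median(tab$phi), 0)
})
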