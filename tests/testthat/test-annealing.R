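test_that("the placement loss obeys its limiting contracts", {
  cl <- fx_cluster()
  p <- fx_protein()
  params <- nanodock:::params_with_c(loss_params(d0 = 5), cl)
  phi0 <- matrix(0, 8, 60)
  # far cluster: every term decays to zero
  heads_far <- cl$head_centroids + 500
  L_far <- placement_loss(heads_far, cl$com + 500, p$cp, phi0, params)
  expect_lt(abs(L_far), 1e-6)
  # single C-alpha at exactly d0 from one head, k = 0: L = g(d0) plus the
  # vanishing contribution of the other (far) heads
  ca1 <- matrix(cl$head_centroids[1, ] +
                  c(5, 0, 0) * 0, 1, 3)  # start from head, then offset
  dirv <- cl$head_centroids[1, ] - cl$com
  dirv <- dirv / sqrt(sum(dirv^2))
  ca1 <- matrix(cl$head_centroids[1, ] + dirv * params$d0, 1, 3)
  k0 <- params; k0$k <- 0; k0$close_margin <- -Inf
  L <- placement_loss(cl$head_centroids, cl$com, ca1, matrix(0, 8, 1), k0)
  g_d0 <- params$theta / params$d0^4 - 1
  other <- sum(nanodock:::well_g(
    nanodock:::cross_dist(cl$head_centroids[-1, ], ca1), params))
  expect_equal(L, g_d0 + other, tolerance = 1e-9)
  expect_equal(g_d0, 1 / 3 - 1)
  # one in-range pair with phi = 1 and k = 1 lowers the loss by exactly 1
  phi1 <- matrix(0, 8, 1)
  phi1[1, 1] <- 1
  k1 <- k0; k1$k <- 1
  expect_equal(placement_loss(cl$head_centroids, cl$com, ca1, phi1, k1),
               L - 1, tolerance = 1e-12)
})

test_that("the loss is invariant under a global rigid motion", {
  cl <- fx_cluster()
  p <- fx_protein()
  phi <- fx_table()$phi
  params <- nanodock:::params_with_c(loss_params(), cl)
  L0 <- placement_loss(cl$head_centroids, cl$com, p$cp$ca, phi, params)
  R <- rotation_matrix(c(1, 1, 0), 0.9)
  shift <- c(3, -7, 2)
  L1 <- placement_loss(cl$head_centroids %*% t(R) + rep(shift, each = 8),
                       as.numeric(R %*% cl$com + shift),
                       p$cp$ca %*% t(R) + rep(shift, each = 60),
                       phi, params)
  expect_equal(L1, L0, tolerance = 1e-9)
})

test_that("increasing k strictly lowers the loss with a positive-phi pair", {
  cl <- fx_cluster()
  p <- fx_protein()
  phi <- fx_table()$phi
  # approach along the patch direction so an attractive contact exists
  u <- colMeans(p$cp$ca[p$patches[[1]], ]) - colMeans(p$cp$ca)
  u <- u / sqrt(sum(u^2))
  pose <- nanodock:::approach_pose(p$cp$ca, cl, u, diag(3), 3)
  heads <- nanodock:::apply_pose(cl$head_centroids, pose, cl$com)
  D <- nanodock:::cross_dist(heads, p$cp$ca)
  expect_gt(sum(phi[D <= 5.5]), 0)
  p1 <- nanodock:::params_with_c(loss_params(k = 1), cl)
  p2 <- nanodock:::params_with_c(loss_params(k = 2), cl)
  expect_lt(placement_loss(heads, cl$com + pose$t, p$cp$ca, phi, p2),
            placement_loss(heads, cl$com + pose$t, p$cp$ca, phi, p1))
})

test_that("Metropolis acceptance follows min(1, exp(-dL/T))", {
  set.seed(9)
  expect_true(all(vapply(1:50, function(i) metropolis_accept(-5, 0.5), TRUE)))
  # dL = T ln 2 accepts with probability exactly 1/2
  T <- 0.8
  acc <- vapply(1:4000, function(i) metropolis_accept(T * log(2), T), TRUE)
  expect_lt(abs(mean(acc) - 0.5), 0.03)   # ~4 binomial SE
  expect_false(any(vapply(1:50, function(i)
    metropolis_accept(1e6, 0.1), TRUE)))
})

test_that("a Metropolis chain reproduces Boltzmann occupancy on 2 states", {
  # states with energies 0 and dE at temperature T: occupancy ratio e^(-dE/T)
  set.seed(31)
  dE <- 1.0
  T <- 1.0
  n <- 40000
  state <- 0
  visits <- 0
  for (i in seq_len(n)) {
    delta <- if (state == 0) dE else -dE
    if (metropolis_accept(delta, T)) state <- 1 - state
    visits <- visits + state
  }
  p1 <- visits / n
  expected <- exp(-dE / T) / (1 + exp(-dE / T))
  se <- sqrt(expected * (1 - expected) / n)
  # 3 standard errors, inflated for chain autocorrelation
  expect_lt(abs(p1 - expected), 3 * se * 4)
})

test_that("the step controller applies the 40-60% band rule with clamps", {
  s <- list(translation = 2, rotation = 0.3)
  up <- adapt_steps(0.7, s)
  expect_equal(up$translation, 2.2)
  expect_equal(up$rotation, 0.33)
  expect_equal(adapt_steps(0.5, s), s)
  dn <- adapt_steps(0.2, s)
  expect_equal(dn$translation, 1.8)
  expect_equal(adapt_steps(0.9, list(translation = 19.5, rotation = 3.1)),
               list(translation = 20, rotation = pi))
  expect_equal(adapt_steps(0.1, list(translation = 1e-3, rotation = 1e-3)),
               list(translation = 1e-3, rotation = 1e-3))
})

test_that("near-zero temperature gives a monotone loss trajectory", {
  cl <- fx_cluster()
  p <- fx_protein()
  phi <- fx_table()$phi
  runs <- anneal(p$cp, cl, phi,
                 schedule = anneal_schedule(n_steps = 400, t0 = 1e-9,
                                            constant = TRUE),
                 n_runs = 1, seed = 4)
  expect_true(all(diff(runs[[1]]$loss_trace) <= 1e-12))
})

test_that("annealing runs are reproducible bit-for-bit under a seed", {
  cl <- fx_cluster()
  p <- fx_protein()
  phi <- fx_table()$phi
  sched <- anneal_schedule(n_steps = 300)
  r1 <- anneal(p$cp, cl, phi, schedule = sched, n_runs = 2, seed = 11)
  r2 <- anneal(p$cp, cl, phi, schedule = sched, n_runs = 2, seed = 11)
  expect_identical(r1[[1]]$com_trace, r2[[1]]$com_trace)
  expect_identical(r1[[2]]$com_trace, r2[[2]]$com_trace)
  expect_identical(r1[[1]]$loss, r2[[1]]$loss)
})

test_that("geometry-only placement shows no azimuthal bias on a sphere", {
  # spherical shell protein, k = 0: final azimuths should be uniform
  dirs <- fibonacci_sphere(80)
  cp <- structure(list(ca = dirs * 12,
                       labels = data.frame(chain_id = "A", residue_id = 1:80,
                                           residue_name = "ALA")),
                  class = "coarse_protein")
  cl <- fx_cluster()
  phi0 <- matrix(0, 8, 80)
  runs <- anneal(cp, cl, phi0, params = loss_params(k = 0),
                 schedule = anneal_schedule(n_steps = 800), n_runs = 24,
                 seed = 2)
  az <- vapply(runs, function(r) atan2(r$com[2], r$com[1]), 0)
  # Rayleigh test of circular uniformity
  n <- length(az)
  Rbar <- sqrt(mean(cos(az))^2 + mean(sin(az))^2)
  p_value <- exp(-n * Rbar^2)
  expect_gt(p_value, 0.01)
})

test_that("site selection ranks clusters by membership and returns n", {
  set.seed(5)
  cl <- fx_cluster()
  blobA <- matrix(rnorm(30 * 3, sd = 1), 30, 3)
  blobB <- matrix(rnorm(10 * 3, sd = 1), 10, 3) +
    matrix(c(60, 0, 0), 10, 3, byrow = TRUE)
  pts <- rbind(blobA, blobB)
  runs <- lapply(seq_len(nrow(pts)), function(i)
    list(pose = list(R = diag(3), t = pts[i, ] - cl$com),
         com = pts[i, ], loss = 0))
  ca <- matrix(c(1000, 0, 0), 1, 3)
  energy <- matrix(0, 8, 1)
  sites <- select_sites(runs, ca, cl, energy, n = 2, threshold = 10)
  expect_length(sites$sites, 2)
  expect_equal(sites$sites[[1]]$count, 30)
  expect_equal(sites$sites[[2]]$count, 10)
  expect_true(sites$sites[[1]]$representative %in% 1:30)
  # degenerate: all points identical collapses to one cluster with warning
  runs1 <- runs[c(1, 1, 1)]
  w <- capture_warnings(s1 <- select_sites(runs1, ca, cl, energy, n = 3))
  expect_match(w, "returning all", all = FALSE)
  expect_length(s1$sites, 1)
})

test_that("refinement respects the COM restraint and the steric floor", {
  p <- fx_protein()
  cl <- fx_cluster()
  g <- fx_graph()
  tab <- fx_table()
  pose <- nanodock:::approach_pose(p$cp$ca, cl, c(0, 0, 1), diag(3), 3)
  site_com <- cl$com + pose$t
  ref <- refine_pose(p$atoms, g, cl, pose, tab$phi,
                     params = loss_params(d0 = 4.0),
                     restrict_radius = 8, n_steps = 400, seed = 2)
  expect_lte(sqrt(sum((ref$com - site_com)^2)), 8 + 1e-9)
  expect_gte(ref$min_dist, 1.5)
  expect_true(ref$feasible)
})
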