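test_that("model potentials have consistent analytic gradients", {
  set.seed(1)
  pots <- list(harmonic_potential(c(3, 8)),
               double_well_potential(4, 1),
               build_surrogate_reaction_landscape(),
               build_surrogate_us_profile(),
               build_surrogate_pucker_landscape())
  for (pot in pots) {
    x <- if (pot$dim == 1) matrix(runif(60, -1.4, 1.4)) else
      cbind(runif(60, 0, 2), runif(60, 1, 3))
    expect_lt(check_gradient(pot, x), 1e-5)
  }
})

test_that("Langevin sampling satisfies equipartition in a harmonic well", {
  pot <- harmonic_potential(10)
  tr <- run_langevin(pot, 0, n_steps = 400000, seed = 11)
  expect_equal(var(tr[, 1]), kT300 / 10, tolerance = 0.05)
})

test_that("zero-temperature overdamped dynamics relaxes monotonically to the minimum", {
  pot <- harmonic_potential(10)
  tr <- run_langevin(pot, 2, n_steps = 40000, temperature = 0, friction = 50,
                     traj_stride = 10)
  expect_true(all(diff(abs(tr[, 1])) <= 1e-12))
  expect_lt(abs(tr[nrow(tr), 1]), 0.01)
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  pot <- double_well_potential(3)
  t1 <- run_langevin(pot, 0, 2000, seed = 5)
  t2 <- run_langevin(pot, 0, 2000, seed = 5)
  expect_identical(t1, t2)
  m1 <- run_metadynamics(pot, 0, 50, 50, sigma = 0.1, h0 = 0.3, delta_T = 5, seed = 5)
  m2 <- run_metadynamics(pot, 0, 50, 50, sigma = 0.1, h0 = 0.3, delta_T = 5, seed = 5)
  expect_identical(m1$bias$centers, m2$bias$centers)
  expect_identical(m1$bias$heights, m2$bias$heights)
})

test_that("unstable integration is reported with the time step", {
  pot <- harmonic_potential(1e6)
  expect_error(run_langevin(pot, 1, 10000, dt = 1, seed = 1), "dt")
})

test_that("unbiased sampling reproduces the Boltzmann distribution", {
  dw <- double_well_potential(barrier = 1.5, half_separation = 1)
  tr <- run_langevin(dw, 1, 4e6, friction = 5, seed = 7, traj_stride = 4)
  h <- hist(tr[, 1], breaks = 60, plot = FALSE)
  keep <- h$density > 0.03
  Fh <- -kT300 * log(h$density)
  Vt <- potential_energy(dw, matrix(h$mids))
  dev <- (Fh - Vt)[keep]
  expect_lt(max(abs(dev - mean(dev))), 0.25)
})

test_that("hill deposition follows the well-tempered damping rule", {
  b <- bias_state(sigma = 0.1, delta_T = 2)
  b <- deposit_hill(b, 0, h0 = 0.5)
  expect_equal(b$heights[1], 0.5)             # first hill: zero bias
  ## accumulate bias at the origin until it reaches delta_T * log(2),
  ## then the next hill height is h0 / 2
  b2 <- bias_state(sigma = 0.1, delta_T = 2)
  b2$centers <- matrix(0); b2$heights <- 2 * log(2); b2$steps <- 100L
  b2 <- deposit_hill(b2, 0, h0 = 0.5)
  expect_equal(b2$heights[2], 0.25)
  ## heights at a revisited fixed point are non-increasing
  b3 <- bias_state(sigma = 0.1, delta_T = 2)
  for (i in 1:8) b3 <- deposit_hill(b3, 0, h0 = 0.5)
  expect_true(all(diff(b3$heights) <= 0))
  ## and decay geometrically consistent with exp(-V/delta_T)
  for (i in 2:8) {
    v <- sum(b3$heights[1:(i - 1)])
    expect_equal(b3$heights[i], 0.5 * exp(-v / 2), tolerance = 1e-12)
  }
})

test_that("bias energy is an exact hill sum with periodic minimum image", {
  b <- bias_state(sigma = c(2, 0.5), delta_T = 5,
                  periodic = c(TRUE, FALSE), period = c(360, NA))
  b$centers <- matrix(c(359, 1), 1, 2)
  b$heights <- 0.7; b$steps <- 100L
  expect_equal(bias_energy(b, c(359, 1)), 0.7)
  expect_equal(bias_energy(b, c(1, 1)),
               0.7 * exp(-0.5 * (2 / 2)^2))       # 2 deg via the boundary
  expect_lt(bias_energy(b, c(180, 1)), 1e-10)     # far away
})

test_that("hill bookkeeping identity holds", {
  md <- run_metadynamics(double_well_potential(2), 0, n_hills = 854,
                         stride = 100, sigma = 0.1, h0 = 0.5, delta_T = 15,
                         dt = 1e-3, seed = 1, traj_stride = 100)
  bk <- hill_bookkeeping(md$bias)
  expect_identical(bk$n_hills, 854L)
  expect_equal(bk$total_time_ps, 854 * 100 * 1e-3)
  expect_equal(md$log$total_time_ps, 85.4)
})

test_that("metadynamics surmounts a double-well barrier and recovers its shape", {
  dw <- double_well_potential(barrier = 5, half_separation = 1)
  md <- run_metadynamics(dw, x0 = -1, n_hills = 5000, stride = 100,
                         sigma = 0.1, h0 = 0.2, delta_T = 5, seed = 21)
  crossings <- count_basin_transitions(md$trajectory[, 1],
                                       list(A = c(-1.6, -0.6), B = c(0.6, 1.6)))
  expect_gte(crossings, 2)
  fes <- reconstruct_fes(md$bias, list(seq(-1.5, 1.5, length.out = 151)))
  Vt <- potential_energy(dw, matrix(fes$axes[[1]]))
  Vt <- Vt - min(Vt)
  sel <- abs(fes$axes[[1]]) <= 1.1
  err <- fes$values[sel] - Vt[sel]
  expect_lt(max(abs(err - mean(err))), 1)
})

test_that("a flat potential yields a flat reconstructed surface", {
  flat <- model_potential(1, walls = list(lo = -1.5, hi = 1.5, k = 100))
  md <- run_metadynamics(flat, 0, n_hills = 4000, stride = 50, sigma = 0.1,
                         h0 = 0.2, delta_T = 5, seed = 3)
  ## interior of the confined range; the soft walls shape the edges
  fes <- reconstruct_fes(md$bias, list(seq(-0.9, 0.9, length.out = 121)),
                         average_fraction = 0.5)
  expect_lt(max(fes$values), 1)
})

test_that("FES reconstruction scales the bias by (T + dT)/dT and anchors at zero", {
  b <- bias_state(sigma = 0.2, delta_T = 30, temperature = 300)
  b <- deposit_hill(b, 0, h0 = 1)
  fes <- reconstruct_fes(b, list(seq(-1, 1, length.out = 201)))
  expect_equal(min(fes$values), 0)
  dT_K <- 30 / 0.0019872041
  scale <- (300 + dT_K) / dT_K
  ## an inverted Gaussian: depth equals scale * height, minimum at the edge
  expect_equal(max(fes$values), scale * 1 * (1 - exp(-0.5 * (1 / 0.2)^2)),
               tolerance = 1e-6)
  expect_equal(which.min(fes$values), 101)    # grid centre, under the hill
  ## huge delta_T: the scaling factor approaches 1 (standard metadynamics)
  b2 <- bias_state(sigma = 0.2, delta_T = 1e6)
  b2 <- deposit_hill(b2, 0, h0 = 1)
  f2 <- reconstruct_fes(b2, list(seq(-1, 1, length.out = 201)))
  expect_equal(max(f2$values), 1 * (1 - exp(-0.5 * 25)), tolerance = 1e-4)
  expect_error(reconstruct_fes(bias_state(0.1, 5), list(0:1)), "empty")
})

test_that("basin transition counting uses a full-entry hysteresis rule", {
  A <- c(-2, -1); B <- c(1, 2)
  expect_identical(count_basin_transitions(c(-1.5, 0, 1.5, 0, -1.5),
                                           list(A = A, B = B)), 2L)
  ## grazing the gap without entering the other basin does not count
  expect_identical(count_basin_transitions(c(-1.5, 0.9, -1.2, 0.5, -1.6),
                                           list(A = A, B = B)), 0L)
  expect_identical(count_basin_transitions(rep(-1.5, 10), list(A = A, B = B)), 0L)
  expect_error(count_basin_transitions(1:10, list(c(0, 5), c(4, 9))),
               "overlap")
  expect_error(count_basin_transitions(1:10, list(c(0, 5))), "two basins")
})

test_that("gridded bias bookkeeping matches exact summation", {
  pot <- build_surrogate_us_profile()
  m1 <- run_metadynamics(pot, 0, 300, 100, sigma = 0.1, h0 = 0.5,
                         delta_T = 15, seed = 9, grid_bias = FALSE)
  m2 <- run_metadynamics(pot, 0, 300, 100, sigma = 0.1, h0 = 0.5,
                         delta_T = 15, seed = 9, grid_bias = TRUE)
  ## early hills agree closely before chaotic divergence sets in
  expect_lt(max(abs(m1$bias$heights[1:40] - m2$bias$heights[1:40])), 0.05)
  expect_lt(max(abs(m1$bias$centers[1:40, ] - m2$bias$centers[1:40, ])), 0.15)
})
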