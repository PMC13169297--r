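test_that("find_minima locates bowls and respects the depth floor", {
  ax <- seq(-2, 2, length.out = 41)
  bowl <- outer(ax, ax, function(x, y) x^2 + y^2)
  f <- fes_grid(list(ax, ax), bowl)
  m <- find_minima(f)
  expect_equal(nrow(m), 1)
  expect_equal(c(m$cv1, m$cv2), c(0, 0))
  flat <- fes_grid(list(ax, ax), matrix(1, 41, 41))
  expect_equal(nrow(find_minima(flat, depth_floor = 0.5)), 0)
})

test_that("the surrogate reaction landscape shows the reported stationary layout", {
  pot <- build_surrogate_reaction_landscape()
  ax1 <- seq(-1.9, 2.8, length.out = 151)
  ax2 <- seq(-0.55, 4.45, length.out = 151)
  V <- matrix(potential_energy(pot, as.matrix(expand.grid(ax1, ax2))), 151, 151)
  f <- fes_grid(list(ax1, ax2), V, anchor = FALSE)
  m <- find_minima(f, depth_floor = 1)
  cell <- c(diff(ax1)[1], diff(ax2)[1])
  near <- function(target) any(abs(m$cv1 - target[1]) <= cell[1] &
                                 abs(m$cv2 - target[2]) <= cell[2])
  expect_true(near(c(-1.0, 1.1)))     # MC
  expect_true(near(c(1.8, 3.4)))      # PC
  expect_true(near(c(1.8, 1.7)))      # IC
  path <- find_mfep(f, c(-1, 1.1), c(1.8, 3.4))
  ts <- path[attr(path, "saddle"), ]
  expect_lt(abs(ts$cv1 - 0.7), 2 * cell[1])
  expect_lt(abs(ts$cv2 - 0.3), 2 * cell[2])
  bd <- barrier_and_dg(path)
  expect_equal(bd$dg_act, 19, tolerance = 0.05)
  expect_equal(bd$dg_rxn, -5, tolerance = 0.05)
  ## the intermediate sits 1 kcal/mol below the reactant
  expect_equal(min(bd$intermediates$F_rel_start), -1, tolerance = 0.1)
})

test_that("two bowls across a parabolic ridge cross at the ridge's lowest point", {
  ax <- seq(-2, 2, length.out = 81)
  v <- outer(ax, ax, function(x, y) (x^2 - 1)^2 * 3 + y^2)
  f <- fes_grid(list(ax, ax), v)
  path <- find_mfep(f, c(-1, 0), c(1, 0))
  ts <- path[attr(path, "saddle"), ]
  expect_equal(c(ts$cv1, ts$cv2), c(0, 0))
})

test_that("grid minimax level equals exhaustive enumeration on 5x5 grids", {
  set.seed(13)
  for (rep in 1:6) {
    v <- matrix(runif(25), 5, 5)
    ## force distinct corners to be the two lowest cells
    v[1, 1] <- -1; v[5, 5] <- -0.9
    f <- fes_grid(list(1:5, 1:5), v, anchor = FALSE)
    path <- find_mfep(f, c(1, 1), c(5, 5))
    expect_equal(attr(path, "level"), brute_minimax(v, c(1, 1), c(5, 5)),
                 tolerance = 1e-12)
  }
})

test_that("the minimax level is invariant under monotone transformations", {
  set.seed(14)
  v <- matrix(runif(25), 5, 5); v[1, 1] <- -1; v[5, 5] <- -0.9
  f1 <- fes_grid(list(1:5, 1:5), v, anchor = FALSE)
  l1 <- attr(find_mfep(f1, c(1, 1), c(5, 5)), "level")
  g <- function(x) x^3 + 2 * x          # strictly increasing
  f2 <- fes_grid(list(1:5, 1:5), g(v), anchor = FALSE)
  l2 <- attr(find_mfep(f2, c(1, 1), c(5, 5)), "level")
  expect_equal(l2, g(l1), tolerance = 1e-12)
})

test_that("saddle energy is symmetric in the endpoints and dg transforms correctly", {
  pot <- build_surrogate_reaction_landscape()
  ax1 <- seq(-1.9, 2.8, length.out = 101)
  ax2 <- seq(-0.55, 4.45, length.out = 101)
  V <- matrix(potential_energy(pot, as.matrix(expand.grid(ax1, ax2))), 101, 101)
  f <- fes_grid(list(ax1, ax2), V, anchor = FALSE)
  pab <- find_mfep(f, c(-1, 1.1), c(1.8, 3.4))
  pba <- find_mfep(f, c(1.8, 3.4), c(-1, 1.1))
  expect_equal(attr(pab, "level"), attr(pba, "level"), tolerance = 1e-12)
  bab <- barrier_and_dg(pab); bba <- barrier_and_dg(pba)
  expect_equal(bba$dg_rxn, -bab$dg_rxn, tolerance = 1e-9)
  expect_equal(bba$dg_act, bab$dg_act - bab$dg_rxn, tolerance = 1e-9)
})

test_that("barrier extraction handles monotone and symmetric profiles", {
  mono <- barrier_and_dg(seq(5, 0, length.out = 30))
  expect_equal(mono$dg_act, 0)
  expect_equal(mono$dg_rxn, -5)
  expect_equal(nrow(mono$intermediates), 0)
  sym <- barrier_and_dg(c(0, 2, 4, 2, 0))
  expect_equal(sym$dg_act, 4)
  expect_equal(sym$dg_rxn, 0)
})

test_that("grid refinement changes the extracted barrier by less than 0.2 kcal/mol", {
  pot <- build_surrogate_reaction_landscape()
  bar <- sapply(c(101, 201), function(n) {
    ax1 <- seq(-1.9, 2.8, length.out = n)
    ax2 <- seq(-0.55, 4.45, length.out = n)
    V <- matrix(potential_energy(pot, as.matrix(expand.grid(ax1, ax2))), n, n)
    f <- fes_grid(list(ax1, ax2), V, anchor = FALSE)
    barrier_and_dg(find_mfep(f, c(-1, 1.1), c(1.8, 3.4)))$dg_act
  })
  expect_lt(abs(diff(bar)), 0.2)
})

test_that("1D projection preserves endpoints and extrema", {
  pot <- build_surrogate_reaction_landscape()
  ax1 <- seq(-1.9, 2.8, length.out = 101)
  ax2 <- seq(-0.55, 4.45, length.out = 101)
  V <- matrix(potential_energy(pot, as.matrix(expand.grid(ax1, ax2))), 101, 101)
  f <- fes_grid(list(ax1, ax2), V, anchor = FALSE)
  path <- find_mfep(f, c(-1, 1.1), c(1.8, 3.4))
  pr <- project_1d(path)
  expect_equal(range(pr$s), c(0, 1))
  bd <- barrier_and_dg(path)
  expect_equal(max(pr$F), bd$dg_act + pr$F[1])
  ## MC -> TS -> IC -> PC ordering along the projection
  i_ts <- which.max(pr$F)
  i_ic <- which(barrier_and_dg(path)$intermediates$node > i_ts)
  expect_gt(length(i_ic), 0)
  expect_lt(pr$F[1], max(pr$F))
  expect_lt(pr$F[nrow(pr)], pr$F[1])
})

test_that("tube averaging reports means per node and flags empty boxes", {
  path <- data.frame(node = 1:3, cv1 = c(0, 1, 2), cv2 = c(0, 0, 0),
                     F = c(0, 1, 0), arclength = c(0, 1, 2))
  frames <- data.frame(cv1 = c(0.05, 0.95, 1.05, 0.0), cv2 = 0,
                       obs = c(10, 20, 30, 10))
  ta <- tube_average(frames, path, tol = c(cv1 = 0.1, cv2 = 0.1))
  expect_equal(ta$obs, c(10, 25, NA))
  expect_equal(ta$n, c(2L, 2L, 0L))
  ## an observable equal to CV1 tracks the path within the tolerance
  frames2 <- data.frame(cv1 = runif(200, -0.1, 2.1), cv2 = 0)
  frames2$mirror <- frames2$cv1
  ta2 <- tube_average(frames2, path, tol = c(cv1 = 0.1, cv2 = 0.1))
  ok <- !is.na(ta2$mirror)
  expect_true(all(abs(ta2$mirror[ok] - path$cv1[ok]) <= 0.1))
  expect_error(tube_average(frames, path, tol = c(cv1 = -1, cv2 = 0.1)),
               "positive")
  far <- data.frame(cv1 = 100, cv2 = 100, obs = 1)
  expect_error(tube_average(far, path, tol = c(cv1 = 0.1, cv2 = 0.1)),
               "no frames")
})

test_that("bond-order changes averaged around the path match the stage anchors", {
  rs <- reaction_distance_series(n_frames = 301, seed = 3)
  pot <- build_surrogate_reaction_landscape()
  ax1 <- seq(-1.9, 2.8, length.out = 121)
  ax2 <- seq(-0.55, 4.45, length.out = 121)
  V <- matrix(potential_energy(pot, as.matrix(expand.grid(ax1, ax2))), 121, 121)
  f <- fes_grid(list(ax1, ax2), V, anchor = FALSE)
  path <- find_mfep(f, c(-1, 1.1), c(1.8, 3.4))
  ta <- tube_average(rs, path, tol = c(cv1 = 0.1, cv2 = 0.1))
  ts_node <- attr(path, "saddle")
  ## C5-C6 contracts from 1.54 at the reactant to 1.45 at the saddle
  expect_equal(ta$dC5C6[1], 1.54, tolerance = 0.02)
  expect_equal(ta$dC5C6[ts_node], 1.45, tolerance = 0.02)
  ## C4-C5 acquires double-bond character (1.50 -> 1.37) by the intermediate
  expect_equal(ta$dC4C5[1], 1.50, tolerance = 0.02)
  bd <- barrier_and_dg(path)
  ic_node <- bd$intermediates$node[1]
  expect_equal(ta$dC4C5[ic_node], 1.37, tolerance = 0.02)
})
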