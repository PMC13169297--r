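test_that("window placement is inclusive and evenly spaced", {
  w <- make_windows(-0.75, 1.25, 0.25)
  expect_length(w, 9)
  expect_equal(w[1], -0.75)
  expect_equal(w[9], 1.25)
  expect_equal(unique(round(diff(w), 12)), 0.25)
  expect_length(make_windows(0, 1, 0.5), 3)
  expect_error(make_windows(0, 1, -0.1), "positive")
  expect_error(make_windows(1, 0, 0.1), "exceed")
})

test_that("the default force constant follows the spacing design rule", {
  expect_equal(default_window_k(0.25), kT300 / 0.125^2)
})

test_that("restrained sampling has the harmonic statistics on a flat landscape", {
  flat <- model_potential(1, walls = list(lo = -5, hi = 5, k = 100))
  w <- sample_window(flat, center = 0.3, k = 20, n_steps = 200000,
                     friction = 5, seed = 2)
  expect_lt(abs(mean(w$samples) - 0.3), 0.02)
  expect_equal(var(w$samples), kT300 / 20, tolerance = 0.15)
  ## a steep wall left of the centre pushes the mean right
  wallpot <- model_potential(1, walls = list(lo = 0.3, hi = 5, k = 500))
  w2 <- sample_window(wallpot, center = 0.3, k = 20, n_steps = 50000,
                      friction = 10, seed = 2)
  expect_gt(mean(w2$samples), 0.3)
  ## reproducibility and the equilibration discard
  w3 <- sample_window(flat, 0.3, 20, n_steps = 9000, seed = 4)
  w4 <- sample_window(flat, 0.3, 20, n_steps = 9000, seed = 4)
  expect_identical(w3$samples, w4$samples)
  expect_length(w3$samples, 6000)
})

test_that("overlap coefficients behave at the extremes and match direct summation", {
  mk <- function(x) structure(list(center = mean(x), k = 1, samples = x,
                                   n_total = length(x), equil_fraction = 0,
                                   temperature = 300),
                              class = "umbrella_window")
  set.seed(3)
  a <- rnorm(5000)
  expect_equal(overlap_report(list(mk(a), mk(a + 1e-9)))$overlap, 1,
               tolerance = 1e-3)
  expect_equal(overlap_report(list(mk(a), mk(a + 50)))$overlap, 0)
  ## half-shifted Gaussians against a direct bin-sum oracle
  b <- rnorm(5000, 0.5)
  rng <- range(c(a, b))
  breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 102)
  ha <- hist(a, breaks = breaks, plot = FALSE)$counts / 5000
  hb <- hist(b, breaks = breaks, plot = FALSE)$counts / 5000
  expect_equal(overlap_report(list(mk(a), mk(b)))$overlap, sum(pmin(ha, hb)),
               tolerance = 1e-9)
  expect_error(overlap_report(list(mk(a))), "two windows")
})

test_that("WHAM recovers a harmonic potential of mean force", {
  pot <- harmonic_potential(5)
  centers <- make_windows(-2, 2, 0.5)
  wins <- lapply(seq_along(centers), function(i)
    sample_window(pot, centers[i], k = 20, n_steps = 400000, friction = 5,
                  seed = i))
  pmf <- wham_solve(wins, n_bins = 151)
  truth <- 0.5 * 5 * pmf$bins^2
  truth <- truth - min(truth)
  keep <- pmf$counts > 500
  dev <- (pmf$F - truth)[keep]
  expect_lt(max(abs(dev - mean(dev))), 0.6)
  ## retained samples are conserved in the per-bin counts
  expect_equal(sum(pmf$counts), sum(lengths(lapply(wins, `[[`, "samples"))))
  ## bin-count doubling leaves the profile unchanged within tolerance
  pmf2 <- wham_solve(wins, n_bins = 302)
  f2 <- approx(pmf2$bins, pmf2$F, xout = pmf$bins[keep])$y
  expect_lt(max(abs(pmf$F[keep] - f2 - mean(pmf$F[keep] - f2)), na.rm = TRUE), 0.5)
})

test_that("WHAM is gauge invariant in the window constants", {
  pot <- harmonic_potential(5)
  centers <- make_windows(-1, 1, 0.5)
  wins <- lapply(seq_along(centers), function(i)
    sample_window(pot, centers[i], k = 20, n_steps = 20000, seed = i))
  p0 <- wham_solve(wins)
  p1 <- wham_solve(wins, f_init = rep(7.3, length(wins)))
  expect_equal(p0$F, p1$F, tolerance = 1e-6)
})

test_that("WHAM rejects windows without overlap, naming the gap", {
  mk <- function(x, c) structure(list(center = c, k = 50, samples = x,
                                      n_total = length(x), equil_fraction = 0,
                                      temperature = 300),
                                 class = "umbrella_window")
  set.seed(5)
  wins <- list(mk(rnorm(1000, 0, 0.05), 0), mk(rnorm(1000, 5, 0.05), 5))
  expect_error(wham_solve(wins), "overlap.*0\\.000|no histogram overlap")
})

test_that("umbrella sampling on the constructed profile recovers its barrier as samples grow", {
  us <- build_surrogate_us_profile()
  centers <- make_windows(-0.75, 1.25, 0.25)
  run <- function(n_steps) {
    wins <- lapply(seq_along(centers), function(i)
      sample_window(us, centers[i], k = 200, n_steps = n_steps,
                    friction = 10, seed = 300 + i))
    pmf_barrier(wham_solve(wins, n_bins = 201), min_count = 100, smooth = 6)
  }
  short <- run(70000)
  long <- run(250000)
  expect_lt(abs(long - 17.7), abs(short - 17.7) + 1.5)
  expect_lt(abs(long - 17.7), 2)
})
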