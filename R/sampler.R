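#' Accumulated well-tempered bias
#'
#' Ordered Gaussian hills plus the well-tempered bookkeeping needed to damp
#' new hills and to rescale the bias into a free-energy estimate.  The
#' well-tempered parameter `delta_T` is carried in energy units (kcal/mol);
#' the equivalent bias factor is gamma = (T + delta_T/kB) / T.
#'
#' @param sigma per-dimension hill widths (CV units).
#' @param delta_T well-tempered parameter (kcal/mol, > 0).
#' @param temperature simulation temperature (K).
#' @param stride deposition stride in MD steps.
#' @param dt time step (ps).
#' @param periodic,period per-dimension periodicity of the CV space.
#' @return an empty `bias_state`.
#' @export
bias_state <- function(sigma, delta_T, temperature = 300, stride = 100,
                       dt = 1e-3, periodic = rep(FALSE, length(sigma)),
                       period = rep(NA_real_, length(sigma))) {
  stopifnot(all(sigma > 0), delta_T > 0, stride >= 1, dt > 0)
  d <- length(sigma)
  structure(list(centers = matrix(numeric(0), 0, d),
                 heights = numeric(0), steps = integer(0),
                 sigma = as.numeric(sigma), delta_T = delta_T,
                 temperature = temperature, stride = as.integer(stride),
                 dt = dt, periodic = periodic, period = period),
            class = "bias_state")
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf("bias_state: %d hill(s), sigma = (%s), delta_T = %g kcal/mol (gamma = %.1f), T = %g K\n",
              nrow(x$centers), paste(signif(x$sigma, 3), collapse = ", "),
              x$delta_T, bias_factor(x), x$temperature))
  bk <- hill_bookkeeping(x)
  if (nrow(x$centers) > 0)
    cat(sprintf("  bookkeeping: %d hills x stride %d x dt %g ps = %g ps\n",
                bk$n_hills, bk$stride, bk$dt, bk$total_time_ps))
  invisible(x)
}

#' Well-tempered bias factor gamma = (T + delta_T/kB) / T
#' @param bias a [bias_state()].
#' @export
bias_factor <- function(bias) {
  (bias$temperature + bias$delta_T / kB_KCAL) / bias$temperature
}

#' Hill bookkeeping identity
#'
#' Total simulated time implied by a hill log: n_hills x stride x dt.
#'
#' @param bias a [bias_state()], or the number of hills.
#' @param stride,dt used when `bias` is a count.
#' @return list with `n_hills`, `stride`, `dt` (ps) and `total_time_ps`.
#' @export
hill_bookkeeping <- function(bias, stride = NULL, dt = NULL) {
  if (inherits(bias, "bias_state")) {
    n <- nrow(bias$centers); stride <- bias$stride; dt <- bias$dt
  } else n <- as.integer(bias)
  list(n_hills = n, stride = stride, dt = dt,
       total_time_ps = n * stride * dt)
}

#' Deposit one well-tempered hill
#'
#' Appends a Gaussian hill at CV point `s` with the well-tempered damped
#' height `h0 * exp(-V_bias(s) / delta_T)`.
#'
#' @param bias a [bias_state()].
#' @param s CV point (numeric vector).
#' @param h0 reference hill height (kcal/mol, > 0).
#' @param step MD step index recorded for the hill.
#' @return the updated `bias_state`; the new hill is its last row.
#' @export
deposit_hill <- function(bias, s, h0, step = NULL) {
  stopifnot(inherits(bias, "bias_state"), h0 > 0)
  h <- h0 * exp(-bias_energy(bias, s) / bias$delta_T)
  bias$centers <- rbind(bias$centers, as.numeric(s))
  bias$heights <- c(bias$heights, h)
  bias$steps <- c(bias$steps,
                  if (is.null(step)) (length(bias$heights)) * bias$stride else step)
  bias
}

#' Evaluate the accumulated bias potential
#'
#' Exact sum over all hills, with minimum-image distances on periodic
#' dimensions.
#'
#' @param bias a [bias_state()].
#' @param s CV point (vector) or matrix of points (rows).
#' @return bias energy (kcal/mol) at each point.
#' @export
bias_energy <- function(bias, s) {
  s <- .as_points(s, length(bias$sigma))
  if (nrow(bias$centers) == 0) return(rep(0, nrow(s)))
  sig <- matrix(bias$sigma, nrow(bias$centers), length(bias$sigma), byrow = TRUE)
  cpp_bias_energy(bias$centers, bias$heights, sig,
                  bias$periodic, ifelse(is.na(bias$period), 0, bias$period), s)
}

#' Langevin dynamics on a model potential
#'
#' BAOAB-discretised Langevin dynamics, the surrogate sampler that stands in
#' for molecular-dynamics propagation on CV space.  Runs are bitwise
#' reproducible for a fixed seed.
#'
#' @param pot a [model_potential()].
#' @param x0 starting point.
#' @param n_steps number of steps (>= 1).
#' @param dt time step (ps; default 1 fs).
#' @param friction Langevin friction (1/ps).
#' @param temperature temperature (K; 0 gives deterministic relaxation).
#' @param mass particle mass (kcal/mol ps^2 per CV-unit^2).
#' @param seed optional integer seed.
#' @param traj_stride store every `traj_stride`-th frame.
#' @return matrix of CV positions (frames x dim), with attribute `"final"`.
#' @export
run_langevin <- function(pot, x0, n_steps, dt = 1e-3, friction = 1,
                         temperature = 300, mass = 1, seed = NULL,
                         traj_stride = 1L) {
  stopifnot(dt > 0, temperature >= 0, n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_sample(unclass(pot), as.numeric(x0), as.integer(n_steps), dt,
                    friction, temperature, mass, kB_KCAL,
                    0L, numeric(pot$dim), 0, 1, as.integer(traj_stride))
  traj <- res$trajectory
  colnames(traj) <- paste0("cv", seq_len(pot$dim))
  attr(traj, "final") <- res$final
  traj
}

#' Well-tempered metadynamics on a model potential
#'
#' Interleaves Langevin propagation on `pot` plus the accumulated bias with
#' hill deposition every `stride` steps, damping hill heights by
#' `exp(-V_bias/delta_T)`.
#'
#' @inheritParams run_langevin
#' @param n_hills number of hills to deposit (>= 1); the run length is
#'   `n_hills * stride` steps.
#' @param stride deposition stride (MD steps).
#' @param sigma per-dimension hill widths (CV units).
#' @param h0 reference hill height (kcal/mol).
#' @param delta_T well-tempered parameter (kcal/mol).
#' @param traj_stride store every `traj_stride`-th frame.
#' @param grid_bias accumulate the bias on a grid (spacing `sigma/4`,
#'   multilinear interpolation; the standard long-run bookkeeping) instead
#'   of exact hill summation.  `"auto"` (default) switches the grid on when
#'   more than 2000 hills are requested and the potential carries walls or
#'   periodic bounds from which a grid extent can be derived.
#' @return list with `trajectory` (matrix), `bias` (a [bias_state()] holding
#'   the full hill history) and `log` (bookkeeping: bias factor, total time).
#' @export
run_metadynamics <- function(pot, x0, n_hills, stride = 100, sigma, h0,
                             delta_T, dt = 1e-3, friction = 1,
                             temperature = 300, mass = 1, seed = NULL,
                             traj_stride = 10L, grid_bias = "auto") {
  stopifnot(n_hills >= 1, length(sigma) == pot$dim, h0 > 0, delta_T > 0)
  if (!is.null(seed)) set.seed(seed)
  n_steps <- as.integer(n_hills) * as.integer(stride)
  spec <- NULL
  boundable <- all(pot$periodic | rep(!is.null(pot$walls), pot$dim))
  want_grid <- isTRUE(grid_bias) || (identical(grid_bias, "auto") && n_hills > 2000)
  if (want_grid && boundable) {
    lo <- hi <- numeric(pot$dim)
    for (i in seq_len(pot$dim)) {
      if (pot$periodic[i]) {
        lo[i] <- 0; hi[i] <- pot$period[i]
      } else {
        lo[i] <- pot$walls$lo[i] - 1; hi[i] <- pot$walls$hi[i] + 1
      }
    }
    spec <- list(lo = lo, hi = hi,
                 n = as.integer(ceiling((hi - lo) / (sigma / 4))))
  }
  res <- cpp_sample(unclass(pot), as.numeric(x0), n_steps, dt, friction,
                    temperature, mass, kB_KCAL, as.integer(stride),
                    as.numeric(sigma), h0, delta_T, as.integer(traj_stride),
                    spec)
  bias <- bias_state(sigma, delta_T, temperature, stride, dt,
                     pot$periodic, pot$period)
  bias$centers <- res$centers
  bias$heights <- as.numeric(res$heights)
  bias$steps <- as.integer(res$steps)
  traj <- res$trajectory
  colnames(traj) <- paste0("cv", seq_len(pot$dim))
  bk <- hill_bookkeeping(bias)
  list(trajectory = traj, bias = bias,
       log = c(bk, list(gamma = bias_factor(bias), h0 = h0,
                        temperature = temperature)))
}

#' Reconstruct the free-energy surface from a well-tempered bias
#'
#' F(s) = -(T + dT) / dT * V_bias(s) with dT the well-tempered parameter in
#' temperature units, shifted so the minimum over the grid is zero.
#'
#' @param bias a [bias_state()] with at least one hill.
#' @param axes list of grid axis vectors (one per CV dimension).
#' @param average_fraction average the free-energy estimate over every
#'   intermediate hill count in the final fraction of the hill history
#'   (instead of using only the final bias); damps the deposition ripple and
#'   the basin-to-basin oscillation of the estimate.  `0` (default) uses the
#'   final bias only.
#' @return a [fes_grid()].
#' @export
reconstruct_fes <- function(bias, axes, average_fraction = 0) {
  n <- nrow(bias$centers)
  if (n == 0) stop("empty bias: no hills to reconstruct from")
  if (is.numeric(axes)) axes <- list(axes)
  pts <- as.matrix(expand.grid(axes))
  dT_K <- bias$delta_T / kB_KCAL
  scale <- (bias$temperature + dT_K) / dT_K
  sig <- matrix(bias$sigma, n, length(bias$sigma), byrow = TRUE)
  per <- ifelse(is.na(bias$period), 0, bias$period)
  h <- .averaged_heights(bias$heights, average_fraction)
  F <- -scale * cpp_bias_energy(bias$centers, h, sig, bias$periodic, per, pts)
  vals <- array(F, dim = vapply(axes, length, integer(1)))
  fes_grid(axes, vals - min(vals), periodic = bias$periodic)
}

## mean over checkpoints m = n0..n of the prefix bias sum equals a single
## weighted sum: hill k appears in the checkpoints m >= max(k, n0)
.averaged_heights <- function(heights, average_fraction) {
  n <- length(heights)
  if (average_fraction <= 0 || n <= 1) return(heights)
  n0 <- max(1L, floor(n * (1 - average_fraction)))
  k <- seq_len(n)
  heights * (n - pmax(k, n0) + 1) / (n - n0 + 1)
}

#' Free-energy estimate at selected CV points
#'
#' Same estimator as [reconstruct_fes()] (optionally time-averaged over the
#' hill history) evaluated only at the requested points; no anchoring is
#' applied, so only differences between the returned values are meaningful.
#'
#' @inheritParams reconstruct_fes
#' @param at point (vector) or matrix of points (rows).
#' @return numeric vector of unanchored free energies (kcal/mol).
#' @export
fes_estimate_at <- function(bias, at, average_fraction = 0) {
  if (nrow(bias$centers) == 0) stop("empty bias: no hills to reconstruct from")
  at <- .as_points(at, length(bias$sigma))
  dT_K <- bias$delta_T / kB_KCAL
  scale <- (bias$temperature + dT_K) / dT_K
  sig <- matrix(bias$sigma, nrow(bias$centers), length(bias$sigma), byrow = TRUE)
  per <- ifelse(is.na(bias$period), 0, bias$period)
  h <- .averaged_heights(bias$heights, average_fraction)
  -scale * cpp_bias_energy(bias$centers, h, sig, bias$periodic, per, at)
}

#' Count completed transitions between basins along a CV series
#'
#' A transition is counted only when the walker fully enters a different
#' basin than the one last occupied (hysteresis rule); grazing the region
#' between basins does not count.
#'
#' @param series numeric vector (1D CV) or matrix (frames x dim).
#' @param basins named list of basin regions: for 1D, `c(lo, hi)` intervals;
#'   for higher dimensions, `list(lo =, hi =)` boxes.  Basins must be
#'   disjoint.
#' @return integer number of completed basin-to-basin transitions.
#' @export
count_basin_transitions <- function(series, basins) {
  if (length(basins) < 2) stop("need at least two basins")
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  boxes <- lapply(basins, function(b) {
    if (is.list(b)) cbind(lo = b$lo, hi = b$hi) else cbind(lo = b[1], hi = b[2])
  })
  d <- ncol(series)
  for (b in boxes) if (nrow(b) != d) stop("basin dimensionality mismatch")
  ## overlap check (pairwise box intersection)
  nb <- length(boxes)
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    if (all(boxes[[i]][, "lo"] <= boxes[[j]][, "hi"] &
            boxes[[j]][, "lo"] <= boxes[[i]][, "hi"]))
      stop("overlapping basins: ", i, " and ", j)
  }
  inside <- function(x, b) all(x >= b[, "lo"] & x <= b[, "hi"])
  current <- NA_integer_
  n <- 0L
  for (k in seq_len(nrow(series))) {
    for (b in seq_len(nb)) {
      if (inside(series[k, ], boxes[[b]])) {
        if (!is.na(current) && b != current) n <- n + 1L
        current <- b
        break
      }
    }
  }
  n
}
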