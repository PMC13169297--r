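#' Umbrella-sampling window centres
#'
#' Inclusive, evenly spaced window centres along a 1D collective variable.
#'
#' @param start,stop range of centres (Angstrom), `stop > start`.
#' @param spacing centre spacing (Angstrom, > 0).
#' @return numeric vector of `round((stop - start)/spacing) + 1` centres.
#' @export
make_windows <- function(start, stop, spacing) {
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be positive")
  if (stop <= start) stop("stop must exceed start")
  n <- round((stop - start) / spacing) + 1
  seq(start, by = spacing, length.out = n)
}

#' Default umbrella force constant
#'
#' Standard design rule: the restrained standard deviation at temperature `T`
#' is about half the window spacing, i.e. k = kB T / (spacing/2)^2.
#'
#' @param spacing window spacing (Angstrom).
#' @param temperature K.
#' @return force constant (kcal/mol/A^2).
#' @export
default_window_k <- function(spacing, temperature = 300) {
  kB_KCAL * temperature / (spacing / 2)^2
}

#' Sample one umbrella window
#'
#' Langevin sampling of `pot` plus the harmonic restraint
#' 0.5 k (s - center)^2; the first `equil_fraction` of the run is discarded
#' as equilibration (default one third, mirroring a 7.5 ps window of which
#' the last 5 ps are kept).
#'
#' @param pot a 1D [model_potential()].
#' @param center restraint centre (Angstrom).
#' @param k force constant (kcal/mol/A^2, > 0).
#' @param n_steps total steps before the equilibration discard.
#' @param equil_fraction fraction of initial samples discarded.
#' @inheritParams run_langevin
#' @return object of class `umbrella_window`: list with `center`, `k`,
#'   `samples` (retained CV values), `n_total` and `equil_fraction`.
#' @export
sample_window <- function(pot, center, k, n_steps = 20000, dt = 1e-3,
                          friction = 1, temperature = 300, mass = 1,
                          equil_fraction = 1 / 3, seed = NULL,
                          traj_stride = 1L) {
  stopifnot(pot$dim == 1L, k > 0, equil_fraction >= 0, equil_fraction < 1)
  restrained <- pot
  restrained$quads <- c(restrained$quads, list(list(k = k, center = center)))
  traj <- run_langevin(restrained, x0 = center, n_steps = n_steps, dt = dt,
                       friction = friction, temperature = temperature,
                       mass = mass, seed = seed, traj_stride = traj_stride)
  x <- as.numeric(traj[, 1])
  drop <- floor(length(x) * equil_fraction)
  samples <- if (drop > 0) x[-seq_len(drop)] else x
  structure(list(center = center, k = k, samples = samples,
                 n_total = length(x), equil_fraction = equil_fraction,
                 temperature = temperature),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella_window: center %.3f, k = %.1f kcal/mol/A^2, %d retained samples (mean %.3f, sd %.3f)\n",
              x$center, x$k, length(x$samples), mean(x$samples), stats::sd(x$samples)))
  invisible(x)
}

#' Pairwise histogram overlap of adjacent windows
#'
#' Overlap coefficient (sum over bins of the smaller of the two normalised
#' histogram masses; 1 for identical sample sets, 0 for disjoint supports)
#' for every adjacent window pair, windows taken in centre order.
#'
#' @param windows list of [sample_window()] results.
#' @param n_bins number of histogram bins over the pooled sample range.
#' @return data.frame with the pair indices, centres and `overlap`.
#' @export
overlap_report <- function(windows, n_bins = 101) {
  if (length(windows) < 2) stop("need at least two windows")
  o <- order(vapply(windows, function(w) w$center, numeric(1)))
  windows <- windows[o]
  rng <- range(unlist(lapply(windows, function(w) w$samples)))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9; breaks[n_bins + 1] <- breaks[n_bins + 1] + 1e-9
  hist_of <- function(w) {
    h <- hist(w$samples, breaks = breaks, plot = FALSE)$counts
    h / sum(h)
  }
  H <- vapply(windows, hist_of, numeric(n_bins))
  n <- length(windows)
  data.frame(window_a = seq_len(n - 1), window_b = 2:n,
             center_a = vapply(windows[-n], `[[`, numeric(1), "center"),
             center_b = vapply(windows[-1], `[[`, numeric(1), "center"),
             overlap = vapply(seq_len(n - 1), function(i)
               sum(pmin(H[, i], H[, i + 1])), numeric(1)))
}

#' WHAM: stitch umbrella windows into a potential of mean force
#'
#' Self-consistent iteration of the weighted-histogram equations over the
#' retained samples of all windows until the window free-energy constants
#' change by less than `tol`; the PMF is anchored so its minimum is zero.
#'
#' @param windows list of [sample_window()] results (>= 2, with histogram
#'   overlap between adjacent windows above `overlap_floor`).
#' @param temperature K.
#' @param n_bins number of PMF bins over the pooled sample range.
#' @param tol convergence tolerance on window constants (kcal/mol).
#' @param max_iter iteration cap.
#' @param overlap_floor minimum adjacent-window overlap coefficient.
#' @param f_init optional initial window constants (gauge: any additive
#'   constant gives the same anchored PMF).
#' @return object of class `pmf_profile`: list with `bins` (centres), `F`
#'   (anchored PMF), `counts` (per-bin retained samples), `window_f`
#'   (window constants) and `meta` (iterations, residual).
#' @export
wham_solve <- function(windows, temperature = 300, n_bins = 101, tol = 1e-8,
                       max_iter = 1e5, overlap_floor = 1e-4, f_init = NULL) {
  if (length(windows) < 2) stop("need at least two windows")
  ov <- overlap_report(windows, n_bins)
  if (any(ov$overlap < overlap_floor)) {
    bad <- ov[which.min(ov$overlap), ]
    stop(sprintf("no histogram overlap between windows at centers %.3f and %.3f (overlap %.2g)",
                 bad$center_a, bad$center_b, bad$overlap))
  }
  kT <- kB_KCAL * temperature
  samples <- lapply(windows, function(w) w$samples)
  rng <- range(unlist(samples))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  breaks[1] <- breaks[1] - 1e-9; breaks[n_bins + 1] <- breaks[n_bins + 1] + 1e-9
  bins <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  counts <- vapply(samples, function(s)
    hist(s, breaks = breaks, plot = FALSE)$counts, numeric(n_bins))
  n_i <- rowSums(counts)
  N_j <- vapply(samples, length, numeric(1))
  nw <- length(windows)
  ## bias energy of bin i in window j
  cij <- vapply(seq_len(nw), function(j)
    0.5 * windows[[j]]$k * (bins - windows[[j]]$center)^2, numeric(n_bins))
  f <- if (is.null(f_init)) rep(0, nw) else as.numeric(f_init)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(exp(sweep(-cij / kT, 2, f / kT, "+")) %*% N_j)
    p <- n_i / pmax(denom, .Machine$double.xmin)
    p <- p / sum(p)
    fnew <- -kT * log(pmax(colSums(p * exp(-cij / kT)), .Machine$double.xmin))
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol) break
  }
  if (resid >= tol)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                 as.integer(max_iter), resid))
  F <- -kT * log(pmax(p, .Machine$double.xmin))
  keep <- n_i > 0
  F[!keep] <- NA
  F <- F - min(F, na.rm = TRUE)
  structure(list(bins = bins, F = F, counts = n_i, window_f = f,
                 meta = list(iterations = it, residual = resid,
                             temperature = temperature)),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("pmf_profile: %d bins, barrier (max - min over sampled range) = %.3f kcal/mol, converged in %d iterations\n",
              length(x$bins), max(x$F, na.rm = TRUE), x$meta$iterations))
  invisible(x)
}

#' Barrier of a PMF profile
#'
#' Maximum minus minimum of the PMF over adequately sampled bins.  Sparse
#' edge bins (few counts) carry large upward-biased free energies from
#' -kT log of a tiny histogram mass and are excluded.
#'
#' @param pmf a [wham_solve()] result.
#' @param min_count minimum per-bin retained-sample count.
#' @param smooth half-width (in bins) of a count-weighted moving average
#'   applied before taking the extrema; `0` disables smoothing.
#' @export
pmf_barrier <- function(pmf, min_count = 50, smooth = 4) {
  keep <- !is.na(pmf$F) & pmf$counts >= min_count
  if (!any(keep)) stop("no adequately sampled bins")
  F <- pmf$F
  if (smooth > 0) {
    n <- length(F)
    F <- vapply(seq_len(n), function(i) {
      j <- max(1, i - smooth):min(n, i + smooth)
      j <- j[keep[j]]
      if (length(j) < smooth) NA_real_ else mean(pmf$F[j])
    }, numeric(1))
    if (all(is.na(F))) F <- pmf$F
  }
  max(F[keep], na.rm = TRUE) - min(F[keep], na.rm = TRUE)
}

#' Block standard error of the window means
#'
#' Simple block-averaged standard error for each window's retained samples.
#'
#' @param windows list of [sample_window()] results.
#' @param n_blocks number of blocks.
#' @return numeric vector, one standard error per window.
#' @export
window_block_se <- function(windows, n_blocks = 10) {
  vapply(windows, function(w) {
    s <- w$samples
    b <- split(s, cut(seq_along(s), n_blocks, labels = FALSE))
    m <- vapply(b, mean, numeric(1))
    stats::sd(m) / sqrt(length(m))
  }, numeric(1))
}
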