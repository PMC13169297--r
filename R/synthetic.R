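## Synthetic-data generators --------------------------------------------------
##
## Everything the pipeline consumes can be generated here: ideal and
## perturbed ring geometries, interpolated puckering trajectories, smooth
## distance series along the beta-elimination path, and analytic surrogate
## free-energy landscapes whose stationary points reproduce the reported
## MC/TS/IC/PC layout.  All generators are seed-deterministic; the surrogate
## builders finish with an independent finite-difference stationary-point
## audit and refuse to return a landscape that fails it.

## ---- ideal ring geometries -------------------------------------------------

#' Ideal ring geometry for a canonical conformer
#'
#' Inverse Cremer-Pople construction: the out-of-plane displacement pattern
#' of the requested (theta, phi) at amplitude Q is laid onto a hexagonal
#' ring whose in-plane radius is solved so the mean bond length matches
#' ideal pyranose bonds (1.52 A C-C, 1.43 A C-O).  The returned geometry
#' reproduces the canonical (theta, phi) exactly under [cremer_pople()].
#'
#' @param label canonical conformer name (see [conformer_table()]), or a
#'   numeric `c(theta, phi)` in degrees.
#' @param Q total puckering amplitude (Angstrom), in (0.05, 1.0).
#' @return a [ring_geometry()].
#' @export
ideal_conformer_geometry <- function(label, Q = 0.57) {
  if (Q <= 0.05 || Q >= 1.0) stop("Q must lie in (0.05, 1.0) A")
  tp <- if (is.character(label)) {
    row <- .lookup_conformer(label)
    c(row$theta, row$phi)
  } else as.numeric(label)
  .ring_from_pucker(tp[1], tp[2], Q)
}

## build coordinates from (theta deg, phi deg, Q)
.ring_from_pucker <- function(theta, phi, Q) {
  j <- 0:5
  th <- theta * pi / 180; ph <- phi * pi / 180
  q2 <- Q * sin(th); q3 <- Q * cos(th)
  z <- sqrt(1 / 3) * q2 * cos(ph + 2 * pi * 2 * j / 6) +
    sqrt(1 / 6) * q3 * (-1)^j
  ## mean ideal bond (4 C-C at 1.52 A, 2 C-O at 1.43 A)
  Lbar <- (4 * 1.52 + 2 * 1.43) / 6
  ## clockwise placement (viewed from +z) keeps the Cremer-Pople normal
  ## aligned with +z so the displacements are recovered with their sign
  psi <- -2 * pi * j / 6
  a <- Lbar
  for (it in 1:50) {
    xy <- cbind(a * cos(psi), a * sin(psi))
    bonds <- sqrt(rowSums((rbind(xy[-1, ], xy[1, ]) - xy)^2) +
                    (c(z[-1], z[1]) - z)^2)
    err <- mean(bonds) - Lbar
    if (abs(err) < 1e-12) break
    chord <- 2 * sin(pi / 6)       # in-plane chord per unit radius
    a <- a - err / chord
  }
  ring_geometry(cbind(a * cos(psi), a * sin(psi), z))
}

## ---- puckering trajectories ------------------------------------------------

.sph_to_vec <- function(theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}
.vec_to_sph <- function(v) {
  v <- v / sqrt(sum(v^2))
  c(theta = acos(pmin(1, pmax(-1, v[3]))) * 180 / pi,
    phi = (atan2(v[2], v[1]) * 180 / pi) %% 360)
}

#' Great-circle puckering trajectory between two conformers
#'
#' Interpolates along the geodesic on the Cremer-Pople sphere at fixed
#' amplitude Q (slerp), optionally adding Gaussian angular noise, and builds
#' the corresponding ring geometries.
#'
#' @param a,b canonical conformer names (start, end).
#' @param n_frames number of frames (>= 2).
#' @param noise angular noise standard deviation (degrees).
#' @param seed optional integer seed.
#' @param Q puckering amplitude (Angstrom).
#' @return list with `geometries` (list of [ring_geometry()]), `table`
#'   (data.frame `frame`, `theta`, `phi`) and the endpoints.
#' @export
pucker_trajectory <- function(a, b, n_frames, noise = 0, seed = NULL,
                              Q = 0.57) {
  if (n_frames < 2) stop("need at least two frames")
  if (!is.null(seed)) set.seed(seed)
  ra <- .lookup_conformer(a); rb <- .lookup_conformer(b)
  va <- .sph_to_vec(ra$theta, ra$phi); vb <- .sph_to_vec(rb$theta, rb$phi)
  ang <- acos(pmin(1, pmax(-1, sum(va * vb))))
  u <- seq(0, 1, length.out = n_frames)
  tp <- t(vapply(u, function(s) {
    v <- if (ang < 1e-12) va else
      (sin((1 - s) * ang) * va + sin(s * ang) * vb) / sin(ang)
    .vec_to_sph(v)
  }, numeric(2)))
  if (noise > 0) {
    tp[, 1] <- tp[, 1] + stats::rnorm(n_frames, 0, noise)
    tp[, 1] <- pmin(pmax(tp[, 1], 0.1), 179.9)
    tp[, 2] <- (tp[, 2] + stats::rnorm(n_frames, 0, noise)) %% 360
  }
  geoms <- lapply(seq_len(n_frames), function(k)
    .ring_from_pucker(tp[k, 1], tp[k, 2], Q))
  list(geometries = geoms,
       table = data.frame(frame = seq_len(n_frames),
                          theta = tp[, 1], phi = tp[, 2]),
       a = a, b = b)
}

#' Ring-geometry fixture for the beta-elimination itinerary
#'
#' Emulates the conformational change of the +1 sugar along the reaction
#' path: the ring stays in the 1C4 region through the Michaelis complex and
#' the transition state and relaxes to 1H2 in the product complex, moving
#' along the phi = 270 meridian.
#'
#' @param n_frames number of frames.
#' @param noise angular noise (degrees).
#' @param seed optional seed.
#' @return list with `geometries`, `table` and `stages`
#'   (`c(MC =, TS =, PC =)` frame indices).
#' @export
reaction_pucker_fixture <- function(n_frames = 60, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th_end <- .lookup_conformer("1H2")$theta
  theta <- seq(178, th_end, length.out = n_frames)
  phi <- rep(270, n_frames)
  if (noise > 0) {
    theta <- pmin(pmax(theta + stats::rnorm(n_frames, 0, noise), 0.1), 179.9)
    phi <- (phi + stats::rnorm(n_frames, 0, noise)) %% 360
  }
  theta[n_frames] <- th_end            # product frame lands on 1H2 exactly
  geoms <- lapply(seq_len(n_frames), function(k)
    .ring_from_pucker(theta[k], phi[k], 0.5))
  list(geometries = geoms,
       table = data.frame(frame = seq_len(n_frames), theta = theta, phi = phi),
       stages = c(MC = 1L, TS = as.integer(round(0.35 * n_frames)),
                  PC = as.integer(n_frames)))
}

## ---- distance series along the reaction path -------------------------------

.STAGE_DISTANCES <- data.frame(
  stage = c("MC", "TS", "IC", "PC"),
  u = 0:3,
  d1 = c(1.09, 2.00, 2.85, 3.70),
  d2 = c(2.09, 1.33, 1.05, 1.90),
  d3 = c(2.44, 2.50, 2.15, 0.98),
  d4 = c(1.45, 1.47, 2.80, 2.48),
  dC5C6 = c(1.54, 1.45, 1.54, 1.52),
  dC4C5 = c(1.50, 1.44, 1.37, 1.35))

#' Stage-anchored distances of the beta-elimination mechanism
#'
#' The catalytically relevant distances at the four stationary points
#' (MC, TS, IC, PC): H5-C5 (d1), H5-N (d2), H5-O4 (d3), the glycosidic
#' C4-O4 bond (d4), and the C5-C6 / C4-C5 ring bonds whose orders change as
#' the C4=C5 double bond forms.  The implied CV values are CV1 = d1 - d2 and
#' CV2 = d2 - d3 + d4; at MC these give (-1.0, 1.1), at TS (0.67, 0.3), at
#' IC (1.8, 1.7) and at PC (1.8, 3.4).
#'
#' @return data.frame of stage anchors.
#' @export
stage_distance_anchors <- function() .STAGE_DISTANCES

#' Smooth distance series along the reaction path
#'
#' Monotone cubic interpolation of the stage anchors over a progress
#' coordinate, with Gaussian noise; CV1/CV2 are computed from the (noisy)
#' distances so the CV columns are exactly consistent with the distance
#' columns.
#'
#' @param n_frames number of frames (>= 3).
#' @param seed optional seed.
#' @param noise distance noise standard deviation (Angstrom).
#' @return data.frame with `frame`, `u` (progress, 0..3), the six distances,
#'   `cv1`, `cv2`; stage anchors attached as attribute `"anchors"`.
#' @export
reaction_distance_series <- function(n_frames = 121, seed = NULL,
                                     noise = 0.01) {
  if (n_frames < 3) stop("need at least three frames")
  if (!is.null(seed)) set.seed(seed)
  anchors <- .STAGE_DISTANCES
  u <- seq(0, 3, length.out = n_frames)
  out <- data.frame(frame = seq_len(n_frames), u = u)
  for (col in c("d1", "d2", "d3", "d4", "dC5C6", "dC4C5")) {
    f <- stats::splinefun(anchors$u, anchors[[col]], method = "monoH.FC")
    v <- f(u)
    if (noise > 0) v <- v + stats::rnorm(n_frames, 0, noise)
    out[[col]] <- pmax(v, 0.5)
  }
  out$cv1 <- out$d1 - out$d2
  out$cv2 <- out$d2 - out$d3 + out$d4
  attr(out, "anchors") <- anchors
  out
}

## ---- stationary-point machinery --------------------------------------------

## Newton search for a stationary point from a starting guess (any index)
.newton_stationary <- function(pot, x0, max_iter = 80, tol = 1e-11) {
  x <- as.numeric(x0)
  d <- pot$dim
  h <- 1e-5
  for (it in seq_len(max_iter)) {
    g <- as.numeric(potential_gradient(pot, x))
    if (sqrt(sum(g^2)) < tol) break
    H <- matrix(0, d, d)
    for (i in seq_len(d)) {
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      H[i, ] <- (as.numeric(potential_gradient(pot, xp)) -
                   as.numeric(potential_gradient(pot, xm))) / (2 * h)
    }
    H <- (H + t(H)) / 2
    dx <- tryCatch(solve(H, g), error = function(e) g * 0.01)
    nd <- sqrt(sum(dx^2))
    if (nd > 0.2) dx <- dx * 0.2 / nd
    x <- x - dx
  }
  list(x = x, F = potential_energy(pot, x),
       grad_norm = sqrt(sum(potential_gradient(pot, x)^2)))
}

.fd_hessian <- function(pot, x, h = 1e-4) {
  d <- pot$dim
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    H[i, ] <- (as.numeric(potential_gradient(pot, xp)) -
                 as.numeric(potential_gradient(pot, xm))) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Audit the stationary points of a surrogate landscape
#'
#' Independent finite-difference check of a landscape's constructed
#' stationary points: at each anchor the gradient must (numerically) vanish,
#' the energy must match the target within `tol_F`, the position must be
#' stationary within `tol_x`, and the Hessian signature must match the
#' declared kind (`"min"` or `"saddle"`).
#'
#' @param pot a [model_potential()].
#' @param anchors data.frame with columns `name`, `kind`, per-dimension
#'   coordinates and `F` (target energy).
#' @param tol_F energy tolerance (kcal/mol).
#' @param tol_x position tolerance (CV units).
#' @return invisibly, the audit table (with achieved positions/energies);
#'   errors if any check fails.
#' @export
audit_stationary_points <- function(pot, anchors, tol_F = 0.1, tol_x = 0.05) {
  d <- pot$dim
  coord_cols <- setdiff(names(anchors), c("name", "kind", "F"))[seq_len(d)]
  res <- anchors
  res$x_err <- res$F_err <- res$grad <- NA_real_
  for (k in seq_len(nrow(anchors))) {
    x0 <- as.numeric(anchors[k, coord_cols])
    st <- .newton_stationary(pot, x0)
    ## finite-difference gradient at the refined point (independent of the
    ## analytic gradient used by the samplers)
    h <- 1e-5
    gfd <- vapply(seq_len(d), function(i) {
      xp <- st$x; xp[i] <- xp[i] + h
      xm <- st$x; xm[i] <- xm[i] - h
      (potential_energy(pot, xp) - potential_energy(pot, xm)) / (2 * h)
    }, numeric(1))
    ev <- eigen(.fd_hessian(pot, st$x), symmetric = TRUE, only.values = TRUE)$values
    kind_ok <- if (anchors$kind[k] == "min") all(ev > 0) else
      (sum(ev < 0) == 1 && sum(ev > 0) == d - 1)
    res$x_err[k] <- sqrt(sum((st$x - x0)^2))
    res$F_err[k] <- st$F - anchors$F[k]
    res$grad[k] <- sqrt(sum(gfd^2))
    if (res$x_err[k] > tol_x)
      stop(sprintf("audit: %s stationary point off target by %.3f",
                   anchors$name[k], res$x_err[k]))
    if (abs(res$F_err[k]) > tol_F)
      stop(sprintf("audit: %s energy off target by %.3f kcal/mol",
                   anchors$name[k], res$F_err[k]))
    if (res$grad[k] > 5e-3)
      stop(sprintf("audit: %s gradient does not vanish (%.2g)",
                   anchors$name[k], res$grad[k]))
    if (!kind_ok)
      stop(sprintf("audit: %s has the wrong Hessian signature", anchors$name[k]))
  }
  invisible(res)
}

## ---- surrogate reaction landscape ------------------------------------------

.surrogate_env <- new.env(parent = emptyenv())

.REACTION_ANCHORS <- data.frame(
  name = c("MC", "TS", "IC", "PC"),
  kind = c("min", "saddle", "min", "min"),
  cv1 = c(-1.0, 0.7, 1.8, 1.8),
  cv2 = c(1.1, 0.3, 1.7, 3.4),
  F = c(0, 19, -1, -5))

## assemble the reaction landscape: a valley tube along a smooth spline
## through the four anchors, carrying a piecewise-cosine energy profile with
## zero slope at each anchor (so every anchor is an exact stationary point),
## on an otherwise flat plateau bounded by quadratic walls
.reaction_pot <- function(plateau = 45, sigma_perp = 0.35,
                          ic_pc_bump = 0.5, n_poly = 321) {
  A <- as.matrix(.REACTION_ANCHORS[, c("cv1", "cv2")])
  tt <- c(0, cumsum(sqrt(rowSums(diff(A)^2))))
  sx <- stats::splinefun(tt, A[, 1], method = "natural")
  sy <- stats::splinefun(tt, A[, 2], method = "natural")
  uu <- seq(0, max(tt), length.out = 2000)
  cx <- sx(uu); cy <- sy(uu)
  arc <- c(0, cumsum(sqrt(diff(cx)^2 + diff(cy)^2)))
  ## resample uniformly in arclength
  s_out <- seq(0, max(arc), length.out = n_poly)
  pts <- cbind(stats::approx(arc, cx, xout = s_out)$y,
               stats::approx(arc, cy, xout = s_out)$y)
  pot <- model_potential(
    dim = 2,
    tube = list(points = pts, sb = 0, fb = 0, sigma = sigma_perp,
                plateau = plateau),
    walls = list(lo = c(-2.0, -0.6), hi = c(2.9, 4.5), k = 100),
    offset = plateau)
  ## profile knots at the arclength of each anchor's projection onto the
  ## final polyline (self-consistent with the tube's own projection), plus
  ## the small barrier between IC and PC that makes the IC a genuine basin
  pr <- .tube_project(pot$tube, A)
  sb <- pr$s
  fb <- .REACTION_ANCHORS$F
  sb <- c(sb[1:3], (sb[3] + sb[4]) / 2, sb[4])
  fb <- c(fb[1:3], ic_pc_bump, fb[4])
  pot$tube$sb <- sb
  pot$tube$fb <- fb
  pot
}

#' Surrogate reaction free-energy landscape
#'
#' Analytic 2D model potential over (CV1, CV2): a smooth valley following a
#' spline path through the four stationary points of the beta-elimination
#' mechanism, carrying an energy profile with MC at (-1.0, 1.1) and F = 0,
#' the saddle TS at (0.7, 0.3) with F = 19, a shallow intermediate IC at
#' (1.8, 1.7) with F = -1 (separated from the product by a 1.5 kcal/mol
#' bump) and PC at (1.8, 3.4) with F = -5 (kcal/mol), embedded in a flat
#' 25 kcal/mol plateau with confining walls.  All stationary points are
#' exact by construction and are verified with
#' [audit_stationary_points()] before the landscape is returned.
#'
#' @return a [model_potential()] with attribute `"anchors"`.
#' @export
build_surrogate_reaction_landscape <- function() {
  if (is.null(.surrogate_env$reaction)) {
    pot <- .reaction_pot()
    audit_stationary_points(pot, .REACTION_ANCHORS)
    attr(pot, "anchors") <- .REACTION_ANCHORS
    .surrogate_env$reaction <- pot
  }
  .surrogate_env$reaction
}

## ---- surrogate conformational (pucker) landscape ---------------------------

.PUCKER_ANCHORS <- local({
  d <- data.frame(
    name = c("1C4", "5S1", "OS2"),
    kind = "min",
    phi = c(270, 90, 330) * pi / 180,
    theta = c(180, 90, 90) * pi / 180,
    F = c(0, 0.5, 2.0))
  d
})

.pucker_pot <- function(p) {
  model_potential(
    dim = 2, periodic = c(TRUE, FALSE), period = c(2 * pi, NA),
    gauss = list(
      centers = rbind(c(0, pi), c(pi / 2, pi / 2), c(11 * pi / 6, pi / 2)),
      prec = list(diag(c(0, 1 / 0.30^2)),        # 1C4 trench along theta = pi
                  diag(1 / c(0.35, 0.35)^2),
                  diag(1 / c(0.35, 0.35)^2)),
      heights = c(-p$D1, -p$D5, -p$DO)),
    walls = list(lo = c(0, 1.0), hi = c(2 * pi, pi), k = 50),
    offset = p$P)
}

.calibrate_pucker <- function(n_iter = 40) {
  p <- list(P = 5, D1 = 5, D5 = 4.5, DO = 3)
  for (it in seq_len(n_iter)) {
    pot <- .pucker_pot(p)
    f1 <- potential_energy(pot, c(3 * pi / 2, pi))
    s5 <- .newton_stationary(pot, c(pi / 2, pi / 2))
    sO <- .newton_stationary(pot, c(11 * pi / 6, pi / 2))
    p$D5 <- p$D5 + 0.9 * ((s5$F - f1) - 0.5)
    p$DO <- p$DO + 0.9 * ((sO$F - f1) - 2.0)
    p$P <- p$P - f1
  }
  p
}

#' Surrogate conformational landscape on the puckering coordinates
#'
#' Periodic 2D model potential over (phi, theta) in radians, with a global
#' 1C4 minimum along the theta = pi polar line, a 5S1 minimum 0.5 kcal/mol
#' above it and an OS2 minimum 2.0 kcal/mol above it, matching the
#' conformational free-energy landscape of the +1 sugar.  phi is periodic;
#' theta is confined to [1.0, pi] by quadratic walls.
#'
#' @return a [model_potential()] with attribute `"anchors"`.
#' @export
build_surrogate_pucker_landscape <- function() {
  if (is.null(.surrogate_env$pucker)) {
    p <- .calibrate_pucker()
    pot <- .pucker_pot(p)
    anchors <- .PUCKER_ANCHORS[-1, ]    # the polar trench is checked separately
    names(anchors)[3:4] <- c("phi", "theta")
    audit_stationary_points(
      pot, data.frame(name = anchors$name, kind = anchors$kind,
                      phi = anchors$phi, theta = anchors$theta,
                      F = anchors$F))
    ## trench reference: flat in phi, minimum in theta at the pole
    f1 <- potential_energy(pot, cbind(seq(0, 2 * pi, length.out = 13), pi))
    if (max(abs(f1 - 0)) > 0.1)
      stop("audit: 1C4 polar trench is not at the reference level")
    attr(pot, "anchors") <- .PUCKER_ANCHORS
    .surrogate_env$pucker <- pot
  }
  .surrogate_env$pucker
}

## ---- surrogate 1D profile for umbrella sampling ----------------------------

#' Surrogate 1D free-energy profile for umbrella sampling
#'
#' Analytic 1D potential along CV1: a piecewise-cosine profile with a
#' reactant minimum at -0.75 A (F = 0), the barrier maximum at CV1 = 0.7 A
#' with F = 17.7 kcal/mol (the refined activation free energy), and a
#' product minimum at 1.9 A with F = -5, bounded by quadratic walls.  Knots
#' have zero slope, so the stationary points are exact by construction.
#'
#' @return a [model_potential()] with attributes `"anchors"` and
#'   `"barrier"`.
#' @export
build_surrogate_us_profile <- function() {
  if (!is.null(.surrogate_env$us)) return(.surrogate_env$us)
  pot <- model_potential(
    dim = 1,
    profile = list(sb = c(-0.75, 0.7, 1.9), fb = c(0, 17.7, -5)),
    walls = list(lo = -1.6, hi = 2.5, k = 100))
  anchors <- data.frame(name = c("reactant", "TS", "product"),
                        kind = c("min", "saddle", "min"),
                        cv1 = c(-0.75, 0.7, 1.9), F = c(0, 17.7, -5))
  audit_stationary_points(pot, anchors, tol_x = 0.02)
  attr(pot, "anchors") <- anchors
  attr(pot, "barrier") <- 17.7
  .surrogate_env$us <- pot
  pot
}
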