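#' Six-membered ring geometry
#'
#' Holds the Cartesian coordinates (Angstrom) of the six ring atoms of a
#' pyranose, cyclically ordered O5, C1, C2, C3, C4, C5 (the package's fixed
#' Cremer-Pople convention: O5 is atom 1).  Use [reorder_ring()] if your
#' source lists the atoms differently.
#'
#' @param coords 6 x 3 numeric matrix of positions.
#' @param atoms character vector of atom names (defaults to the convention
#'   order).
#' @return object of class `ring_geometry`.
#' @export
ring_geometry <- function(coords, atoms = .RING_ATOMS) {
  coords <- as.matrix(coords)
  if (!all(dim(coords) == c(6, 3)) || !is.numeric(coords))
    stop("ring coordinates must be a 6 x 3 numeric matrix")
  if (anyNA(coords)) stop("ring coordinates contain NA")
  d <- sqrt(rowSums((coords - coords[c(2:6, 1), ])^2))
  if (any(d < 1e-6)) stop("coincident consecutive ring atoms")
  dd <- as.matrix(stats::dist(coords))
  if (any(dd[upper.tri(dd)] < 1e-6)) stop("coincident ring atoms")
  structure(list(coords = coords, atoms = as.character(atoms)),
            class = "ring_geometry")
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat("ring_geometry (", paste(x$atoms, collapse = "-"), ")\n", sep = "")
  print(round(x$coords, 4))
  invisible(x)
}

#' Reorder ring atoms into the package convention
#'
#' @param geometry a [ring_geometry()] (or 6 x 3 matrix) whose rows are
#'   labeled by `atoms`.
#' @param order character vector giving the desired order (default the
#'   O5, C1...C5 convention).
#' @return a [ring_geometry()] in convention order.
#' @export
reorder_ring <- function(geometry, order = .RING_ATOMS) {
  if (inherits(geometry, "ring_geometry")) {
    coords <- geometry$coords; atoms <- geometry$atoms
  } else {
    coords <- as.matrix(geometry); atoms <- rownames(coords)
  }
  i <- match(order, atoms)
  if (anyNA(i)) stop("missing ring atom(s): ", paste(order[is.na(i)], collapse = ", "))
  ring_geometry(coords[i, , drop = FALSE], order)
}

#' Cremer-Pople puckering coordinates of a six-membered ring
#'
#' Computes the puckering amplitude-phase description (Q, theta, phi) of a
#' six-membered ring: translation to the geometric centre, mean-plane normal
#' from the two fixed trigonometric position sums, out-of-plane displacements,
#' and their Fourier decomposition into the m = 2 (q2, phi2) and m = 3 (q3)
#' modes.  The result is invariant under rigid rotation and translation of
#' the input.
#'
#' @param geometry a [ring_geometry()] or 6 x 3 coordinate matrix in
#'   convention order.
#' @param amplitude_floor total amplitudes Q below this value (Angstrom) are
#'   treated as planar: theta/phi are then undefined and an error is raised.
#' @return object of class `pucker_coords`: list with `Q` (Angstrom), `theta`
#'   (degrees, 0..180), `phi` (degrees, 0..360, periodic), `q2`, `q3`, `phi2`.
#' @export
cremer_pople <- function(geometry, amplitude_floor = 0.05) {
  if (inherits(geometry, "ring_geometry")) coords <- geometry$coords
  else coords <- ring_geometry(geometry)$coords

  r <- sweep(coords, 2, colMeans(coords))
  j <- 0:5
  s <- sin(2 * pi * j / 6); cc <- cos(2 * pi * j / 6)
  R1 <- colSums(r * s)
  R2 <- colSums(r * cc)
  n <- c(R1[2] * R2[3] - R1[3] * R2[2],
         R1[3] * R2[1] - R1[1] * R2[3],
         R1[1] * R2[2] - R1[2] * R2[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("degenerate ring geometry (collinear atoms)")
  n <- n / nn
  z <- as.numeric(r %*% n)

  ang2 <- 2 * pi * 2 * j / 6
  q2c <- sqrt(1 / 3) * sum(z * cos(ang2))
  q2s <- -sqrt(1 / 3) * sum(z * sin(ang2))
  q2 <- sqrt(q2c^2 + q2s^2)
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  Q <- sqrt(q2^2 + q3^2)
  planar <- Q < amplitude_floor
  if (planar)
    stop("planar ring (Q = ", signif(Q, 3), " A below amplitude floor ",
         amplitude_floor, " A): theta/phi undefined")
  phi2 <- (atan2(q2s, q2c) * 180 / pi) %% 360
  theta <- atan2(q2, q3) * 180 / pi
  structure(list(Q = Q, theta = theta, phi = phi2, q2 = q2, q3 = q3,
                 phi2 = phi2), class = "pucker_coords")
}

#' @export
print.pucker_coords <- function(x, ...) {
  cat(sprintf("pucker_coords: Q = %.4f A, theta = %.2f deg, phi = %.2f deg\n",
              x$Q, x$theta, x$phi))
  invisible(x)
}

## great-circle angular distance (degrees) between (theta, phi) points on the
## puckering sphere; phi periodic
.sphere_dist <- function(theta1, phi1, theta2, phi2) {
  t1 <- theta1 * pi / 180; t2 <- theta2 * pi / 180
  dp <- (phi1 - phi2) * pi / 180
  cd <- cos(t1) * cos(t2) + sin(t1) * sin(t2) * cos(dp)
  acos(pmin(1, pmax(-1, cd))) * 180 / pi
}

#' Classify a puckered ring against the canonical conformer sphere
#'
#' Returns the canonical conformer whose (theta, phi) position minimises the
#' great-circle distance on the Cremer-Pople sphere (phi periodic).  Ties are
#' broken deterministically by table order.
#'
#' @param p a [cremer_pople()] result, or a list/vector with `theta` and
#'   `phi` in degrees.
#' @return one-row data.frame (`name`, `class`, `theta`, `phi`, `distance`).
#' @export
classify_conformer <- function(p) {
  tp <- .theta_phi(p)
  tab <- conformer_table()
  d <- .sphere_dist(tp[1], tp[2], tab$theta, tab$phi)
  i <- which.min(d)            # which.min takes the first of tied entries
  out <- tab[i, ]
  out$distance <- d[i]
  rownames(out) <- NULL
  out
}

.theta_phi <- function(p) {
  if (inherits(p, "pucker_coords") || is.list(p)) {
    if (is.null(p$theta) || is.null(p$phi)) stop("need theta and phi")
    c(p$theta, p$phi)
  } else if (is.numeric(p) && length(p) == 2) {
    c(p[1], p[2])
  } else stop("cannot interpret puckering state")
}

#' Product-ring pathway relation for polysaccharide lyases
#'
#' The unsaturated product of a lyase keeps the C3-C4-C5-O5 ring atoms
#' coplanar; the canonical conformers compatible with that restriction lie on
#' the continuous curve theta = 90 + 39 cos(phi - 270) on the Cremer-Pople
#' Mercator surface (degrees).
#'
#' @param phi meridian angle(s), degrees.
#' @return theta on the pathway, degrees (range 51..129, period 360).
#' @export
pl_path_theta <- function(phi) {
  90 + 39 * cos((phi - 270) * pi / 180)
}

#' Angular distance from a puckering state to the PL product pathway
#'
#' Minimum great-circle distance (degrees) from (theta, phi) to the
#' parametric curve [pl_path_theta()], found numerically over the curve
#' parameter.
#'
#' @inheritParams classify_conformer
#' @return distance in degrees.
#' @export
distance_to_pl_path <- function(p) {
  tp <- .theta_phi(p)
  f <- function(phi) .sphere_dist(tp[1], tp[2], pl_path_theta(phi), phi)
  grid <- seq(0, 359.5, by = 0.5)
  dg <- f(grid)
  i <- which.min(dg)
  lo <- grid[i] - 1; hi <- grid[i] + 1
  ## minimise the squared distance: smooth at the on-curve minimum
  sqrt(stats::optimize(function(p) f(p)^2, c(lo, hi), tol = 1e-12)$objective)
}

#' Conformers on the PL product pathway
#'
#' The eight canonical conformers satisfying the C3-C4-C5-O5 planarity
#' restriction of unsaturated lyase products.
#' @return character vector of conformer names.
#' @export
pl_path_conformers <- function() {
  c("3,OB", "E1", "2H1", "2E", "B3,O", "1E", "1H2", "E2")
}
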