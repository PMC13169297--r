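#' Analytic model potentials on collective-variable space
#'
#' A `model_potential` is a smooth analytic energy function (kcal/mol) over a
#' 1- or 2-dimensional collective-variable space, used as a desk-scale
#' surrogate for the forces that a QM/MM engine would supply.  It is a sum of
#' (possibly rotated, anisotropic) Gaussian components, harmonic terms and
#' one-sided quadratic walls, with per-dimension periodicity.  The analytic
#' gradient is available and is checked against finite differences in the test
#' suite.
#'
#' @param dim dimensionality (1 or 2).
#' @param periodic logical vector, one flag per dimension.
#' @param period numeric vector of periods (used where `periodic` is `TRUE`).
#' @param offset constant energy shift (kcal/mol).
#' @param gauss list with `centers` (G x dim matrix), `prec` (list of
#'   dim x dim precision matrices) and `heights` (numeric, signed; negative
#'   heights are wells).
#' @param quads list of harmonic terms, each `list(k =, center =)` with
#'   per-dimension force constants (0 disables a dimension).
#' @param walls `list(lo =, hi =, k =)` one-sided quadratic walls applied to
#'   non-periodic dimensions, or `NULL`.
#' @param tube valley ("tube") component for 2D potentials:
#'   `list(points =, sb =, fb =, sigma =, plateau =)`.  The energy is
#'   `plateau - (plateau - f(s)) * exp(-d^2 / (2 sigma^2))` where `s` and `d`
#'   are the arclength and perpendicular distance of the nearest point on the
#'   polyline `points`, and `f` is the piecewise-cosine profile through the
#'   knots `(sb, fb)` (zero slope at every knot, so each knot on the path is
#'   an exact stationary point).
#' @param profile 1D piecewise-cosine energy profile `list(sb =, fb =)`:
#'   `V(x) = f(x)` with zero slope at every knot.
#' @return an object of class `model_potential`.
#' @export
model_potential <- function(dim, periodic = rep(FALSE, dim),
                            period = rep(NA_real_, dim), offset = 0,
                            gauss = NULL, quads = NULL, walls = NULL,
                            tube = NULL, profile = NULL) {
  stopifnot(dim %in% c(1L, 2L), length(periodic) == dim)
  if (!is.null(gauss)) {
    gauss$centers <- matrix(as.numeric(gauss$centers), ncol = dim)
    stopifnot(length(gauss$heights) == nrow(gauss$centers),
              length(gauss$prec) == nrow(gauss$centers))
    gauss$prec <- lapply(gauss$prec, function(p) matrix(as.numeric(p), dim, dim))
  }
  if (!is.null(quads)) {
    quads <- lapply(quads, function(q) {
      stopifnot(length(q$k) == dim, length(q$center) == dim)
      q
    })
  }
  if (!is.null(tube)) {
    stopifnot(dim == 2L, is.matrix(tube$points), ncol(tube$points) == 2,
              length(tube$sb) == length(tube$fb), tube$sigma > 0)
    seg <- diff(tube$points)
    tube$arc <- c(0, cumsum(sqrt(rowSums(seg^2))))
  }
  if (!is.null(profile)) {
    stopifnot(dim == 1L, length(profile$sb) == length(profile$fb),
              !is.unsorted(profile$sb))
  }
  pot <- list(dim = as.integer(dim), periodic = as.logical(periodic),
              period = as.numeric(period), offset = as.numeric(offset),
              gauss = gauss, quads = quads, walls = walls,
              tube = tube, profile = profile)
  class(pot) <- "model_potential"
  pot
}

## piecewise-cosine interpolation through (sb, fb) with zero slope at knots;
## returns value and derivative
.pw_cosine <- function(s, sb, fb) {
  n <- length(sb)
  i <- findInterval(s, sb)
  v <- numeric(length(s)); dv <- numeric(length(s))
  lo <- i < 1 | s <= sb[1]
  hi <- i >= n
  v[lo] <- fb[1]; v[hi] <- fb[n]
  mid <- !(lo | hi)
  if (any(mid)) {
    im <- i[mid]
    d <- sb[im + 1] - sb[im]
    u <- (s[mid] - sb[im]) / d
    a <- fb[im]; b <- fb[im + 1]
    v[mid] <- a + (b - a) * (1 - cos(pi * u)) / 2
    dv[mid] <- (b - a) * pi * sin(pi * u) / (2 * d)
  }
  list(v = v, dv = dv)
}

## nearest point on a polyline: returns arclength s, distance d, tangent and
## outward normal for each query point (rows of x)
.tube_project <- function(tube, x) {
  pts <- tube$points; arc <- tube$arc
  n <- nrow(pts)
  out_s <- out_d <- numeric(nrow(x))
  out_t <- out_n <- matrix(0, nrow(x), 2)
  clamped <- logical(nrow(x))
  p1 <- pts[-n, , drop = FALSE]; p2 <- pts[-1, , drop = FALSE]
  seg <- p2 - p1
  len2 <- rowSums(seg^2)
  for (q in seq_len(nrow(x))) {
    dx <- x[q, 1] - p1[, 1]; dy <- x[q, 2] - p1[, 2]
    tpar <- pmin(pmax((dx * seg[, 1] + dy * seg[, 2]) / len2, 0), 1)
    px <- p1[, 1] + tpar * seg[, 1]; py <- p1[, 2] + tpar * seg[, 2]
    d2 <- (x[q, 1] - px)^2 + (x[q, 2] - py)^2
    k <- which.min(d2)
    d <- sqrt(d2[k])
    out_s[q] <- arc[k] + tpar[k] * sqrt(len2[k])
    out_d[q] <- d
    out_t[q, ] <- seg[k, ] / sqrt(len2[k])
    out_n[q, ] <- if (d > 1e-12) c(x[q, 1] - px[k], x[q, 2] - py[k]) / d else c(0, 0)
    ## projection pinned to a vertex: s is locally constant there
    clamped[q] <- tpar[k] <= 0 || tpar[k] >= 1
  }
  list(s = out_s, d = out_d, t = out_t, n = out_n, clamped = clamped)
}

#' @export
print.model_potential <- function(x, ...) {
  ng <- if (is.null(x$gauss)) 0L else nrow(x$gauss$centers)
  nq <- if (is.null(x$quads)) 0L else length(x$quads)
  cat(sprintf("model_potential: %dD, %d Gaussian component(s), %d harmonic term(s)%s\n",
              x$dim, ng, nq,
              if (any(x$periodic)) sprintf(", periodic dim(s): %s",
                                           paste(which(x$periodic), collapse = ",")) else ""))
  invisible(x)
}

## minimum-image difference, vectorised over a column
.wrap_diff <- function(d, periodic, period) {
  if (!periodic) return(d)
  d <- d %% period
  d[d > period / 2] <- d[d > period / 2] - period
  d
}

#' Evaluate a model potential
#'
#' @param pot a [model_potential()].
#' @param x numeric vector (one point) or matrix with one point per row.
#' @return numeric vector of energies (kcal/mol).
#' @export
potential_energy <- function(pot, x) {
  x <- .as_points(x, pot$dim)
  n <- nrow(x)
  V <- rep(pot$offset, n)
  if (!is.null(pot$gauss)) {
    for (g in seq_along(pot$gauss$heights)) {
      dx <- vapply(seq_len(pot$dim), function(i)
        .wrap_diff(x[, i] - pot$gauss$centers[g, i], pot$periodic[i], pot$period[i]),
        numeric(n))
      dx <- matrix(dx, nrow = n)
      P <- pot$gauss$prec[[g]]
      q <- rowSums((dx %*% P) * dx)
      V <- V + pot$gauss$heights[g] * exp(-0.5 * q)
    }
  }
  for (qd in pot$quads) {
    for (i in seq_len(pot$dim)) {
      d <- .wrap_diff(x[, i] - qd$center[i], pot$periodic[i], pot$period[i])
      V <- V + 0.5 * qd$k[i] * d^2
    }
  }
  if (!is.null(pot$tube)) {
    pr <- .tube_project(pot$tube, x)
    f <- .pw_cosine(pr$s, pot$tube$sb, pot$tube$fb)$v
    V <- V - (pot$tube$plateau - f) * exp(-pr$d^2 / (2 * pot$tube$sigma^2))
  }
  if (!is.null(pot$profile)) {
    V <- V + .pw_cosine(x[, 1], pot$profile$sb, pot$profile$fb)$v
  }
  if (!is.null(pot$walls)) {
    for (i in seq_len(pot$dim)) {
      if (pot$periodic[i]) next
      over <- pmax(x[, i] - pot$walls$hi[i], 0)
      under <- pmax(pot$walls$lo[i] - x[, i], 0)
      V <- V + pot$walls$k * (over^2 + under^2)
    }
  }
  V
}

#' Analytic gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return matrix (points x dim) of gradients (kcal/mol per CV unit).
#' @export
potential_gradient <- function(pot, x) {
  x <- .as_points(x, pot$dim)
  n <- nrow(x)
  G <- matrix(0, n, pot$dim)
  if (!is.null(pot$gauss)) {
    for (g in seq_along(pot$gauss$heights)) {
      dx <- vapply(seq_len(pot$dim), function(i)
        .wrap_diff(x[, i] - pot$gauss$centers[g, i], pot$periodic[i], pot$period[i]),
        numeric(n))
      dx <- matrix(dx, nrow = n)
      P <- pot$gauss$prec[[g]]
      pd <- dx %*% P
      q <- rowSums(pd * dx)
      G <- G - pot$gauss$heights[g] * exp(-0.5 * q) * pd
    }
  }
  for (qd in pot$quads) {
    for (i in seq_len(pot$dim)) {
      d <- .wrap_diff(x[, i] - qd$center[i], pot$periodic[i], pot$period[i])
      G[, i] <- G[, i] + qd$k[i] * d
    }
  }
  if (!is.null(pot$tube)) {
    pr <- .tube_project(pot$tube, x)
    f <- .pw_cosine(pr$s, pot$tube$sb, pot$tube$fb)
    e <- exp(-pr$d^2 / (2 * pot$tube$sigma^2))
    A <- pot$tube$plateau - f$v
    G <- G + (f$dv * !pr$clamped) * e * pr$t +
      A * e * (pr$d / pot$tube$sigma^2) * pr$n
  }
  if (!is.null(pot$profile)) {
    G[, 1] <- G[, 1] + .pw_cosine(x[, 1], pot$profile$sb, pot$profile$fb)$dv
  }
  if (!is.null(pot$walls)) {
    for (i in seq_len(pot$dim)) {
      if (pot$periodic[i]) next
      over <- pmax(x[, i] - pot$walls$hi[i], 0)
      under <- pmax(pot$walls$lo[i] - x[, i], 0)
      G[, i] <- G[, i] + 2 * pot$walls$k * (over - under)
    }
  }
  G
}

#' Check the analytic gradient against central finite differences
#'
#' @param pot a [model_potential()].
#' @param x matrix of evaluation points (one per row).
#' @param h finite-difference step.
#' @return maximum absolute deviation between analytic and numerical gradient.
#' @export
check_gradient <- function(pot, x, h = 1e-6) {
  x <- .as_points(x, pot$dim)
  ga <- potential_gradient(pot, x)
  worst <- 0
  for (i in seq_len(pot$dim)) {
    xp <- x; xp[, i] <- xp[, i] + h
    xm <- x; xm[, i] <- xm[, i] - h
    gn <- (potential_energy(pot, xp) - potential_energy(pot, xm)) / (2 * h)
    worst <- max(worst, max(abs(gn - ga[, i])))
  }
  worst
}

#' Harmonic well
#'
#' @param k per-dimension force constants (kcal/mol per unit^2).
#' @param center well position.
#' @return a [model_potential()].
#' @export
harmonic_potential <- function(k, center = rep(0, length(k))) {
  model_potential(dim = length(k),
                  quads = list(list(k = as.numeric(k), center = as.numeric(center))))
}

#' Symmetric 1D double well
#'
#' Two minima at `+-half_separation` separated by a barrier of exactly
#' `barrier` kcal/mol at the origin, realised as a harmonic confinement plus a
#' central Gaussian bump (closed-form construction, no fitting).
#'
#' @param barrier barrier height (kcal/mol).
#' @param half_separation half the distance between the two minima.
#' @return a [model_potential()] whose attribute `"minima"` holds the two
#'   minimum positions and `"barrier"` the constructed barrier.
#' @export
double_well_potential <- function(barrier = 5, half_separation = 1) {
  x0 <- half_separation
  sigma <- x0 / 2
  B <- barrier / (1 - 3 * exp(-2))
  k <- B * exp(-2) / sigma^2
  pot <- model_potential(
    dim = 1,
    gauss = list(centers = matrix(0), prec = list(matrix(1 / sigma^2)), heights = B),
    quads = list(list(k = k, center = 0)),
    walls = list(lo = -4 * x0, hi = 4 * x0, k = 100),
    offset = -(0.5 * k * x0^2 + B * exp(-2)))
  attr(pot, "minima") <- c(-x0, x0)
  attr(pot, "barrier") <- barrier
  pot
}

## rotated 2D Gaussian precision matrix from axis widths and an angle
.prec2d <- function(sigma_long, sigma_perp, angle) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  R %*% diag(c(1 / sigma_long^2, 1 / sigma_perp^2)) %*% t(R)
}

.as_points <- function(x, dim) {
  if (is.null(dim(x))) {
    if (length(x) == dim) x <- matrix(x, nrow = 1)
    else if (dim == 1L) x <- matrix(x, ncol = 1)
    else stop("point has wrong dimensionality")
  }
  x <- as.matrix(x)
  if (ncol(x) != dim) stop("points must have ", dim, " column(s)")
  x
}

#' Boltzmann constant in kcal/(mol K)
#' @export
kB_KCAL <- 0.0019872041
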