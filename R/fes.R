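#' Gridded free-energy surface
#'
#' Free-energy values (kcal/mol) on a regular 1D or 2D grid over CV space,
#' anchored so the global minimum is zero.
#'
#' @param axes list of per-dimension axis vectors (CV units), strictly
#'   increasing and evenly spaced.
#' @param values numeric array of free energies matching the axis lengths.
#' @param periodic per-dimension periodicity flags.
#' @param anchor shift values so that `min(values) == 0` (default `TRUE`).
#' @return object of class `fes_grid`.
#' @export
fes_grid <- function(axes, values, periodic = rep(FALSE, length(axes)),
                     anchor = TRUE) {
  if (is.numeric(axes)) axes <- list(axes)
  values <- if (length(axes) == 1) as.numeric(values) else as.matrix(values)
  dims <- vapply(axes, length, integer(1))
  if (!all(dim(as.array(values)) == dims))
    stop("value array shape does not match axes")
  if (any(!is.finite(values))) stop("non-finite free-energy values")
  if (anchor) values <- values - min(values)
  structure(list(axes = axes, values = values,
                 periodic = as.logical(periodic)),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  dims <- vapply(x$axes, length, integer(1))
  cat(sprintf("fes_grid: %s grid, F range 0 .. %.3f kcal/mol\n",
              paste(dims, collapse = " x "), max(x$values)))
  invisible(x)
}

#' Interpolate a free-energy surface at arbitrary points
#'
#' Bilinear (2D) or linear (1D) interpolation.
#'
#' @param f a [fes_grid()].
#' @param at point (vector) or matrix of points.
#' @return numeric vector of free energies.
#' @export
fes_at <- function(f, at) {
  d <- length(f$axes)
  at <- .as_points(at, d)
  locate <- function(ax, x, per) {
    h <- ax[2] - ax[1]
    if (per) {
      L <- length(ax) * h
      x <- ax[1] + (x - ax[1]) %% L
    }
    i <- pmin(pmax(floor((x - ax[1]) / h) + 1, 1), length(ax) - 1)
    w <- (x - ax[i]) / h
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  if (d == 1) {
    l <- locate(f$axes[[1]], at[, 1], f$periodic[1])
    (1 - l$w) * f$values[l$i] + l$w * f$values[l$i + 1]
  } else {
    l1 <- locate(f$axes[[1]], at[, 1], f$periodic[1])
    l2 <- locate(f$axes[[2]], at[, 2], f$periodic[2])
    v <- f$values
    (1 - l1$w) * (1 - l2$w) * v[cbind(l1$i, l2$i)] +
      l1$w * (1 - l2$w) * v[cbind(l1$i + 1, l2$i)] +
      (1 - l1$w) * l2$w * v[cbind(l1$i, l2$i + 1)] +
      l1$w * l2$w * v[cbind(l1$i + 1, l2$i + 1)]
  }
}

## 8-connected (2D) / 2-connected (1D) neighbour indices of a flat cell index
.grid_neighbours <- function(dims, periodic) {
  n1 <- dims[1]
  if (length(dims) == 1) {
    function(id) {
      out <- c(id - 1L, id + 1L)
      if (periodic[1]) out <- ((out - 1L) %% n1) + 1L
      out[out >= 1L & out <= n1]
    }
  } else {
    n2 <- dims[2]
    offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
    offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
    function(id) {
      i <- (id - 1L) %% n1 + 1L
      j <- (id - 1L) %/% n1 + 1L
      ii <- i + offs[, 1]; jj <- j + offs[, 2]
      if (periodic[1]) ii <- ((ii - 1L) %% n1) + 1L
      if (periodic[2]) jj <- ((jj - 1L) %% n2) + 1L
      ok <- ii >= 1L & ii <= n1 & jj >= 1L & jj <= n2
      (ii + (jj - 1L) * n1)[ok]
    }
  }
}

#' Locate free-energy minima on a grid
#'
#' Finds all grid-local minima and filters them by persistence: the depth of
#' a minimum relative to the lowest level at which its basin merges with the
#' basin of a deeper minimum (its lowest escape).  Minima whose depth exceeds
#' `depth_floor` are returned sorted by energy.
#'
#' @param f a [fes_grid()].
#' @param depth_floor minimum basin depth (kcal/mol) for a minimum to be
#'   reported.
#' @return data.frame with grid indices, CV coordinates, `F` and `depth`
#'   (`Inf` for the global minimum); zero rows if none qualify.
#' @export
find_minima <- function(f, depth_floor = 0) {
  v <- as.numeric(f$values)
  dims <- vapply(f$axes, length, integer(1))
  N <- length(v)
  nb <- .grid_neighbours(dims, f$periodic)
  ord <- order(v, seq_len(N))
  rank <- integer(N); rank[ord] <- seq_len(N)
  parent <- seq_len(N)
  root_min <- integer(N)          # representative minimum cell of each set
  uf_find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  is_min <- logical(N)
  depth <- rep(Inf, N)
  done <- logical(N)
  for (c in ord) {
    done[c] <- TRUE
    nbs <- nb(c)
    nbs <- nbs[done[nbs]]
    if (length(nbs) == 0) {
      is_min[c] <- TRUE
      root_min[c] <- c
      next
    }
    roots <- unique(vapply(nbs, uf_find, integer(1)))
    ## attach c to the set whose minimum is deepest
    mins <- root_min[roots]
    main <- roots[which.min(v[mins] + rank[mins] * 0)]
    if (length(roots) > 1) {
      o <- order(v[mins], rank[mins])
      main <- roots[o[1]]
      for (r in roots[o[-1]]) {
        m <- root_min[r]
        depth[m] <- v[c] - v[m]
        parent[r] <- main
      }
    }
    parent[c] <- main
  }
  cells <- which(is_min & depth > depth_floor)
  ## strictness: a minimum must lie strictly below all its neighbours
  ## (ties on a plateau are not minima)
  if (length(cells))
    cells <- cells[vapply(cells, function(c)
      v[c] < min(v[nb(c)]), logical(1))]
  if (length(cells) == 0)
    return(data.frame(F = numeric(0), depth = numeric(0)))
  coords <- .cell_coords(f, cells)
  out <- data.frame(coords, F = v[cells], depth = depth[cells])
  out <- out[order(out$F), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.cell_coords <- function(f, cells) {
  dims <- vapply(f$axes, length, integer(1))
  if (length(dims) == 1) {
    data.frame(i = cells, cv1 = f$axes[[1]][cells])
  } else {
    i <- (cells - 1L) %% dims[1] + 1L
    j <- (cells - 1L) %/% dims[1] + 1L
    data.frame(i = i, j = j, cv1 = f$axes[[1]][i], cv2 = f$axes[[2]][j])
  }
}

## greedy steepest-descent walk on the grid, returns flat cell indices
.descend <- function(v, dims, periodic, start) {
  nb <- .grid_neighbours(dims, periodic)
  path <- start
  cur <- start
  for (iter in seq_len(sum(dims)^2)) {
    nbs <- nb(cur)
    best <- nbs[order(v[nbs], nbs)][1]
    if (v[best] >= v[cur]) break
    cur <- best
    path <- c(path, cur)
  }
  path
}

#' Minimum free-energy path between two minima of a 2D surface
#'
#' The path is the lowest-maximum (minimax) path on the 8-connected grid
#' graph, obtained by a union-find sweep in ascending energy order followed
#' by a deterministic shortest-path search (cumulative energy, ties by cell
#' index) within the sublevel set; the saddle is the path maximum.  The two
#' legs are then smoothed by steepest-descent relaxation from the saddle
#' toward each minimum.
#'
#' @param f a 2D [fes_grid()].
#' @param a,b the two minima: rows of [find_minima()] output, `c(i, j)` grid
#'   indices, or CV coordinates (snapped to the nearest grid cell and
#'   descended to the local minimum).
#' @param labels names for the start/end stationary points (defaults MC/PC).
#' @return object of class `mfep_result`: data.frame (`node`, `i`, `j`,
#'   `cv1`, `cv2`, `F`, `arclength`, `label`) with attributes `saddle`
#'   (node index of the TS) and `level` (saddle free energy).
#' @export
find_mfep <- function(f, a, b, labels = c("MC", "PC")) {
  if (length(f$axes) != 2) stop("find_mfep requires a 2D fes_grid")
  dims <- vapply(f$axes, length, integer(1))
  v <- f$values
  snap <- function(p) {
    if (is.data.frame(p)) return(c(p$i[1], p$j[1]))
    p <- as.numeric(p)
    if (length(p) != 2) stop("minimum must be (i, j) or (cv1, cv2)")
    if (all(p == round(p)) && all(p >= 1) && p[1] <= dims[1] && p[2] <= dims[2] &&
        all(p <= dims)) return(as.integer(p))
    c(which.min(abs(f$axes[[1]] - p[1])), which.min(abs(f$axes[[2]] - p[2])))
  }
  flat <- function(ij) (ij[1] + (ij[2] - 1L) * dims[1])
  unflat <- function(id) c((id - 1L) %% dims[1] + 1L, (id - 1L) %/% dims[1] + 1L)
  ia <- snap(a); ib <- snap(b)
  ## settle onto the local minimum
  ia <- unflat(utils::tail(.descend(v, dims, f$periodic, flat(ia)), 1))
  ib <- unflat(utils::tail(.descend(v, dims, f$periodic, flat(ib)), 1))
  if (all(ia == ib)) stop("the two endpoints descend to the same minimum")

  res <- cpp_mfep(v, f$periodic[1], f$periodic[2],
                  ia[1] - 1L, ia[2] - 1L, ib[1] - 1L, ib[2] - 1L)
  raw <- res$path
  raw_ids <- raw[, 1] + (raw[, 2] - 1L) * dims[1]
  k_sad <- which.max(v[raw_ids] - seq_along(raw_ids) * 0)
  sad <- raw_ids[k_sad]

  smooth_leg <- function(from_k, target, step) {
    ## descend from the raw-path cell adjacent to the saddle; fall back to
    ## the raw segment if greedy descent strands in a different basin
    if (from_k < 1 || from_k > length(raw_ids)) return(integer(0))
    leg <- .descend(v, dims, f$periodic, raw_ids[from_k])
    if (utils::tail(leg, 1) == flat(target)) leg
    else raw_ids[seq(from_k, if (step < 0) 1 else length(raw_ids), by = step)]
  }
  leg_a <- smooth_leg(k_sad - 1, ia, -1L)
  leg_b <- smooth_leg(k_sad + 1, ib, 1L)
  ids <- c(rev(leg_a), sad, leg_b)
  ids <- ids[c(TRUE, diff(ids) != 0)]

  ij <- t(vapply(ids, unflat, integer(2)))
  cv1 <- f$axes[[1]][ij[, 1]]; cv2 <- f$axes[[2]][ij[, 2]]
  seg <- sqrt(diff(cv1)^2 + diff(cv2)^2)
  path <- data.frame(node = seq_along(ids), i = ij[, 1], j = ij[, 2],
                     cv1 = cv1, cv2 = cv2, F = v[ids],
                     arclength = c(0, cumsum(seg)),
                     label = NA_character_)
  path$label[1] <- labels[1]
  path$label[nrow(path)] <- labels[2]
  ts_node <- which.max(path$F)
  path$label[ts_node] <- "TS"
  structure(path, class = c("mfep_result", "data.frame"),
            saddle = ts_node, level = path$F[ts_node])
}

#' @export
print.mfep_result <- function(x, ...) {
  cat(sprintf("mfep_result: %d nodes, saddle F = %.3f kcal/mol at node %d\n",
              nrow(x), attr(x, "level"), attr(x, "saddle")))
  invisible(x)
}

#' Barriers and reaction free energy along a path
#'
#' Computes the activation free energy (path maximum relative to the start),
#' the overall reaction free energy (end relative to start), and reports
#' intermediate basins: contiguous along-path segments whose minimum lies at
#' least `ic_depth` kcal/mol below both flanking path maxima.
#'
#' @param path an [find_mfep()] result, or a numeric free-energy profile.
#' @param ic_depth intermediate-detection depth threshold (kcal/mol).
#' @return list with `dg_act`, `dg_rxn`, `intermediates` (data.frame of
#'   node, F and F relative to the start) and `stationary` (labeled table of
#'   start/TS/intermediates/end).
#' @export
barrier_and_dg <- function(path, ic_depth = 0.5) {
  Fp <- if (is.data.frame(path)) path$F else as.numeric(path)
  n <- length(Fp)
  ts <- which.max(Fp)
  dg_act <- Fp[ts] - Fp[1]
  dg_rxn <- Fp[n] - Fp[1]
  ## interior local minima with flanking maxima at least ic_depth above
  ints <- integer(0)
  if (n >= 3) {
    loc_min <- which(diff(sign(diff(Fp))) > 0) + 1
    for (m in loc_min) {
      left_max <- max(Fp[1:m])
      right_max <- max(Fp[m:n])
      if (left_max - Fp[m] >= ic_depth && right_max - Fp[m] >= ic_depth)
        ints <- c(ints, m)
    }
  }
  intermediates <- data.frame(node = ints, F = Fp[ints],
                              F_rel_start = Fp[ints] - Fp[1])
  stat <- data.frame(
    label = c("start", "TS", if (length(ints)) paste0("IC", seq_along(ints)),
              "end"),
    node = c(1L, ts, ints, n),
    F = c(Fp[1], Fp[ts], Fp[ints], Fp[n]))
  list(dg_act = dg_act, dg_rxn = dg_rxn, intermediates = intermediates,
       stationary = stat)
}

#' One-dimensional projection of a path
#'
#' Free energy against normalised arclength; endpoints and extrema are those
#' of the path itself.
#'
#' @param path an [find_mfep()] result.
#' @return data.frame with `s` (0..1) and `F` (kcal/mol).
#' @export
project_1d <- function(path) {
  stopifnot(is.data.frame(path), all(c("F", "arclength") %in% names(path)))
  L <- max(path$arclength)
  data.frame(s = if (L > 0) path$arclength / L else
               seq(0, 1, length.out = nrow(path)),
             F = path$F)
}

#' Average observables in a tube around a path
#'
#' For each path node, averages each observable over the frames whose CV
#' values lie within the per-CV tolerance box centred on the node.  Empty
#' boxes yield `NA` (reported, never silently interpolated).
#'
#' @param frames data.frame holding CV columns and observable columns.
#' @param path an [find_mfep()] result (CV columns `cv1`, `cv2`, ...).
#' @param tol named numeric vector of per-CV half-widths (same CV names).
#' @param observables columns of `frames` to average (default: all columns
#'   not named like a CV).
#' @return data.frame: `node`, `n` (frames in the box) and one mean per
#'   observable.
#' @export
tube_average <- function(frames, path, tol, observables = NULL) {
  if (any(tol <= 0)) stop("tolerances must be positive")
  cvn <- names(tol)
  if (is.null(cvn)) stop("tol must be named by CV column")
  if (!all(cvn %in% names(frames))) stop("frames lack CV column(s)")
  if (!all(cvn %in% names(path))) stop("path lacks CV column(s)")
  if (is.null(observables))
    observables <- setdiff(names(frames), c(cvn, "frame", "time"))
  out <- data.frame(node = seq_len(nrow(path)), n = 0L)
  for (ob in observables) out[[ob]] <- NA_real_
  for (k in seq_len(nrow(path))) {
    keep <- rep(TRUE, nrow(frames))
    for (cv in cvn)
      keep <- keep & abs(frames[[cv]] - path[[cv]][k]) <= tol[[cv]]
    out$n[k] <- sum(keep)
    if (any(keep))
      for (ob in observables) out[[ob]][k] <- mean(frames[[ob]][keep])
  }
  if (all(out$n == 0))
    stop("no frames fall inside any tolerance box along the path")
  out
}
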