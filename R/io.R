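## PLUMED-style text I/O ------------------------------------------------------
##
## HILLS / COLVAR / gridded-FES files are whitespace tables headed by a
## `#! FIELDS ...` line.  Writers emit full double precision (%.17g) so a
## read-write round trip preserves every value exactly.

.read_fields_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty file: ", path)
  hdr_i <- grep("^#!\\s*FIELDS", lines)
  if (length(hdr_i) == 0) stop("missing '#! FIELDS' header in ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", lines[hdr_i[1]]), "\\s+")[[1]]
  sets <- list()
  set_i <- grep("^#!\\s*SET\\s+", lines)
  for (i in set_i) {
    kv <- strsplit(sub("^#!\\s*SET\\s+", "", lines[i]), "\\s+")[[1]]
    if (length(kv) >= 2) sets[[kv[1]]] <- kv[2]
  }
  data_i <- setdiff(seq_along(lines), grep("^\\s*(#|$)", lines))
  rows <- lapply(data_i, function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != length(fields) || anyNA(v))
      stop("parse error at line ", i, " of ", path,
           ": expected ", length(fields), " numeric fields")
    v
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, length(fields))
  colnames(tab) <- fields
  list(fields = fields, data = tab, sets = sets)
}

.fmt_row <- function(x) paste(sprintf("%.17g", x), collapse = " ")

#' Read a HILLS-style hill log
#'
#' Parses a PLUMED-dialect hill log (`#! FIELDS time <cvs...> <sigma_cvs...>
#' height biasf`) into a [bias_state()], preserving hill order.
#'
#' @param path file path.
#' @param temperature temperature (K) used to convert the bias factor into
#'   the well-tempered parameter in energy units.
#' @param stride,dt deposition bookkeeping; when `NULL`, inferred from the
#'   time column (time assumed in ps).
#' @param periodic,period per-CV periodicity (defaults: none).
#' @return a [bias_state()].
#' @export
read_hills <- function(path, temperature = 300, stride = NULL, dt = NULL,
                       periodic = NULL, period = NULL) {
  tb <- .read_fields_table(path)
  f <- tb$fields
  if (f[1] != "time" || !("height" %in% f))
    stop("not a HILLS file (need 'time' first and a 'height' column): ", path)
  sig_cols <- grep("^sigma_", f, value = TRUE)
  cv_cols <- setdiff(f, c("time", "height", "biasf", sig_cols))
  if (length(cv_cols) == 0 || !identical(paste0("sigma_", cv_cols), sig_cols))
    stop("malformed HILLS header in ", path)
  d <- tb$data
  if (nrow(d) == 0) stop("HILLS file has no hills: ", path)
  if ("biasf" %in% f) {
    gamma <- unname(d[1, "biasf"])
    delta_T <- kB_KCAL * temperature * (gamma - 1)
  } else stop("HILLS file lacks a biasf column: ", path)
  if (is.null(dt)) dt <- 1e-3
  if (is.null(stride)) {
    tt <- d[, "time"]
    stride <- if (nrow(d) > 1) max(1L, round((tt[2] - tt[1]) / dt)) else 100L
  }
  sigma <- as.numeric(d[1, sig_cols])
  if (is.null(periodic)) periodic <- rep(FALSE, length(cv_cols))
  if (is.null(period)) period <- rep(NA_real_, length(cv_cols))
  bias <- bias_state(sigma, delta_T, temperature, stride, dt, periodic, period)
  bias$centers <- unname(d[, cv_cols, drop = FALSE])
  bias$heights <- as.numeric(d[, "height"])
  bias$steps <- as.integer(round(d[, "time"] / dt))
  attr(bias, "cv_names") <- cv_cols
  bias
}

#' Write a HILLS-style hill log
#'
#' @param bias a [bias_state()] with at least one hill.
#' @param path output file.
#' @param cv_names CV column names (default `cv1`, `cv2`, ...).
#' @return the path, invisibly.
#' @export
write_hills <- function(bias, path, cv_names = NULL) {
  d <- length(bias$sigma)
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  hdr <- paste("#! FIELDS time", paste(cv_names, collapse = " "),
               paste(paste0("sigma_", cv_names), collapse = " "),
               "height biasf")
  gamma <- bias_factor(bias)
  rows <- vapply(seq_along(bias$heights), function(k)
    .fmt_row(c(bias$steps[k] * bias$dt, bias$centers[k, ], bias$sigma,
               bias$heights[k], gamma)), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write COLVAR-style CV time series
#'
#' Whitespace tables with a `#! FIELDS time <cv...>` header.
#'
#' @param path file path.
#' @return data.frame with a `time` column plus one column per CV.
#' @export
read_colvar <- function(path) {
  tb <- .read_fields_table(path)
  if (tb$fields[1] != "time") stop("not a COLVAR file (no time column): ", path)
  as.data.frame(tb$data)
}

#' @rdname read_colvar
#' @param series data.frame whose first column is time (ps).
#' @export
write_colvar <- function(series, path) {
  stopifnot(is.data.frame(series))
  hdr <- paste("#! FIELDS", paste(names(series), collapse = " "))
  rows <- vapply(seq_len(nrow(series)), function(k)
    .fmt_row(as.numeric(series[k, ])), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read / write a gridded free-energy surface
#'
#' PLUMED-style gridded text: `#! FIELDS <cv...> free`, `#! SET` axis
#' metadata lines, and one row per grid point with the first CV varying
#' fastest.
#'
#' @param path file path.
#' @return a [fes_grid()].
#' @export
read_fes_grid <- function(path) {
  tb <- .read_fields_table(path)
  cvs <- setdiff(tb$fields, "free")
  axes <- list(); periodic <- logical(0)
  for (cv in cvs) {
    mn <- as.numeric(tb$sets[[paste0("min_", cv)]])
    mx <- as.numeric(tb$sets[[paste0("max_", cv)]])
    nb <- as.integer(tb$sets[[paste0("nbins_", cv)]])
    if (anyNA(c(mn, mx, nb))) stop("missing axis metadata for ", cv, " in ", path)
    axes[[cv]] <- seq(mn, mx, length.out = nb)
    periodic <- c(periodic, identical(tb$sets[[paste0("periodic_", cv)]], "true"))
  }
  vals <- array(tb$data[, "free"],
                dim = unname(vapply(axes, length, integer(1))))
  fes_grid(unname(axes), vals, periodic = periodic, anchor = FALSE)
}

#' @rdname read_fes_grid
#' @param f a [fes_grid()].
#' @param cv_names axis names (default `cv1`, `cv2`, ...).
#' @export
write_fes_grid <- function(f, path, cv_names = NULL) {
  d <- length(f$axes)
  if (is.null(cv_names)) cv_names <- paste0("cv", seq_len(d))
  hdr <- paste("#! FIELDS", paste(cv_names, collapse = " "), "free")
  sets <- character(0)
  for (i in seq_len(d)) {
    ax <- f$axes[[i]]
    sets <- c(sets,
              sprintf("#! SET min_%s %.17g", cv_names[i], ax[1]),
              sprintf("#! SET max_%s %.17g", cv_names[i], ax[length(ax)]),
              sprintf("#! SET nbins_%s %d", cv_names[i], length(ax)),
              sprintf("#! SET periodic_%s %s", cv_names[i],
                      if (f$periodic[i]) "true" else "false"))
  }
  pts <- as.matrix(expand.grid(f$axes))
  vals <- as.numeric(f$values)
  rows <- vapply(seq_len(nrow(pts)), function(k)
    .fmt_row(c(pts[k, ], vals[k])), character(1))
  writeLines(c(hdr, sets, rows), path)
  invisible(path)
}

## Ring-coordinate input ------------------------------------------------------

#' Read six-membered-ring geometries from an XYZ or PDB trajectory
#'
#' For XYZ (xmol) files the six ring atoms are selected per frame either by
#' 1-based atom indices or by atom-name match; for PDB files (read via
#' bio3d, including multi-model files) selection is by atom name.  Atoms are
#' returned in the order given, which must follow the package's O5, C1...C5
#' convention (use [reorder_ring()] otherwise).
#'
#' @param path file path (`.xyz` or `.pdb`).
#' @param selection six atom indices (XYZ) or six atom names (XYZ/PDB).
#' @param format `"auto"`, `"xyz"` or `"pdb"`.
#' @return list of [ring_geometry()] objects, one per frame.
#' @export
read_ring_frames <- function(path, selection = .RING_ATOMS, format = "auto") {
  if (format == "auto")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  if (length(selection) != 6) stop("selection must name exactly six ring atoms")
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    nm <- trimws(pdb$atom$elety)
    idx <- match(selection, nm)
    if (anyNA(idx))
      stop("atom(s) not found in PDB: ",
           paste(selection[is.na(idx)], collapse = ", "))
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    lapply(seq_len(nrow(xyz)), function(fr) {
      co <- matrix(xyz[fr, ], ncol = 3, byrow = TRUE)[idx, , drop = FALSE]
      ring_geometry(co, selection)
    })
  } else {
    lines <- readLines(path)
    frames <- list()
    i <- 1L; fr <- 0L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n)) stop("bad XYZ atom count at line ", i, " of ", path)
      fr <- fr + 1L
      block <- lines[(i + 2L):(i + 1L + n)]
      parts <- strsplit(trimws(block), "\\s+")
      names_fr <- vapply(parts, `[[`, character(1), 1)
      co <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
      idx <- if (is.numeric(selection)) as.integer(selection)
             else match(selection, names_fr)
      if (anyNA(idx) || any(idx < 1 | idx > n)) {
        missing <- if (is.numeric(selection)) selection[idx < 1 | idx > n | is.na(idx)]
                   else selection[is.na(idx)]
        stop("frame ", fr, ": ring atom(s) not found: ",
             paste(missing, collapse = ", "))
      }
      sel_names <- if (is.numeric(selection)) names_fr[idx] else selection
      frames[[fr]] <- ring_geometry(co[idx, , drop = FALSE], sel_names)
      i <- i + 2L + n
    }
    if (length(frames) == 0) stop("no frames in ", path)
    frames
  }
}

#' Write ring geometries as a multi-frame XYZ file
#'
#' @param geometries a [ring_geometry()] or list of them.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ring_xyz <- function(geometries, path) {
  if (inherits(geometries, "ring_geometry")) geometries <- list(geometries)
  out <- unlist(lapply(seq_along(geometries), function(fr) {
    g <- geometries[[fr]]
    c("6", sprintf("frame %d", fr),
      vapply(1:6, function(k)
        sprintf("%s %.17g %.17g %.17g", g$atoms[k], g$coords[k, 1],
                g$coords[k, 2], g$coords[k, 3]), character(1)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Puckering table for a trajectory of ring geometries
#'
#' Convenience wrapper producing the tidy table emitted by the `pucker` CLI
#' subcommand: one row per frame with Q, theta, phi and the nearest canonical
#' conformer.
#'
#' @param frames list of [ring_geometry()] objects.
#' @return data.frame with `frame`, `Q`, `theta`, `phi`, `conformer`.
#' @export
pucker_table <- function(frames) {
  if (inherits(frames, "ring_geometry")) frames <- list(frames)
  if (length(frames) == 0) stop("no frames")
  rows <- lapply(seq_along(frames), function(k) {
    p <- cremer_pople(frames[[k]])
    data.frame(frame = k, Q = p$Q, theta = p$theta, phi = p$phi,
               conformer = classify_conformer(p)$name)
  })
  do.call(rbind, rows)
}
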