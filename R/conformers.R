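## Canonical pyranose conformer table ----------------------------------------
##
## The 38 canonical conformers of a six-membered (pyranose) ring, located on
## the Cremer-Pople sphere: 2 chairs at the poles, 6 boats and 6 twist-boats
## (skew-boats) on the equator, 12 half-chairs at theta = 50.8/129.2 deg and
## 12 envelopes at theta = 54.7/125.3 deg.  Ring atoms are taken in the order
## O5, C1, C2, C3, C4, C5 with O5 as Cremer-Pople atom 1 (documented package
## convention; conformer names depend on it).
##
## The table is generated, not transcribed: each conformer is written as its
## ideal out-of-plane displacement pattern (which atoms lie above/below the
## ring plane) and projected onto the puckering modes.  A plain-text copy is
## shipped in inst/extdata for interoperability.

.RING_ATOMS <- c("O5", "C1", "C2", "C3", "C4", "C5")
## naming token per ring position: O5 -> "O", C1..C5 -> "1".."5"
.ATOM_TOKEN <- c("O", "1", "2", "3", "4", "5")

## project a 6-vector of out-of-plane displacements onto (q2, phi2, q3)
.project_pattern <- function(z) {
  j <- 0:5
  ang2 <- 2 * pi * 2 * j / 6
  q2c <- sqrt(1 / 3) * sum(z * cos(ang2))
  q2s <- -sqrt(1 / 3) * sum(z * sin(ang2))
  q3 <- sqrt(1 / 6) * sum(z * (-1)^j)
  q2 <- sqrt(q2c^2 + q2s^2)
  phi <- atan2(q2s, q2c) * 180 / pi
  if (q2 < 1e-12) phi <- 0
  theta <- atan2(q2, q3) * 180 / pi
  list(theta = theta, phi = phi %% 360)
}

.conformer_patterns <- function() {
  tok <- .ATOM_TOKEN
  pat <- list()
  add <- function(name, class, z) pat[[length(pat) + 1]] <<-
    list(name = name, class = class, z = z)

  ## chairs: alternating displacement, 4C1 has O5/C2/C4 above
  add("4C1", "C", rep(c(1, -1), 3))
  add("1C4", "C", rep(c(-1, 1), 3))

  ## equator: boats at even multiples of 60 deg, twist-boats between them;
  ## pattern is the pure q2 mode cos(phi2 + 120 deg * (j-1))
  equator_names <- c("3,OB", "3S1", "B1,4", "5S1", "2,5B", "2SO",
                     "B3,O", "1S3", "1,4B", "1S5", "B2,5", "OS2")
  for (m in seq_along(equator_names)) {
    phi2 <- (m - 1) * 30 * pi / 180
    z <- cos(phi2 + 2 * pi * 2 * (0:5) / 6)
    add(equator_names[m], ifelse(m %% 2 == 1, "B", "S"), z)
  }

  ## envelopes: a single atom above (kE) or below (Ek) the plane of the rest
  for (k in 1:6) {
    zu <- numeric(6); zu[k] <- 1
    add(paste0(tok[k], "E"), "E", zu)
    add(paste0("E", tok[k]), "E", -zu)
  }

  ## half-chairs: two adjacent atoms displaced to opposite sides (x above,
  ## y below -> xHy)
  for (k in 1:6) {
    k2 <- if (k == 6) 1 else k + 1
    z <- numeric(6); z[k] <- 1; z[k2] <- -1
    add(paste0(tok[k], "H", tok[k2]), "H", z)
    add(paste0(tok[k2], "H", tok[k]), "H", -z)
  }
  pat
}

.build_conformer_table <- function() {
  pat <- .conformer_patterns()
  df <- do.call(rbind, lapply(pat, function(p) {
    pr <- .project_pattern(p$z)
    data.frame(name = p$name, class = p$class,
               theta = pr$theta, phi = pr$phi, stringsAsFactors = FALSE)
  }))
  ## snap latitudes to their exact class values (projection is already exact
  ## up to floating point; snapping makes the shipped table tidy)
  canon <- c(0, 50.76848, 54.73561, 90, 125.26439, 129.23152, 180)
  df$theta <- vapply(df$theta, function(t) canon[which.min(abs(canon - t))], numeric(1))
  df$phi <- round(df$phi, 6) %% 360
  rownames(df) <- NULL
  df
}

.conformer_env <- new.env(parent = emptyenv())

#' Canonical pyranose conformer table
#'
#' Positions of the 38 canonical six-membered-ring conformers on the
#' Cremer-Pople sphere (degrees), under the O5, C1...C5 atom-ordering
#' convention with O5 as atom 1.  Chairs sit at the poles (`4C1` at
#' theta = 0, `1C4` at theta = 180), boats and twist-boats on the equator at
#' 30-degree intervals, half-chairs at theta = 50.8/129.2 and envelopes at
#' theta = 54.7/125.3.
#'
#' @return data.frame with columns `name`, `class` (C/B/S/E/H), `theta`,
#'   `phi` (degrees).
#' @export
conformer_table <- function() {
  if (is.null(.conformer_env$table)) .conformer_env$table <- .build_conformer_table()
  .conformer_env$table
}

#' Write the canonical conformer table as plain text
#'
#' @param path output file (tab-separated).
#' @return the path, invisibly.
#' @export
write_conformer_table <- function(path) {
  utils::write.table(conformer_table(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.lookup_conformer <- function(name) {
  tab <- conformer_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown conformer label: ", name)
  tab[i, ]
}
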