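# shared helpers: rigid motions and small reference grids

rotate_translate <- function(coords, angle, axis, shift) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  coords %*% t(R) + matrix(shift, nrow(coords), 3, byrow = TRUE)
}

# planar regular hexagon in the package's (clockwise) winding
planar_hexagon <- function(a = 1.49) {
  psi <- -2 * pi * (0:5) / 6
  cbind(a * cos(psi), a * sin(psi), 0)
}

# exhaustive minimax level between two cells of a small grid by depth-first
# enumeration of simple 8-connected paths with pruning
brute_minimax <- function(v, start, target) {
  n1 <- nrow(v); n2 <- ncol(v)
  best <- Inf
  visited <- matrix(FALSE, n1, n2)
  rec <- function(i, j, mx) {
    mx <- max(mx, v[i, j])
    if (mx >= best) return(invisible())
    if (i == target[1] && j == target[2]) { best <<- mx; return(invisible()) }
    visited[i, j] <<- TRUE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > n1 || jj < 1 || jj > n2 || visited[ii, jj]) next
      rec(ii, jj, mx)
    }
    visited[i, j] <<- FALSE
  }
  rec(start[1], start[2], -Inf)
  best
}

kT300 <- 0.0019872041 * 300
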