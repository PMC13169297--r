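#' Catalytically relevant distance set
#'
#' Named interatomic distances (Angstrom) around the beta-elimination active
#' site: `d1` = d(H5-C5), `d2` = d(H5-N(His)), `d3` = d(H5-O4) and `d4` =
#' d(C4-O4), the glycosidic bond; optionally `dC5C6` and `dC4C5`.
#'
#' @param d1,d2,d3,d4 distances in Angstrom (positive).
#' @param ... further named distances (e.g. `dC5C6`, `dC4C5`).
#' @return object of class `distance_set` (a named list).
#' @export
distance_set <- function(d1 = NULL, d2 = NULL, d3 = NULL, d4 = NULL, ...) {
  d <- c(list(d1 = d1, d2 = d2, d3 = d3, d4 = d4), list(...))
  d <- d[!vapply(d, is.null, logical(1))]
  bad <- vapply(d, function(x) any(!is.finite(x)) || any(x <= 0), logical(1))
  if (any(bad)) stop("non-positive distance(s): ", paste(names(d)[bad], collapse = ", "))
  structure(d, class = "distance_set")
}

.need_dist <- function(d, which) {
  miss <- setdiff(which, names(d))
  if (length(miss)) stop("missing distance(s): ", paste(miss, collapse = ", "))
}

#' Proton-abstraction collective variable CV1 = d1 - d2
#'
#' Antisymmetric combination describing transfer of the ring proton H5 from
#' C5 to the catalytic histidine nitrogen.
#'
#' @param d a [distance_set()] (or named list with `d1`, `d2`).
#' @return CV1 in Angstrom.
#' @export
eval_cv1 <- function(d) {
  .need_dist(d, c("d1", "d2"))
  d$d1 - d$d2
}

#' Glycosidic-bond-cleavage collective variable CV2 = d2 - d3 + d4
#'
#' Couples the His-to-O4 proton relay (d2 - d3) with glycosidic bond
#' cleavage (d4).
#'
#' @param d a [distance_set()] (or named list with `d2`, `d3`, `d4`).
#' @return CV2 in Angstrom.
#' @export
eval_cv2 <- function(d) {
  .need_dist(d, c("d2", "d3", "d4"))
  d$d2 - d$d3 + d$d4
}

#' Collective-variable definition
#'
#' A named, signed linear combination of distances (unit Angstrom), or an
#' angular puckering coordinate flagged periodic.
#'
#' @param name CV name.
#' @param terms named numeric vector of coefficients over distance names,
#'   e.g. `c(d1 = 1, d2 = -1)`.
#' @param unit `"angstrom"` or `"degree"`/`"radian"`.
#' @param periodic logical.
#' @return object of class `cv_definition`.
#' @export
cv_definition <- function(name, terms, unit = "angstrom", periodic = FALSE) {
  if (any(terms == 0)) stop("zero coefficient in CV definition")
  structure(list(name = name, terms = terms, unit = unit, periodic = periodic),
            class = "cv_definition")
}

#' The two reaction collective variables
#'
#' `cv1_definition()` is d1 - d2 (proton abstraction); `cv2_definition()` is
#' d2 - d3 + d4 (proton relay plus glycosidic cleavage).
#' @return a [cv_definition()].
#' @export
cv1_definition <- function() cv_definition("cv1", c(d1 = 1, d2 = -1))

#' @rdname cv1_definition
#' @export
cv2_definition <- function() cv_definition("cv2", c(d2 = 1, d3 = -1, d4 = 1))

#' Evaluate collective variables over a trajectory of distance frames
#'
#' @param traj a data.frame with one row per frame and one column per named
#'   distance, or a list of [distance_set()] frames.
#' @param cvs list of [cv_definition()] objects.
#' @return data.frame with `frame` plus one column per CV; never contains NA.
#' @export
evaluate_cvs <- function(traj, cvs = list(cv1_definition(), cv2_definition())) {
  if (inherits(traj, "distance_set")) traj <- list(traj)
  if (is.list(traj) && !is.data.frame(traj))
    traj <- do.call(rbind, lapply(traj, function(d) as.data.frame(unclass(d))))
  if (!is.data.frame(traj) || nrow(traj) == 0) stop("empty trajectory")
  out <- data.frame(frame = seq_len(nrow(traj)))
  for (cv in cvs) {
    need <- names(cv$terms)
    miss <- setdiff(need, names(traj))
    if (length(miss))
      stop("trajectory lacks distance(s) ", paste(miss, collapse = ", "),
           " required by CV '", cv$name, "'")
    bad <- which(!stats::complete.cases(traj[need]))
    if (length(bad))
      stop("frame ", bad[1], ": missing value in distance(s) ",
           paste(need[is.na(unlist(traj[bad[1], need]))], collapse = ", "))
    out[[cv$name]] <- as.numeric(as.matrix(traj[need]) %*% cv$terms)
  }
  out
}
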