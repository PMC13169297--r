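#' Assign a conformational itinerary along an ordered puckering series
#'
#' Classifies every frame against the canonical conformer sphere, collapses
#' consecutive duplicates into the itinerary sequence, and reports the
#' conformer at marked reaction stages (e.g. MC/TS/PC read off a minimum
#' free-energy path).
#'
#' @param series ordered puckering states: a data.frame with `theta` and
#'   `phi` columns (degrees), or a list of [cremer_pople()] results.
#' @param stages optional named integer vector of frame indices, e.g.
#'   `c(MC = 1, TS = 12, PC = 50)`.
#' @return object of class `itinerary_result`: list with `labels` (per
#'   frame), `collapsed` (duplicates merged), `stages` (named stage labels
#'   or `NULL`).
#' @export
assign_itinerary <- function(series, stages = NULL) {
  if (is.data.frame(series)) {
    if (nrow(series) == 0) stop("empty puckering series")
    tp <- series[, c("theta", "phi")]
  } else if (is.list(series) && length(series) > 0) {
    tp <- data.frame(theta = vapply(series, `[[`, numeric(1), "theta"),
                     phi = vapply(series, `[[`, numeric(1), "phi"))
  } else stop("empty puckering series")
  labels <- vapply(seq_len(nrow(tp)), function(k)
    classify_conformer(c(tp$theta[k], tp$phi[k]))$name, character(1))
  collapsed <- labels[c(TRUE, labels[-1] != labels[-length(labels)])]
  stage_labels <- NULL
  if (!is.null(stages)) {
    if (is.null(names(stages))) stop("stages must be a named index vector")
    if (any(stages < 1 | stages > length(labels)))
      stop("stage index outside the series")
    stage_labels <- stats::setNames(labels[stages], names(stages))
  }
  structure(list(labels = labels, collapsed = collapsed,
                 stages = stage_labels),
            class = "itinerary_result")
}

#' Arrow-joined itinerary string
#'
#' @param x an [assign_itinerary()] result.
#' @param stages use the stage labels (default when present) rather than the
#'   collapsed sequence.
#' @return character scalar like `"1C4 -> 1C4 -> 1H2"`.
#' @export
format_itinerary <- function(x, stages = !is.null(x$stages)) {
  seqs <- if (stages) {
    if (is.null(x$stages)) stop("no stage markers recorded")
    x$stages
  } else x$collapsed
  paste(seqs, collapse = " -> ")
}

#' @export
print.itinerary_result <- function(x, ...) {
  cat("itinerary:", format_itinerary(x, stages = FALSE), "\n")
  if (!is.null(x$stages))
    cat("stages:   ",
        paste(sprintf("%s = %s", names(x$stages), x$stages), collapse = ", "),
        "\n")
  invisible(x)
}

#' Classify a polysaccharide-lyase family by its product-ring conformer
#'
#' Tests whether a product conformer belongs to the eight canonical
#' conformers compatible with the C3-C4-C5-O5 planarity restriction of the
#' unsaturated product (the continuous pathway
#' theta = 90 + 39 cos(phi - 270) on the Cremer-Pople surface), and reports
#' its position on that pathway.
#'
#' @param product conformer name (e.g. `"1H2"`) or a [classify_conformer()]
#'   row.
#' @return list with `name`, `on_path` (logical), `phi`/`theta` (canonical
#'   position, degrees) and `path_distance` (degrees to the pathway curve).
#' @export
classify_pl_family <- function(product) {
  name <- if (is.data.frame(product)) product$name[1] else as.character(product)
  row <- .lookup_conformer(name)      # errors on unknown labels
  list(name = name,
       on_path = name %in% pl_path_conformers(),
       phi = row$phi, theta = row$theta,
       path_distance = distance_to_pl_path(c(row$theta, row$phi)))
}
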