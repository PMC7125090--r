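## Input validation and auxiliary-source conflict resolution.

#' Validate and normalise the input tables
#'
#' Checks the schemas of the detection, cell and auxiliary occurrence tables:
#' key uniqueness, value ranges, unit sanity and consistency between
#' detections and auxiliary information. Conflicting auxiliary sources for
#' the same (species, cell) are resolved in favour of presence (absence
#' information is treated conservatively because it is hard to verify), with
#' a warning; a detection in a cell whose auxiliary state is absence is an
#' error, because the priority rule applies to conflicts between auxiliary
#' sources, not to conflicts with direct observations.
#'
#' @param detections Data frame (species, cell, plot, y, area in m^2).
#' @param cells Data frame (cell, A in km^2, x1, x2).
#' @param aux Data frame (species, cell, z, source) or NULL.
#' @return List with the normalised tables; the `aux` element has one row
#'   per (species, cell) with the resolved state.
#' @export
validate_inputs <- function(detections, cells, aux = NULL) {
  need <- function(df, cols, what)
    if (!all(cols %in% names(df)))
      stop(what, " must have columns: ", paste(cols, collapse = ", "))
  need(detections, c("species", "cell", "plot", "y", "area"), "detections")
  need(cells, c("cell", "A", "x1", "x2"), "cells")
  if (anyDuplicated(cells$cell)) stop("duplicate cell ids in the cell table")
  if (any(!is.finite(cells$A)) || any(cells$A < 0))
    stop("habitat areas must be finite and >= 0")
  key <- paste(detections$species, detections$cell, detections$plot)
  if (anyDuplicated(key)) stop("duplicate (species, cell, plot) detection records")
  if (any(!detections$y %in% c(0, 1))) stop("y must be 0 or 1")
  if (any(!is.finite(detections$area)) || any(detections$area <= 0))
    stop("plot areas must be finite and > 0 (m^2)")
  mx <- c(mean(cells$x1), mean(cells$x2))
  vx <- c(var(cells$x1), var(cells$x2))
  if (nrow(cells) > 2 && (any(abs(mx) > 0.3) || any(abs(vx - 1) > 0.7)))
    warning("cell covariates do not look standardized (mean 0, variance 1)")

  if (is.null(aux))
    aux <- data.frame(species = integer(0), cell = integer(0),
                      z = integer(0), source = character(0))
  if (nrow(aux)) {
    need(aux, c("species", "cell", "z"), "aux")
    if (is.null(aux$source))
      aux$source <- ifelse(aux$z == 1, "presence-source", "absence-source")
    if (any(!aux$z %in% c(0, 1))) stop("aux z must be 0 or 1")
    k <- paste(aux$species, aux$cell)
    if (anyDuplicated(k)) {
      zmax <- tapply(aux$z, k, max)
      zmin <- tapply(aux$z, k, min)
      if (any(zmax != zmin))
        warning(sum(zmax != zmin),
                " (species, cell) pair(s) had conflicting presence and absence sources; presence prioritised")
      first <- !duplicated(k)
      res <- aux[first, , drop = FALSE]
      res$z <- as.integer(zmax[paste(res$species, res$cell)])
      res$source[res$z == 1] <- "presence-source"
      aux <- res
    }
    rownames(aux) <- NULL
  }
  list(detections = detections, cells = cells, aux = aux)
}
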