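#' Build a discrete state space around a trap array
#'
#' Constructs the regular lattice of potential activity-center locations
#' ("state space") used to integrate the spatial capture-recapture
#' likelihood: cell centers on a square lattice anchored at the minimum
#' trap coordinate, keeping every cell whose center lies within `buffer`
#' of at least one trap (the union of trap-centered disks). The
#' construction is deterministic given the trap coordinates.
#'
#' @param traps data frame with numeric `x`, `y` in projected meters.
#' @param buffer buffer width in meters (default 15000).
#' @param cell cell side in meters (default 2500).
#' @return An object of class `state_space`: data frame of cell centers
#'   `x`, `y` with attributes `cell`, `buffer`, `area_km2`
#'   (`cell count * cell^2 / 1e6`).
#' @export
build_state_space <- function(traps, buffer = 15000, cell = 2500) {
  stopifnot(is.data.frame(traps), nrow(traps) >= 1)
  x <- traps$x; y <- traps$y
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("trap coordinates must be finite")
  stop_if_not_scalar(buffer, "buffer"); stop_if_not_scalar(cell, "cell")
  if (buffer <= 0 || cell <= 0) stop("buffer and cell must be positive")
  kx <- seq(floor(-buffer / cell) - 1L,
            ceiling((max(x) - min(x) + buffer) / cell) + 1L)
  ky <- seq(floor(-buffer / cell) - 1L,
            ceiling((max(y) - min(y) + buffer) / cell) + 1L)
  centers <- expand.grid(x = min(x) + kx * cell, y = min(y) + ky * cell)
  d2 <- outer(centers$x, x, "-")^2 + outer(centers$y, y, "-")^2
  keep <- apply(d2, 1, min) <= buffer^2
  grid <- centers[keep, , drop = FALSE]
  rownames(grid) <- NULL
  structure(grid, cell = cell, buffer = buffer,
            area_km2 = nrow(grid) * cell^2 / 1e6,
            class = c("state_space", "data.frame"))
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", nrow(x), "cells of",
      attr(x, "cell"), "m;", "buffer", attr(x, "buffer"), "m; area",
      round(attr(x, "area_km2"), 1), "km^2\n")
  invisible(x)
}

#' @rdname build_state_space
#' @param grid a `state_space`.
#' @export
state_space_area <- function(grid) attr(grid, "area_km2")
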