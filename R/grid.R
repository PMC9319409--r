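#' Lattice specification for field sampling
#'
#' Points are ordered x-fastest with 0-based indices: point `k` has indices
#' `ix = k %% nx`, `iy = (k %/% nx) %% ny`, `iz = k %/% (nx*ny)` and position
#' `origin + spacing * (ix, iy, iz)`.
#'
#' @param origin 3-vector, Angstrom.
#' @param spacing lattice constant, Angstrom.
#' @param npoints integer 3-vector of points per axis.
#' @return object of class `field_grid`.
#' @export
field_grid <- function(origin, spacing, npoints) {
  stopifnot(length(origin) == 3, length(npoints) == 3,
            spacing > 0, all(npoints >= 1))
  structure(list(origin = as.numeric(origin),
                 spacing = as.numeric(spacing),
                 npoints = as.integer(npoints)),
            class = "field_grid")
}

#' @export
print.field_grid <- function(x, ...) {
  cat(sprintf("<field_grid> %d x %d x %d points, spacing %.2f A, origin (%.1f, %.1f, %.1f)\n",
              x$npoints[1], x$npoints[2], x$npoints[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Number of lattice points
#' @param grid a `field_grid`.
#' @export
n_grid_points <- function(grid) prod(grid$npoints)

#' Cartesian coordinates of every lattice point
#'
#' @param grid a `field_grid`.
#' @return matrix (n points x 3), x-fastest ordering.
#' @export
grid_points <- function(grid) {
  ix <- seq_len(grid$npoints[1]) - 1L
  iy <- seq_len(grid$npoints[2]) - 1L
  iz <- seq_len(grid$npoints[3]) - 1L
  idx <- expand.grid(ix = ix, iy = iy, iz = iz)  # ix varies fastest
  cbind(grid$origin[1] + grid$spacing * idx$ix,
        grid$origin[2] + grid$spacing * idx$iy,
        grid$origin[3] + grid$spacing * idx$iz)
}

#' Build a lattice enclosing a molecule set
#'
#' The region spans the union of atom positions plus `margin` on every side,
#' at the requested spacing. The origin is anchored at the integer-Angstrom
#' floor of (min corner - margin), so the same molecules always yield the same
#' grid and grids for grown series are reproducible.
#'
#' @param mols list of `aligned_molecule` sharing one alignment frame.
#' @param spacing lattice constant in Angstrom (default 2.0).
#' @param margin clearance beyond the bounding box, Angstrom (default 4.0).
#' @return a `field_grid`.
#' @export
build_grid <- function(mols, spacing = 2.0, margin = 4.0) {
  if (inherits(mols, "aligned_molecule")) mols <- list(mols)
  if (length(mols) == 0) stop("cannot build a grid from an empty molecule list")
  xyz <- do.call(rbind, lapply(mols, function(m) {
    as.matrix(m$atoms[, c("x", "y", "z")])
  }))
  lo <- floor(apply(xyz, 2, min) - margin)
  hi <- apply(xyz, 2, max) + margin
  npt <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  field_grid(origin = lo, spacing = spacing, npoints = npt)
}
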