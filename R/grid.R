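#' Regular 3D dose-grid geometry
#'
#' A `grid_spec` describes a regular, axis-aligned 3D voxel grid: voxel counts
#' per axis, voxel spacing in mm, and the mm coordinates of the centre of voxel
#' `(1,1,1)`. Axes are ordered LR (left-right), AP (anterior-posterior),
#' CC (cranio-caudal).
#'
#' @param shape integer voxel counts per axis (length 3, or a scalar recycled).
#' @param spacing voxel spacing in mm per axis (length 3 or scalar). Must be
#'   positive.
#' @param origin mm coordinates of the centre of the first voxel (length 3 or
#'   scalar).
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(41, 2, -40)
#' grid_extent(g)
#' @export
grid_spec <- function(shape, spacing, origin) {
  shape <- as.integer(rep_len(shape, 3L))
  spacing <- as.numeric(rep_len(spacing, 3L))
  origin <- as.numeric(rep_len(origin, 3L))
  if (any(shape < 1L)) stop("grid_spec: 'shape' must be >= 1 on every axis")
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid_spec: 'spacing' must be positive and finite on every axis")
  }
  if (any(!is.finite(origin))) stop("grid_spec: 'origin' must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(format(x$spacing), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' Voxel-centre coordinates along each axis
#'
#' @param grid a [grid_spec()].
#' @return A list of three numeric vectors (mm), one per axis.
#' @export
axis_coords <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lapply(1:3, function(a) grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a])
}

#' Extent of a grid (voxel-centre bounding box)
#'
#' @param grid a [grid_spec()].
#' @return A 2 x 3 matrix: rows `min`/`max`, columns the three axes (mm).
#' @export
grid_extent <- function(grid) {
  cc <- axis_coords(grid)
  m <- vapply(cc, range, numeric(2))
  rownames(m) <- c("min", "max")
  colnames(m) <- c("LR", "AP", "CC")
  m
}

#' Default study grid
#'
#' Builds a symmetric, isotropic grid centred on the phantom that is guaranteed
#' to contain the PTV plus the full shift-scan range plus one penumbra width on
#' every side, with a voxel centre exactly at the phantom centre (odd voxel
#' counts). The default 2 mm spacing matches a typical SBRT CT reconstruction;
#' 1 mm is available for convergence checks.
#'
#' @param spacing isotropic voxel spacing in mm (default 2).
#' @param phantom a [phantom_spec()].
#' @param criterion a [coverage_criterion()]; its `shift_range` enters the
#'   required extent.
#' @param penumbra_width penumbra width (mm) that must fit beyond the scan
#'   range (default 8, the widest of the default density sweep).
#' @return A [grid_spec()].
#' @export
default_grid <- function(spacing = 2, phantom = phantom_spec(),
                         criterion = coverage_criterion(),
                         penumbra_width = 8) {
  ptv_outer <- phantom$gtv_radius + phantom$ctv_margin + max(phantom$ptv_margin)
  half <- ptv_outer + criterion$shift_range + penumbra_width
  n_half <- ceiling(half / spacing)
  grid_spec(2L * n_half + 1L, spacing, -n_half * spacing)
}

# Squared distance of every voxel centre from `center`, as a 3D array.
# Built from per-axis outer sums; cheap enough to recompute per call site
# that needs a different centre.
radial_dist2 <- function(grid, center = c(0, 0, 0)) {
  cc <- axis_coords(grid)
  dx2 <- (cc[[1]] - center[1])^2
  dy2 <- (cc[[2]] - center[2])^2
  dz2 <- (cc[[3]] - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+")
}
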