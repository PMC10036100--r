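#' Spherical lung-phantom specification
#'
#' Describes the study geometry: a water-equivalent spherical tumour (GTV) in
#' lung, with CTV = GTV + `ctv_margin` and PTV = CTV + `ptv_margin`. Defaults
#' reproduce the reference setup: a 10 mm GTV radius, zero CTV margin, a 5 mm
#' PTV margin in LR/AP/CC, tumour density 1.0 g/cm3 and lung density
#' 0.3 g/cm3.
#'
#' @param gtv_radius GTV radius in mm (> 0).
#' @param ctv_margin CTV expansion in mm (>= 0).
#' @param ptv_margin PTV expansion in mm per axis (length 3 or scalar, > 0).
#' @param tumor_density tumour electron density in g/cm3, in (0, 2].
#' @param lung_density lung electron density in g/cm3, in (0, 2].
#' @return An object of class `phantom_spec`.
#' @examples
#' phantom_spec()
#' @export
phantom_spec <- function(gtv_radius = 10, ctv_margin = 0, ptv_margin = 5,
                         tumor_density = 1.0, lung_density = 0.3) {
  ptv_margin <- as.numeric(rep_len(ptv_margin, 3L))
  stopifnot(is.finite(gtv_radius), gtv_radius > 0,
            is.finite(ctv_margin), ctv_margin >= 0,
            all(is.finite(ptv_margin)), all(ptv_margin > 0))
  for (d in c(tumor_density, lung_density)) {
    if (!is.finite(d) || d <= 0 || d > 2) {
      stop("phantom_spec: densities must lie in (0, 2] g/cm3")
    }
  }
  structure(list(gtv_radius = gtv_radius, ctv_margin = ctv_margin,
                 ptv_margin = ptv_margin, tumor_density = tumor_density,
                 lung_density = lung_density),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "phantom_spec: GTV r=%g mm, CTV margin %g mm, PTV margin (%s) mm, densities tumour %g / lung %g g/cm3\n",
    x$gtv_radius, x$ctv_margin, paste(x$ptv_margin, collapse = ", "),
    x$tumor_density, x$lung_density))
  invisible(x)
}

#' Spherical structure (GTV/CTV/PTV)
#'
#' @param center mm coordinates of the sphere centre (length 3).
#' @param radius sphere radius in mm (> 0).
#' @param label one of `"GTV"`, `"CTV"`, `"PTV"`.
#' @return An object of class `sphere_structure`.
#' @export
sphere_structure <- function(center, radius, label = c("GTV", "CTV", "PTV")) {
  label <- match.arg(label)
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)),
            is.finite(radius), radius > 0)
  structure(list(center = center, radius = radius, label = label),
            class = "sphere_structure")
}

#' @export
print.sphere_structure <- function(x, ...) {
  cat(sprintf("%s: sphere r=%g mm at (%s) mm\n", x$label, x$radius,
              paste(format(x$center), collapse = ", ")))
  invisible(x)
}

#' Build the GTV/CTV/PTV structure set on a grid
#'
#' Creates the three concentric spheres implied by a [phantom_spec()] and
#' verifies that the grid extent contains the PTV. The isotropic-PTV case uses
#' `max(ptv_margin)` as the PTV radius increment (per-axis margins are equal in
#' the default spec).
#'
#' @param spec a [phantom_spec()].
#' @param grid a [grid_spec()].
#' @param center phantom centre in mm (default the origin).
#' @return A list with elements `GTV`, `CTV`, `PTV`, each a
#'   [sphere_structure()].
#' @examples
#' ph <- make_phantom(phantom_spec(), default_grid())
#' ph$PTV$radius  # 15 mm
#' @export
make_phantom <- function(spec, grid, center = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "grid_spec"))
  r_gtv <- spec$gtv_radius
  r_ctv <- r_gtv + spec$ctv_margin
  r_ptv <- r_ctv + max(spec$ptv_margin)
  ext <- grid_extent(grid)
  lo <- center - r_ptv
  hi <- center + r_ptv
  if (any(lo < ext["min", ]) || any(hi > ext["max", ])) {
    stop(sprintf(
      "make_phantom: grid too small; extent must contain the PTV, i.e. reach [%s] to [%s] mm",
      paste(format(lo), collapse = ", "), paste(format(hi), collapse = ", ")))
  }
  list(GTV = sphere_structure(center, r_gtv, "GTV"),
       CTV = sphere_structure(center, r_ctv, "CTV"),
       PTV = sphere_structure(center, r_ptv, "PTV"))
}

#' Rasterize a spherical structure to a voxel mask
#'
#' A voxel belongs to the structure iff its centre lies inside or on the
#' sphere surface (closed ball); this convention is fixed and shared by every
#' consumer in the package.
#'
#' @param structure a [sphere_structure()].
#' @param grid a [grid_spec()].
#' @return A logical 3D array with `dim == grid$shape`.
#' @export
structure_mask <- function(structure, grid) {
  stopifnot(inherits(structure, "sphere_structure"), inherits(grid, "grid_spec"))
  radial_dist2(grid, structure$center) <= structure$radius^2
}
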