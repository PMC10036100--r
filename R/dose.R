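#' Dose grid container
#'
#' A scalar field on a regular 3D grid carrying either total physical dose or
#' biologically effective dose (BED), in Gy.
#'
#' @param values numeric 3D array of non-negative, finite voxel values (Gy).
#' @param grid the [grid_spec()] the values live on.
#' @param quantity `"physical"` or `"bed"`.
#' @param meta optional named list of provenance metadata (prescription style,
#'   isodose level, prescription dose, profile parameters, ...). Carried along
#'   by transforms and written to file headers.
#' @return An object of class `dose_grid`.
#' @export
dose_grid <- function(values, grid, quantity = c("physical", "bed"),
                      meta = list()) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(grid, "grid_spec"), is.array(values),
            identical(dim(values), as.integer(grid$shape)))
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("dose_grid: values must be finite and non-negative")
  }
  structure(list(values = values, grid = grid, quantity = quantity, meta = meta),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose_grid [%s]: %d x %d x %d voxels, max %.3f Gy\n",
              x$quantity, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              max(x$values)))
  invisible(x)
}

#' Dose-profile parameters
#'
#' Parametrizes the radially symmetric synthetic dose falloff used to emulate
#' point- and marginal-prescription SBRT plans.
#'
#' Both styles share a plateau + "shoulder" construction. The shoulder is an
#' algebraic (power-law) unit step
#' \deqn{S(\rho) = (1 + u/k)^{-k}, \quad u = (\rho - R_0)/w, \; u \ge 0,}
#' steep just beyond the plateau edge \eqn{R_0} and heavy-tailed far out, with
#' penumbra scale \eqn{w} (mm) and shape exponent \eqn{k}.
#'
#' * **marginal** style: uniform plateau, then the shoulder. The plateau radius
#'   is solved at generation time so that the PTV D95 equals the prescription
#'   dose while the prescription isodose surface sits at `isodose_level`% of
#'   the maximum dose.
#' * **point** style: uniform plateau to `plateau_radius`, then a linear
#'   fractional decline of `core_gradient` per mm over `core_range` mm
#'   (emulating the gentle dose rolloff of a multi-beam conformal plan), then
#'   the shoulder.
#'
#' @param style `"point"` or `"marginal"`.
#' @param isodose_level prescription isodose level in percent of the maximum
#'   dose (marginal style only); any value in \[60, 80\] is accepted.
#' @param plateau_radius plateau radius in mm. Point style only (default 13);
#'   for the marginal style it is solved from the normalization contract and
#'   must be left `NULL`.
#' @param penumbra_width shoulder penumbra scale w in mm (> 0, default 4).
#' @param core_gradient point style: fractional dose drop per mm beyond the
#'   plateau (default 0.01).
#' @param core_range point style: length in mm of the linear-decline region
#'   between plateau edge and shoulder start (default 15).
#' @param shoulder_exponent shape exponent k of the power-law shoulder
#'   (default 0.5; larger values approach an exponential falloff).
#' @return An object of class `dose_profile_params`.
#' @examples
#' dose_profile_params("marginal", isodose_level = 80)
#' dose_profile_params("point")
#' @export
dose_profile_params <- function(style = c("point", "marginal"),
                                isodose_level = NULL,
                                plateau_radius = NULL,
                                penumbra_width = 4,
                                core_gradient = 0.01,
                                core_range = 15,
                                shoulder_exponent = 0.5) {
  style <- match.arg(style)
  stopifnot(is.finite(penumbra_width), penumbra_width > 0,
            is.finite(shoulder_exponent), shoulder_exponent > 0,
            is.finite(core_gradient), core_gradient >= 0,
            is.finite(core_range), core_range >= 0)
  if (style == "marginal") {
    if (is.null(isodose_level)) {
      stop("dose_profile_params: marginal style requires 'isodose_level'")
    }
    if (!is.finite(isodose_level) || isodose_level < 60 || isodose_level > 80) {
      stop("dose_profile_params: 'isodose_level' must lie in [60, 80] percent")
    }
    if (!is.null(plateau_radius)) {
      stop("dose_profile_params: marginal plateau_radius is solved from the ",
           "normalization contract; leave it NULL")
    }
  } else {
    if (!is.null(isodose_level)) {
      stop("dose_profile_params: 'isodose_level' applies to marginal style only")
    }
    if (is.null(plateau_radius)) plateau_radius <- 13
    stopifnot(is.finite(plateau_radius), plateau_radius > 0)
  }
  structure(list(style = style, isodose_level = isodose_level,
                 plateau_radius = plateau_radius,
                 penumbra_width = penumbra_width,
                 core_gradient = core_gradient, core_range = core_range,
                 shoulder_exponent = shoulder_exponent),
            class = "dose_profile_params")
}

# Power-law shoulder: 1 inside r0, (1 + u/k)^(-k) beyond, u = (rho-r0)/w.
shoulder_factor <- function(rho, r0, w, k) {
  u <- pmax((rho - r0) / w, 0)
  (1 + u / k)^(-k)
}

# Relative point-style profile (max 1 at the centre).
point_profile <- function(rho, params) {
  rp <- params$plateau_radius
  core <- pmax(1 - params$core_gradient * pmax(rho - rp, 0), 0)
  core * shoulder_factor(rho, rp + params$core_range,
                         params$penumbra_width, params$shoulder_exponent)
}

#' Map electron density to a penumbra width
#'
#' Synthetic stand-in for the broadening of the lateral dose falloff at low
#' electron density (increased secondary-electron range in lung). The mapping
#' is log-linear through the module anchors w(1.0 g/cm3) = 4 mm and
#' w(0.4 g/cm3) = 8 mm, hence strictly decreasing and positive over the whole
#' admissible density range (0, 2]. The anchors are package defaults, not
#' measured values, and can be overridden.
#'
#' @param density electron density in g/cm3, in (0, 2]. Vectorized.
#' @param anchor_densities two densities fixing the mapping (default 1.0, 0.4).
#' @param anchor_widths penumbra widths in mm at the anchors (default 4, 8).
#' @return Penumbra width(s) in mm.
#' @examples
#' density_to_penumbra(c(0.4, 0.7, 1.0))
#' @export
density_to_penumbra <- function(density, anchor_densities = c(1.0, 0.4),
                                anchor_widths = c(4, 8)) {
  if (any(!is.finite(density)) || any(density <= 0) || any(density > 2)) {
    stop("density_to_penumbra: density must lie in (0, 2] g/cm3")
  }
  stopifnot(length(anchor_densities) == 2L, length(anchor_widths) == 2L,
            anchor_densities[1] != anchor_densities[2], all(anchor_widths > 0))
  slope <- (log(anchor_widths[2]) - log(anchor_widths[1])) /
    (anchor_densities[2] - anchor_densities[1])
  exp(log(anchor_widths[1]) + slope * (density - anchor_densities[1]))
}

#' Generate a synthetic prescription dose distribution
#'
#' Produces a radially symmetric, monotonically non-increasing physical dose
#' field around the phantom centre, normalized according to the prescription
#' style:
#'
#' * **point**: the dose at the centre voxel equals `prescription_dose`
#'   exactly (isocenter prescription).
#' * **marginal**: the PTV D95 (bin-free voxel-count quantile) equals
#'   `prescription_dose` exactly, and the maximum dose equals
#'   `prescription_dose * 100 / isodose_level`, i.e. the prescription isodose
#'   surface sits at `isodose_level`% of the maximum.
#'
#' @param params a [dose_profile_params()].
#' @param structures structure set from [make_phantom()] (the PTV is used for
#'   marginal normalization; all structures must share a centre).
#' @param grid a [grid_spec()].
#' @param prescription_dose total prescribed physical dose in Gy (default 48).
#' @return A [dose_grid()] with `quantity = "physical"`. The solved plateau
#'   radius and normalization details are recorded in `$meta`.
#' @examples
#' ph <- make_phantom(phantom_spec(), default_grid())
#' d <- generate_dose(dose_profile_params("marginal", isodose_level = 60),
#'                    ph, default_grid())
#' max(d$values)  # 48 * 100/60 = 80 Gy
#' @export
generate_dose <- function(params, structures, grid, prescription_dose = 48) {
  stopifnot(inherits(params, "dose_profile_params"), inherits(grid, "grid_spec"),
            is.finite(prescription_dose), prescription_dose > 0)
  ptv <- structures$PTV
  stopifnot(inherits(ptv, "sphere_structure"))
  center <- ptv$center
  rho <- sqrt(radial_dist2(grid, center))

  if (params$style == "point") {
    f <- point_profile(rho, params)
    ctr <- which.min(rho)
    if (f[ctr] <= 0) stop("generate_dose: profile vanishes at the isocenter")
    values <- prescription_dose * f / f[ctr]
    r0 <- params$plateau_radius
  } else {
    a <- params$isodose_level / 100
    w <- params$penumbra_width
    k <- params$shoulder_exponent
    rr <- rho[structure_mask(ptv, grid)]
    if (length(rr) == 0L) stop("generate_dose: PTV mask is empty on this grid")
    # D95 voxel-count quantile: radius of the ceiling(0.95 n)-th voxel sorted
    # by increasing distance (profile is non-increasing in rho).
    rq <- sort(rr)[ceiling(0.95 * length(rr))]
    # Solve the plateau radius so the shoulder passes through (rq, a).
    r0 <- rq - k * w * (a^(-1 / k) - 1)
    if (r0 <= 0) {
      stop(sprintf(
        paste0("generate_dose: unattainable normalization; penumbra width ",
               "%.1f mm is too wide for the plateau to cover the PTV at the ",
               "%g%% isodose level (required plateau radius %.2f mm <= 0)"),
        w, params$isodose_level, r0))
    }
    values <- (prescription_dose / a) * shoulder_factor(rho, r0, w, k)
  }

  dose_grid(values, grid, "physical",
            meta = list(style = params$style,
                        isodose_level = params$isodose_level,
                        prescription_dose = prescription_dose,
                        plateau_radius = r0,
                        penumbra_width = params$penumbra_width,
                        core_gradient = params$core_gradient,
                        core_range = params$core_range,
                        shoulder_exponent = params$shoulder_exponent,
                        center = center))
}
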