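#' Coverage criterion for the dosimetric margin
#'
#' The target is considered covered at a given isocenter shift when the dose
#' (or BED) received by at least `quantile` of the CTV volume is at least
#' `threshold_fraction` of the prescribed value. Shifts are scanned from
#' `-shift_range` to `+shift_range` in steps of `shift_step` along a cardinal
#' axis.
#'
#' @param quantile covered volume fraction (default 0.95, i.e. D95).
#' @param threshold_fraction fraction of the prescribed quantity that must be
#'   met (default 0.90).
#' @param shift_range maximum scanned |shift| in mm (default 20).
#' @param shift_step scan step in mm (default 1).
#' @param interpolate if `TRUE`, the acceptance extents are refined by linear
#'   interpolation of the D95-vs-shift curve at the threshold crossing
#'   (sub-step precision); the default `FALSE` reports whole scan steps.
#' @return An object of class `coverage_criterion`.
#' @export
coverage_criterion <- function(quantile = 0.95, threshold_fraction = 0.90,
                               shift_range = 20, shift_step = 1,
                               interpolate = FALSE) {
  stopifnot(is.finite(quantile), quantile > 0, quantile < 1,
            is.finite(threshold_fraction), threshold_fraction > 0,
            threshold_fraction <= 1,
            is.finite(shift_step), shift_step > 0,
            is.finite(shift_range), shift_range >= shift_step,
            is.logical(interpolate), length(interpolate) == 1L)
  structure(list(quantile = quantile, threshold_fraction = threshold_fraction,
                 shift_range = shift_range, shift_step = shift_step,
                 interpolate = interpolate),
            class = "coverage_criterion")
}

axis_unit <- function(axis) {
  i <- match(axis, c("LR", "AP", "CC"))
  if (is.na(i)) stop("axis must be one of 'LR', 'AP', 'CC'")
  u <- c(0, 0, 0); u[i] <- 1
  u
}

#' Dose-volume-histogram quantile (Dq)
#'
#' Returns the largest dose `D` such that at least a fraction `q` of the
#' masked voxels receive `>= D` (bin-free voxel-count convention: the
#' `ceiling(q * n)`-th largest masked value; no volume interpolation).
#'
#' @param dose a [dose_grid()].
#' @param mask a logical array matching the grid, or a [sphere_structure()]
#'   (rasterized with [structure_mask()]).
#' @param q volume fraction in (0, 1]; `q = 1` returns the masked minimum.
#' @return The dose (or BED) value in Gy.
#' @examples
#' g <- grid_spec(5, 1, 0)
#' d <- dose_grid(array(48, c(5, 5, 5)), g)
#' dvh_quantile(d, array(TRUE, c(5, 5, 5)), 0.95)  # 48
#' @export
dvh_quantile <- function(dose, mask, q = 0.95) {
  stopifnot(inherits(dose, "dose_grid"), is.finite(q), q > 0, q <= 1)
  if (inherits(mask, "sphere_structure")) mask <- structure_mask(mask, dose$grid)
  stopifnot(is.logical(mask), identical(dim(mask), dim(dose$values)))
  v <- dose$values[mask]
  if (length(v) == 0L) stop("dvh_quantile: mask selects no voxels")
  sort(v, decreasing = TRUE)[ceiling(q * length(v))]
}

#' D95 of a structure under an isocenter shift
#'
#' Shifting the isocenter by `shift` is realized as translating the structure
#' by `-shift` in the (fixed) dose frame and re-rasterizing it analytically at
#' the translated centre; no dose resampling is involved.
#'
#' @param dose a [dose_grid()].
#' @param ctv a [sphere_structure()].
#' @param shift isocenter displacement in mm (length-3 vector).
#' @param q covered volume fraction (default 0.95).
#' @return The Dq value at that shift, in Gy.
#' @export
shifted_d95 <- function(dose, ctv, shift, q = 0.95) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ctv, "sphere_structure"),
            length(shift) == 3L, all(is.finite(shift)))
  center <- ctv$center - shift
  ext <- grid_extent(dose$grid)
  if (any(center - ctv$radius < ext["min", ]) ||
      any(center + ctv$radius > ext["max", ])) {
    stop("shifted_d95: shifted structure exits the grid extent")
  }
  mask <- radial_dist2(dose$grid, center) <= ctv$radius^2
  v <- dose$values[mask]
  if (length(v) == 0L) stop("shifted_d95: shifted mask selects no voxels")
  sort(v, decreasing = TRUE)[ceiling(q * length(v))]
}

#' Precompute shifted-CTV voxel masks for the margin scan
#'
#' The shift scan re-rasterizes the same sphere at every scanned centre; when
#' many margins are computed on one grid (the study sweep) the index vectors
#' can be shared. The result is keyed by axis, one integer index vector per
#' scanned shift, using the same translate-by-`-shift` convention as
#' [shifted_d95()].
#'
#' @param grid a [grid_spec()].
#' @param ctv a [sphere_structure()].
#' @param criterion a [coverage_criterion()].
#' @param axes axes to precompute (default all three).
#' @return A list: `$shifts` (mm) and `$masks[[axis]][[i]]` index vectors.
#' @export
precompute_shift_masks <- function(grid, ctv, criterion,
                                   axes = c("LR", "AP", "CC")) {
  m <- floor(criterion$shift_range / criterion$shift_step)
  shifts <- criterion$shift_step * (-m:m)
  masks <- lapply(axes, function(ax) {
    u <- axis_unit(ax)
    lapply(shifts, function(s) {
      which(radial_dist2(grid, ctv$center - s * u) <= ctv$radius^2)
    })
  })
  names(masks) <- axes
  list(shifts = shifts, masks = masks)
}

#' Dosimetric margin along a cardinal axis
#'
#' Scans isocenter shifts `0, +-step, ..., +-range` along `axis`, computes the
#' CTV Dq at each shift, and accepts a shift when Dq is at least
#' `threshold_fraction * prescribed_value`. The positive extent is the largest
#' scanned shift `s+` such that the criterion holds at *every* scanned shift
#' in `[0, s+]` (contiguity guards against non-monotone numerical blips); the
#' negative extent is defined analogously. The margin is the minimum of the
#' two extents. With `criterion$interpolate = TRUE` each extent is refined by
#' linear interpolation of the Dq-vs-shift curve at the threshold crossing.
#'
#' Applied to a physical dose grid against the prescription dose this yields
#' the physical dosimetric margin (PDM); applied to a BED grid against the
#' prescribed BED it yields the biological dosimetric margin (BDM).
#'
#' @param dose a [dose_grid()] (physical or BED).
#' @param ctv the CTV [sphere_structure()].
#' @param axis `"LR"`, `"AP"` or `"CC"`.
#' @param criterion a [coverage_criterion()].
#' @param prescribed_value the 100% reference in Gy: prescription dose for
#'   physical grids, prescribed BED for BED grids.
#' @param shift_masks optional precomputed masks from
#'   [precompute_shift_masks()] (must cover `axis` with the same scan).
#' @return An object of class `margin_result`: fields `axis`, `quantity`,
#'   `margin_mm`, `positive_extent_mm`, `negative_extent_mm`, `interpolated`,
#'   `status` (`"ok"` or `"criterion_fails_at_zero_shift"`), and `profile`,
#'   a data frame with columns `axis`, `shift_mm`, `d95`, `accepted`.
#' @examples
#' ph <- make_phantom(phantom_spec(), default_grid())
#' d <- generate_dose(dose_profile_params("marginal", isodose_level = 80),
#'                    ph, default_grid())
#' dosimetric_margin(d, ph$CTV, "LR", coverage_criterion(), 48)$margin_mm
#' @export
dosimetric_margin <- function(dose, ctv, axis, criterion, prescribed_value,
                              shift_masks = NULL) {
  stopifnot(inherits(dose, "dose_grid"), inherits(ctv, "sphere_structure"),
            inherits(criterion, "coverage_criterion"),
            is.finite(prescribed_value), prescribed_value > 0)
  u <- axis_unit(axis)
  m <- floor(criterion$shift_range / criterion$shift_step)
  shifts <- criterion$shift_step * (-m:m)
  q <- criterion$quantile

  if (!is.null(shift_masks)) {
    if (!identical(shift_masks$shifts, shifts) || is.null(shift_masks$masks[[axis]])) {
      stop("dosimetric_margin: 'shift_masks' does not match this scan")
    }
    d95 <- vapply(shift_masks$masks[[axis]], function(idx) {
      v <- dose$values[idx]
      sort(v, decreasing = TRUE)[ceiling(q * length(v))]
    }, numeric(1))
  } else {
    d95 <- vapply(shifts, function(s) shifted_d95(dose, ctv, s * u, q),
                  numeric(1))
  }

  thr <- criterion$threshold_fraction * prescribed_value
  # Tiny relative slack so exact-threshold fields are not rejected by roundoff.
  accepted <- d95 >= thr * (1 - 1e-12)
  i0 <- m + 1L

  extent <- function(dir) {
    # dir = +1 walks positive shifts, -1 negative ones.
    k <- 0L
    while (k < m && accepted[i0 + dir * (k + 1L)]) k <- k + 1L
    ext <- k * criterion$shift_step
    if (criterion$interpolate && k < m) {
      d_in <- d95[i0 + dir * k]
      d_out <- d95[i0 + dir * (k + 1L)]
      if (d_in > d_out && d_in >= thr) {
        ext <- ext + criterion$shift_step * min(1, max(0, (d_in - thr) / (d_in - d_out)))
      }
    }
    ext
  }

  if (!accepted[i0]) {
    warning("dosimetric_margin: coverage criterion fails at zero shift; margin is 0")
    pos <- neg <- 0
    status <- "criterion_fails_at_zero_shift"
  } else {
    pos <- extent(+1L)
    neg <- extent(-1L)
    status <- "ok"
  }

  structure(list(axis = axis, quantity = dose$quantity,
                 margin_mm = min(pos, neg),
                 positive_extent_mm = pos, negative_extent_mm = neg,
                 interpolated = criterion$interpolate, status = status,
                 profile = data.frame(axis = axis, shift_mm = shifts,
                                      d95 = d95, accepted = accepted)),
            class = "margin_result")
}

#' @export
print.margin_result <- function(x, ...) {
  cat(sprintf("%s margin [%s, %s]: %.3f mm (extents +%.3f / -%.3f)%s\n",
              if (x$quantity == "bed") "Biological dosimetric" else "Physical dosimetric",
              x$axis, x$quantity, x$margin_mm,
              x$positive_extent_mm, x$negative_extent_mm,
              if (x$status != "ok") paste0(" [", x$status, "]") else ""))
  invisible(x)
}

#' PDM and BDM of one physical plan under one fractionation scheme
#'
#' Computes the physical dosimetric margin from the physical grid against
#' `threshold_fraction * prescription_dose`, converts the grid to BED with
#' [physical_to_bed()], and computes the biological dosimetric margin against
#' `threshold_fraction * prescribed_bed(scheme, alpha_beta)`.
#'
#' @param physical a [dose_grid()] with `quantity = "physical"`.
#' @param ctv the CTV [sphere_structure()].
#' @param scheme a [fractionation_scheme()].
#' @param alpha_beta alpha/beta ratio in Gy.
#' @param criterion a [coverage_criterion()].
#' @param axis `"LR"`, `"AP"` or `"CC"`.
#' @param prescription_dose prescription dose in Gy (default from grid meta).
#' @param shift_masks optional precomputed masks ([precompute_shift_masks()]).
#' @return A list with elements `PDM` and `BDM`, both [dosimetric_margin()]
#'   results.
#' @export
margin_pair <- function(physical, ctv, scheme, alpha_beta, criterion, axis,
                        prescription_dose = physical$meta$prescription_dose,
                        shift_masks = NULL) {
  stopifnot(identical(physical$quantity, "physical"))
  if (is.null(prescription_dose)) {
    stop("margin_pair: 'prescription_dose' is required")
  }
  pdm <- dosimetric_margin(physical, ctv, axis, criterion, prescription_dose,
                           shift_masks)
  bed <- physical_to_bed(physical, scheme, alpha_beta, prescription_dose)
  bdm <- dosimetric_margin(bed, ctv, axis, criterion,
                           prescribed_bed(scheme, alpha_beta), shift_masks)
  list(PDM = pdm, BDM = bdm)
}
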