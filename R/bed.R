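#' Fractionation scheme
#'
#' @param n number of treatment fractions (integer >= 1).
#' @param d prescription dose per fraction in Gy (> 0).
#' @return An object of class `fractionation_scheme`.
#' @examples
#' fractionation_scheme(4, 12)  # 48 Gy in 4 fractions
#' @export
fractionation_scheme <- function(n, d) {
  stopifnot(is.finite(n), n >= 1, n == as.integer(n), is.finite(d), d > 0)
  structure(list(n = as.integer(n), d = as.numeric(d)),
            class = "fractionation_scheme")
}

#' @export
print.fractionation_scheme <- function(x, ...) {
  cat(sprintf("%g Gy x %d fractions (total %g Gy)\n", x$d, x$n, x$n * x$d))
  invisible(x)
}

#' The eleven SBRT fractionation schemes of the study sweep
#'
#' Dose per fraction 3-20 Gy: 3 Gy x 15, 5 Gy x 10, 6 Gy x 10, 7 Gy x 5,
#' 7.5 Gy x 8, 8 Gy x 3, 10 Gy x 5, 12 Gy x 4, 15 Gy x 3, 18 Gy x 3 and
#' 20 Gy x 3.
#'
#' @return A list of [fractionation_scheme()] objects.
#' @export
study_schemes <- function() {
  dd <- c(3, 5, 6, 7, 7.5, 8, 10, 12, 15, 18, 20)
  nn <- c(15, 10, 10, 5, 8, 3, 5, 4, 3, 3, 3)
  mapply(fractionation_scheme, n = nn, d = dd, SIMPLIFY = FALSE)
}

#' Biologically effective dose of a uniform fractionated course
#'
#' Linear-quadratic model: `BED = n * d * (1 + d / alpha_beta)`.
#'
#' @param n number of fractions (>= 1). Vectorized.
#' @param d dose per fraction in Gy (> 0). Vectorized.
#' @param alpha_beta the tissue alpha/beta ratio in Gy (> 0); about 10 Gy for
#'   tumour, 3 Gy for late-reacting normal tissue.
#' @return BED in Gy.
#' @examples
#' bed_scalar(4, 12, 10)  # 105.6 Gy
#' @export
bed_scalar <- function(n, d, alpha_beta) {
  if (any(!is.finite(alpha_beta)) || any(alpha_beta <= 0)) {
    stop("bed_scalar: 'alpha_beta' must be positive")
  }
  stopifnot(all(n >= 1), all(d > 0))
  n * d * (1 + d / alpha_beta)
}

#' Prescribed BED of a fractionation scheme
#'
#' The 100% BED reference against which the biological coverage criterion is
#' expressed: [bed_scalar()] evaluated at the scheme's `n` and `d`.
#'
#' @param scheme a [fractionation_scheme()].
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @return BED in Gy.
#' @export
prescribed_bed <- function(scheme, alpha_beta) {
  stopifnot(inherits(scheme, "fractionation_scheme"))
  bed_scalar(scheme$n, scheme$d, alpha_beta)
}

#' Convert a physical dose grid to a BED grid
#'
#' Each voxel's total physical dose is first rescaled by
#' `n * d / prescription_dose`, so that the prescription metric carries the
#' scheme's total dose; the rescaled voxel dose is then split into `n` equal
#' fractions (`d_v = D_v / n`) and converted with the linear-quadratic model
#' `BED_v = n * d_v * (1 + d_v / alpha_beta)`. Voxel order is preserved.
#'
#' Rescaling the relative distribution rather than recomputing plans makes the
#' physical dosimetric margin independent of the evaluated scheme (the 90%
#' criterion is relative), so a single PDM reference serves all schemes.
#'
#' @param dose a [dose_grid()] with `quantity = "physical"`.
#' @param scheme a [fractionation_scheme()].
#' @param alpha_beta alpha/beta ratio in Gy (> 0).
#' @param prescription_dose the physical dose carried by the prescription
#'   metric of `dose`, in Gy. Defaults to `dose$meta$prescription_dose` when
#'   present.
#' @return A [dose_grid()] with `quantity = "bed"`.
#' @examples
#' ph <- make_phantom(phantom_spec(), default_grid())
#' d <- generate_dose(dose_profile_params("marginal", isodose_level = 80),
#'                    ph, default_grid())
#' b <- physical_to_bed(d, fractionation_scheme(4, 12), 10)
#' @export
physical_to_bed <- function(dose, scheme, alpha_beta,
                            prescription_dose = dose$meta$prescription_dose) {
  stopifnot(inherits(dose, "dose_grid"), inherits(scheme, "fractionation_scheme"))
  if (!identical(dose$quantity, "physical")) {
    stop("physical_to_bed: input dose grid must carry quantity 'physical'")
  }
  if (is.null(prescription_dose)) {
    stop("physical_to_bed: 'prescription_dose' is required when the grid ",
         "carries no prescription metadata")
  }
  stopifnot(is.finite(prescription_dose), prescription_dose > 0)
  if (any(!is.finite(alpha_beta)) || alpha_beta <= 0) {
    stop("physical_to_bed: 'alpha_beta' must be positive")
  }
  r <- dose$values / prescription_dose
  values <- scheme$n * scheme$d * r * (1 + r * scheme$d / alpha_beta)
  meta <- dose$meta
  meta$scheme <- c(n = scheme$n, d = scheme$d)
  meta$alpha_beta <- alpha_beta
  dose_grid(values, dose$grid, "bed", meta = meta)
}
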