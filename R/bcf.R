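#' Biological conversion factor of a margin pair
#'
#' `BCF = BDM / PDM`: the factor converting a physical dosimetric margin into
#' the biological one for a given fractionation scheme.
#'
#' @param bdm a [dosimetric_margin()] result on a BED grid.
#' @param pdm a [dosimetric_margin()] result on a physical grid, same axis.
#' @return The dimensionless ratio.
#' @examples
#' \dontrun{compute_bcf(pair$BDM, pair$PDM)}
#' @export
compute_bcf <- function(bdm, pdm) {
  stopifnot(inherits(bdm, "margin_result"), inherits(pdm, "margin_result"))
  if (!identical(bdm$axis, pdm$axis)) {
    stop("compute_bcf: BDM and PDM must be measured along the same axis")
  }
  if (pdm$margin_mm <= 0) {
    stop("compute_bcf: PDM is zero; the ratio BDM/PDM is undefined")
  }
  bdm$margin_mm / pdm$margin_mm
}

#' Evaluate the point-prescription BCF model
#'
#' `BCF_point = A * ln(d / (alpha/beta)) + B`.
#'
#' @param d_over_ab dose per fraction divided by alpha/beta (> 0). Vectorized.
#' @param A,B model parameters.
#' @return Model BCF value(s).
#' @examples
#' eval_bcf_point(1, A = -6.84e-2, B = 0.80)  # 0.80
#' @export
eval_bcf_point <- function(d_over_ab, A, B) {
  if (any(!is.finite(d_over_ab)) || any(d_over_ab <= 0)) {
    stop("eval_bcf_point: 'd_over_ab' must be positive")
  }
  A * log(d_over_ab) + B
}

#' Evaluate the marginal-prescription BCF model
#'
#' `BCF_marginal = (C * ID + D) * ln(d / (alpha/beta)) + (E * ID + F)`, where
#' `ID` is the prescription isodose level in percent.
#'
#' @param d_over_ab dose per fraction divided by alpha/beta (> 0). Vectorized.
#' @param id_percent prescription isodose level in percent.
#' @param C,D,E,F model parameters.
#' @return Model BCF value(s).
#' @examples
#' eval_bcf_marginal(1, 80, C = 4.51e-4, D = -4.66e-2, E = 1.86e-3, F = 0.811)
#' @export
eval_bcf_marginal <- function(d_over_ab, id_percent, C, D, E, F) {
  if (any(!is.finite(d_over_ab)) || any(d_over_ab <= 0)) {
    stop("eval_bcf_marginal: 'd_over_ab' must be positive")
  }
  (C * id_percent + D) * log(d_over_ab) + (E * id_percent + F)
}

#' Fit a BCF model by least squares
#'
#' Both BCF models are linear in their parameters given the `ln(d/(alpha/beta))`
#' and `ID` regressors, so the least-squares problem is solved exactly by QR
#' decomposition (no iterative optimization, no initialization or tolerance
#' knobs). Per-parameter standard deviations come from the classical
#' linear-model covariance estimate `sigma2 * (X'X)^-1` with
#' `sigma2 = RSS / (n - p)`.
#'
#' @param samples a data frame with columns `d_over_ab` and `bcf`, plus
#'   `id_percent` for the marginal style. Samples from different directions
#'   enter as separate rows (directions are pooled, not averaged).
#' @param style `"point"` (parameters A, B) or `"marginal"` (C, D, E, F).
#' @return An object of class `bcf_fit` with fields `style`, `params` (named
#'   vector), `param_sd`, `n_samples`, `sigma` (residual SD) and `residuals`.
#' @examples
#' u <- rep(c(0.3, 0.5, 1, 2), 2)
#' fit_bcf(data.frame(d_over_ab = u, bcf = -6.84e-2 * log(u) + 0.80), "point")
#' @export
fit_bcf <- function(samples, style = c("point", "marginal")) {
  style <- match.arg(style)
  stopifnot(is.data.frame(samples),
            all(c("d_over_ab", "bcf") %in% names(samples)))
  u <- samples$d_over_ab
  y <- samples$bcf
  if (any(!is.finite(u)) || any(u <= 0)) {
    stop("fit_bcf: 'd_over_ab' must be positive and finite")
  }
  if (any(!is.finite(y))) stop("fit_bcf: 'bcf' must be finite")
  lu <- log(u)

  if (style == "point") {
    X <- cbind(A = lu, B = 1)
  } else {
    if (!"id_percent" %in% names(samples)) {
      stop("fit_bcf: marginal style requires an 'id_percent' column")
    }
    id <- samples$id_percent
    if (length(unique(id)) < 2L) {
      stop("fit_bcf: rank-deficient design; the marginal model needs ",
           "samples at >= 2 distinct isodose levels")
    }
    X <- cbind(C = id * lu, D = lu, E = id, F = 1)
  }
  p <- ncol(X)
  n <- nrow(X)
  if (n < p) stop(sprintf("fit_bcf: need at least %d samples, got %d", p, n))
  qx <- qr(X)
  if (qx$rank < p) {
    stop("fit_bcf: rank-deficient design; the regressors (ln(d/ab)",
         if (style == "marginal") ", ID" else "",
         ") do not vary enough to identify all parameters")
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  if (n > p) {
    sigma2 <- sum(res^2) / (n - p)
    covb <- sigma2 * chol2inv(qr.R(qx))
    sd <- sqrt(pmax(0, diag(covb)))
  } else {
    sigma2 <- NA_real_
    sd <- rep(NA_real_, p)
  }
  names(sd) <- names(beta) <- colnames(X)
  structure(list(style = style, params = beta, param_sd = sd,
                 n_samples = n, sigma = sqrt(sigma2), residuals = res),
            class = "bcf_fit")
}

#' @export
print.bcf_fit <- function(x, ...) {
  cat(sprintf("BCF fit (%s prescription), n = %d samples\n", x$style, x$n_samples))
  tab <- data.frame(value = signif(x$params, 4), sd = signif(x$param_sd, 4))
  print(tab)
  invisible(x)
}

#' Predict from a fitted BCF model
#'
#' @param object a [fit_bcf()] result.
#' @param d_over_ab dose per fraction over alpha/beta (> 0).
#' @param id_percent isodose level in percent (marginal fits only).
#' @param ... unused.
#' @return Predicted BCF value(s).
#' @export
predict.bcf_fit <- function(object, d_over_ab, id_percent = NULL, ...) {
  p <- object$params
  if (object$style == "point") {
    eval_bcf_point(d_over_ab, p[["A"]], p[["B"]])
  } else {
    if (is.null(id_percent)) {
      stop("predict.bcf_fit: marginal fits require 'id_percent'")
    }
    eval_bcf_marginal(d_over_ab, id_percent,
                      p[["C"]], p[["D"]], p[["E"]], p[["F"]])
  }
}

#' Mean and standard error of BCF samples per group
#'
#' Groups samples by style, isodose level (when present) and `d_over_ab`, and
#' returns the arithmetic mean and the standard error of the mean
#' (`SEM = SD / sqrt(n)`) over the pooled directions. Groups of size 1 report
#' `NA` for the SEM.
#'
#' @param samples a data frame with columns `d_over_ab`, `bcf`, and optionally
#'   `style` and `id_percent`.
#' @return A data frame with one row per group: grouping columns, `n`,
#'   `mean_bcf`, `sem`.
#' @examples
#' pooled_bcf_stats(data.frame(d_over_ab = 1, bcf = c(0.78, 0.80, 0.82)))
#' @export
pooled_bcf_stats <- function(samples) {
  stopifnot(is.data.frame(samples),
            all(c("d_over_ab", "bcf") %in% names(samples)))
  keys <- intersect(c("style", "id_percent", "d_over_ab"), names(samples))
  key_df <- samples[keys]
  key_df[] <- lapply(key_df, function(col) {
    col[is.na(col)] <- if (is.numeric(col)) -Inf else "NA"
    col
  })
  grp <- interaction(key_df, drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(samples)), grp)
  out <- do.call(rbind, lapply(pieces, function(idx) {
    row <- samples[idx[1], keys, drop = FALSE]
    b <- samples$bcf[idx]
    row$n <- length(b)
    row$mean_bcf <- mean(b)
    row$sem <- if (length(b) >= 2L) stats::sd(b) / sqrt(length(b)) else NA_real_
    row
  }))
  rownames(out) <- NULL
  out[order(out$d_over_ab), , drop = FALSE]
}
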