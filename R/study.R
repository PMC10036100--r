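#' Configuration of the full margin/BCF study sweep
#'
#' Bundles the phantom, grid resolution, coverage criterion, fractionation
#' schemes, alpha/beta values, prescription styles, electron densities and
#' axes of the sweep. Defaults reproduce the reference study conditions:
#' 48 Gy prescription, the 11 SBRT schemes, alpha/beta 10 and 3 Gy, one point
#' style plus marginal styles at the 60/70/80% isodose levels, densities
#' 0.4/0.7/1.0 g/cm3, and a -20..20 mm, 1-mm shift scan with D95 >= 90%
#' coverage. The study criterion enables sub-step interpolation of the
#' acceptance crossing so that BCF values are not quantized to ratios of whole
#' scan steps; set `criterion = coverage_criterion()` for raw 1-mm margins.
#'
#' @param phantom a [phantom_spec()].
#' @param spacing grid spacing in mm (default 2).
#' @param criterion a [coverage_criterion()].
#' @param schemes list of [fractionation_scheme()] (default [study_schemes()]).
#' @param alpha_beta alpha/beta values in Gy (default `c(10, 3)`; the first is
#'   the headline tumour value used for the BCF fits).
#' @param styles data frame with columns `style` and `isodose_level` (`NA` for
#'   point rows); default point + marginal at 60/70/80.
#' @param densities electron densities in g/cm3 (default `c(0.4, 0.7, 1.0)`);
#'   must include the reference density 1.0 used for the headline fits.
#' @param axes subset of `c("LR","AP","CC")`.
#' @param prescription_dose prescribed physical dose in Gy (default 48).
#' @param point_params list of point-style profile knobs (`plateau_radius`,
#'   `core_gradient`, `core_range`).
#' @param shoulder_exponent shoulder shape exponent (default 0.5).
#' @param penumbra_anchors list with `densities` and `widths` passed to
#'   [density_to_penumbra()].
#' @param rng_seed integer seed stored for stochastic extensions; the default
#'   pipeline is fully deterministic.
#' @return An object of class `study_config`.
#' @export
study_config <- function(phantom = phantom_spec(),
                         spacing = 2,
                         criterion = coverage_criterion(interpolate = TRUE),
                         schemes = study_schemes(),
                         alpha_beta = c(10, 3),
                         styles = data.frame(
                           style = c("point", "marginal", "marginal", "marginal"),
                           isodose_level = c(NA, 60, 70, 80)),
                         densities = c(0.4, 0.7, 1.0),
                         axes = c("LR", "AP", "CC"),
                         prescription_dose = 48,
                         point_params = list(plateau_radius = 13,
                                             core_gradient = 0.01,
                                             core_range = 15),
                         shoulder_exponent = 0.5,
                         penumbra_anchors = list(densities = c(1.0, 0.4),
                                                 widths = c(4, 8)),
                         rng_seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(criterion, "coverage_criterion"),
            length(schemes) >= 1L,
            all(vapply(schemes, inherits, logical(1), "fractionation_scheme")),
            is.data.frame(styles), nrow(styles) >= 1L,
            all(c("style", "isodose_level") %in% names(styles)),
            all(styles$style %in% c("point", "marginal")),
            all(alpha_beta > 0), length(densities) >= 1L,
            all(axes %in% c("LR", "AP", "CC")), length(axes) >= 1L,
            is.finite(prescription_dose), prescription_dose > 0)
  structure(list(phantom = phantom, spacing = spacing, criterion = criterion,
                 schemes = schemes, alpha_beta = alpha_beta, styles = styles,
                 densities = densities, axes = axes,
                 prescription_dose = prescription_dose,
                 point_params = point_params,
                 shoulder_exponent = shoulder_exponent,
                 penumbra_anchors = penumbra_anchors,
                 rng_seed = as.integer(rng_seed)),
            class = "study_config")
}

style_label <- function(style, id) {
  ifelse(style == "point", "point", sprintf("marginal%02d", id))
}

build_profile_params <- function(config, style, isodose_level, penumbra) {
  if (style == "point") {
    dose_profile_params("point",
                        plateau_radius = config$point_params$plateau_radius,
                        penumbra_width = penumbra,
                        core_gradient = config$point_params$core_gradient,
                        core_range = config$point_params$core_range,
                        shoulder_exponent = config$shoulder_exponent)
  } else {
    dose_profile_params("marginal", isodose_level = isodose_level,
                        penumbra_width = penumbra,
                        shoulder_exponent = config$shoulder_exponent)
  }
}

#' Run the full study sweep
#'
#' For every density and prescription style: generate the dose distribution
#' once, measure the PDM along each axis, then for every alpha/beta and
#' fractionation scheme convert to BED and measure the BDM along each axis.
#' Assembles the per-combination result table and fits the point and marginal
#' BCF models on the reference-density (1.0 g/cm3), headline-alpha/beta
#' (first element of `config$alpha_beta`) samples, pooling all directions.
#' The run is fully deterministic given the configuration.
#'
#' @param config a [study_config()].
#' @return An object of class `study_result`: `table` (one row per swept
#'   combination: style, isodose_level, n, d, alpha_beta, axis, density,
#'   pdm_mm, bdm_mm, bcf), `samples` (the BCF samples entering the fits),
#'   `fits` (list with `point` and `marginal` [fit_bcf()] results, `NULL`
#'   when the configuration gives too few samples), `grid`, and `config`.
#' @examples
#' cfg <- study_config(schemes = study_schemes()[8], alpha_beta = 10,
#'                     styles = data.frame(style = "point", isodose_level = NA),
#'                     densities = 1.0, axes = "LR")
#' res <- run_study(cfg)
#' res$table
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$rng_seed)
  widths <- density_to_penumbra(config$densities,
                                config$penumbra_anchors$densities,
                                config$penumbra_anchors$widths)
  grid <- default_grid(config$spacing, config$phantom, config$criterion,
                       penumbra_width = max(widths))
  structures <- make_phantom(config$phantom, grid)
  masks <- precompute_shift_masks(grid, structures$CTV, config$criterion,
                                  config$axes)
  ref_ab <- config$alpha_beta[1]
  rows <- list()
  for (di in seq_along(config$densities)) {
    density <- config$densities[di]
    w <- widths[di]
    for (si in seq_len(nrow(config$styles))) {
      style <- config$styles$style[si]
      id <- config$styles$isodose_level[si]
      params <- build_profile_params(config, style, id, w)
      dose <- generate_dose(params, structures, grid, config$prescription_dose)
      pdm <- lapply(config$axes, function(ax) {
        dosimetric_margin(dose, structures$CTV, ax, config$criterion,
                          config$prescription_dose, masks)
      })
      names(pdm) <- config$axes
      for (ab in config$alpha_beta) {
        for (scheme in config$schemes) {
          bed <- physical_to_bed(dose, scheme, ab, config$prescription_dose)
          bed_rx <- prescribed_bed(scheme, ab)
          for (ax in config$axes) {
            bdm <- dosimetric_margin(bed, structures$CTV, ax, config$criterion,
                                     bed_rx, masks)
            rows[[length(rows) + 1L]] <- data.frame(
              style = style, isodose_level = id,
              n = scheme$n, d = scheme$d, alpha_beta = ab, axis = ax,
              density = density,
              pdm_mm = pdm[[ax]]$margin_mm, bdm_mm = bdm$margin_mm,
              bcf = bdm$margin_mm / pdm[[ax]]$margin_mm)
          }
        }
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL

  ref <- table[table$alpha_beta == ref_ab &
                 abs(table$density - 1.0) < 1e-9 &
                 is.finite(table$bcf), , drop = FALSE]
  samples <- data.frame(style = ref$style, id_percent = ref$isodose_level,
                        direction = ref$axis, d_over_ab = ref$d / ref$alpha_beta,
                        bcf = ref$bcf, density = ref$density)
  fits <- list(point = NULL, marginal = NULL)
  pt <- samples[samples$style == "point", , drop = FALSE]
  if (nrow(pt) >= 2L && length(unique(pt$d_over_ab)) >= 2L) {
    fits$point <- fit_bcf(pt, "point")
  }
  mg <- samples[samples$style == "marginal", , drop = FALSE]
  if (nrow(mg) >= 4L && length(unique(mg$id_percent)) >= 2L &&
      length(unique(mg$d_over_ab)) >= 2L) {
    fits$marginal <- fit_bcf(mg, "marginal")
  }

  structure(list(table = table, samples = samples, fits = fits,
                 grid = grid, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d rows (%d styles x %d schemes x %d alpha/beta x %d axes x %d densities)\n",
              nrow(x$table), nrow(x$config$styles), length(x$config$schemes),
              length(x$config$alpha_beta), length(x$config$axes),
              length(x$config$densities)))
  for (s in c("point", "marginal")) {
    if (!is.null(x$fits[[s]])) {
      cat(sprintf("  %s fit: %s\n", s,
                  paste(sprintf("%s=%.4g", names(x$fits[[s]]$params),
                                x$fits[[s]]$params), collapse = ", ")))
    }
  }
  invisible(x)
}

#' BCF robustness across electron densities
#'
#' For every style/scheme at the headline alpha/beta, compares the
#' direction-averaged BCF at each swept density with the reference density
#' 1.0 g/cm3: reports the maximum absolute difference alongside the SEM of
#' the reference-density group (over directions), and whether the difference
#' stays within that SEM.
#'
#' @param result a [run_study()] result whose configuration swept at least two
#'   densities including 1.0.
#' @return A data frame: style, isodose_level, n, d, d_over_ab,
#'   `max_abs_diff`, `sem_baseline`, `within_sem`.
#' @export
density_robustness_report <- function(result) {
  stopifnot(inherits(result, "study_result"))
  tab <- result$table
  ref_ab <- result$config$alpha_beta[1]
  tab <- tab[tab$alpha_beta == ref_ab & is.finite(tab$bcf), , drop = FALSE]
  dens <- sort(unique(tab$density))
  if (length(dens) < 2L) {
    stop("density_robustness_report: need results at >= 2 densities")
  }
  if (!any(abs(dens - 1.0) < 1e-9)) {
    stop("density_robustness_report: baseline density 1.0 g/cm3 is missing")
  }
  id_key <- ifelse(is.na(tab$isodose_level), "point", tab$isodose_level)
  key <- interaction(tab$style, id_key, tab$n, tab$d,
                     drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(tab)), key), function(idx) {
    g <- tab[idx, , drop = FALSE]
    base <- g[abs(g$density - 1.0) < 1e-9, , drop = FALSE]
    others <- g[abs(g$density - 1.0) >= 1e-9, , drop = FALSE]
    mean_by_density <- tapply(others$bcf, others$density, mean)
    base_mean <- mean(base$bcf)
    sem <- if (nrow(base) >= 2L) stats::sd(base$bcf) / sqrt(nrow(base)) else NA_real_
    data.frame(style = g$style[1], isodose_level = g$isodose_level[1],
               n = g$n[1], d = g$d[1], d_over_ab = g$d[1] / ref_ab,
               max_abs_diff = max(abs(mean_by_density - base_mean)),
               sem_baseline = sem,
               within_sem = if (is.na(sem)) NA else
                 max(abs(mean_by_density - base_mean)) <= sem)
  }))
  rownames(out) <- NULL
  out[order(out$style, out$isodose_level, out$d), , drop = FALSE]
}

#' Write study outputs to a directory
#'
#' Emits `margins.csv` (the full result table), `bcf_samples.csv` (samples
#' entering the fits: style, ID, direction, d_over_ab, bcf, density),
#' `fits.json` (per-style parameters, SDs and sample counts) and, when the
#' sweep covered more than one density, `density_report.csv`. Outputs are
#' plain text with no timestamps, so identical runs produce byte-identical
#' files.
#'
#' @param result a [run_study()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_study_outputs <- function(result, dir) {
  stopifnot(inherits(result, "study_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "margins.csv")
  utils::write.csv(result$table, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "bcf_samples.csv")
  utils::write.csv(result$samples, p, row.names = FALSE)
  paths <- c(paths, p)
  fits <- lapply(result$fits, function(f) {
    if (is.null(f)) NULL else
      list(style = f$style, params = as.list(f$params),
           sd = as.list(f$param_sd), n = f$n_samples)
  })
  p <- file.path(dir, "fits.json")
  jsonlite::write_json(fits, p, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  paths <- c(paths, p)
  if (length(unique(result$table$density)) >= 2L) {
    p <- file.path(dir, "density_report.csv")
    utils::write.csv(density_robustness_report(result), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export a margin scan as CSV
#'
#' Writes the shift-acceptance profiles (columns `axis`, `shift_mm`, `d95`,
#' `accepted`) and the margin summary (columns `axis`, `quantity`,
#' `margin_mm`, `pos_extent`, `neg_extent`) for a list of margin results.
#'
#' @param margins a list of [dosimetric_margin()] results.
#' @param profile_file path for the per-shift profile CSV (or `NULL` to skip).
#' @param summary_file path for the margin summary CSV (or `NULL` to skip).
#' @return Invisibly, the summary data frame.
#' @export
write_margin_csv <- function(margins, profile_file = NULL, summary_file = NULL) {
  stopifnot(all(vapply(margins, inherits, logical(1), "margin_result")))
  if (!is.null(profile_file)) {
    prof <- do.call(rbind, lapply(margins, `[[`, "profile"))
    utils::write.csv(prof, profile_file, row.names = FALSE)
  }
  summ <- do.call(rbind, lapply(margins, function(m) {
    data.frame(axis = m$axis, quantity = m$quantity, margin_mm = m$margin_mm,
               pos_extent = m$positive_extent_mm,
               neg_extent = m$negative_extent_mm)
  }))
  if (!is.null(summary_file)) {
    utils::write.csv(summ, summary_file, row.names = FALSE)
  }
  invisible(summ)
}
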