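table1_params <- c(A = -6.84e-2, B = 0.80)
table2_params <- c(C = 4.51e-4, D = -4.66e-2, E = 1.86e-3, F = 8.11e-1)

test_that("compute_bcf is the BDM/PDM ratio with a division guard", {
  mk <- function(margin, axis = "LR", quantity = "physical") {
    structure(list(axis = axis, quantity = quantity, margin_mm = margin,
                   positive_extent_mm = margin, negative_extent_mm = margin,
                   interpolated = FALSE, status = "ok",
                   profile = data.frame()), class = "margin_result")
  }
  expect_equal(compute_bcf(mk(10, quantity = "bed"), mk(10)), 1)
  expect_equal(compute_bcf(mk(8, quantity = "bed"), mk(10)), 0.8)
  expect_error(compute_bcf(mk(8, quantity = "bed"), mk(0)), "undefined")
  expect_error(compute_bcf(mk(8, axis = "AP"), mk(10, axis = "LR")),
               "same axis")
})

test_that("model evaluation matches the closed forms at reference points", {
  # ln(1) = 0: intercept terms only
  expect_equal(eval_bcf_point(1, table1_params[["A"]], table1_params[["B"]]),
               table1_params[["B"]])
  expect_equal(eval_bcf_point(exp(1), -6.84e-2, 0.80), 0.80 - 6.84e-2)
  expect_equal(
    eval_bcf_marginal(1, 80, table2_params[["C"]], table2_params[["D"]],
                      table2_params[["E"]], table2_params[["F"]]),
    table2_params[["E"]] * 80 + table2_params[["F"]])
  # C = E = 0 degenerates to the point model with A = D, B = F
  u <- c(0.3, 0.7, 1.4, 2)
  expect_equal(eval_bcf_marginal(u, 65, 0, -0.05, 0, 0.8),
               eval_bcf_point(u, -0.05, 0.8))
  expect_error(eval_bcf_point(-1, 1, 1), "positive")
  expect_error(eval_bcf_marginal(0, 80, 1, 1, 1, 1), "positive")
})

test_that("fitter recovers noise-free generating parameters to machine precision", {
  u <- rep(c(3, 5, 6, 7, 7.5, 8, 10, 12, 15, 18, 20) / 10, each = 3)
  pt <- data.frame(d_over_ab = u,
                   bcf = eval_bcf_point(u, table1_params["A"],
                                        table1_params["B"]))
  fit <- fit_bcf(pt, "point")
  expect_lt(max(abs(fit$params - table1_params) / abs(table1_params)), 1e-10)

  grid_id <- expand.grid(u = c(3, 5, 6, 7, 7.5, 8, 10, 12, 15, 18, 20) / 10,
                         id = c(60, 70, 80))
  mg <- data.frame(d_over_ab = grid_id$u, id_percent = grid_id$id,
                   bcf = eval_bcf_marginal(grid_id$u, grid_id$id,
                                           table2_params["C"], table2_params["D"],
                                           table2_params["E"], table2_params["F"]))
  fitm <- fit_bcf(mg, "marginal")
  expect_lt(max(abs(fitm$params - table2_params) / abs(table2_params)), 1e-10)
  # noise-free: residual sd ~ 0 and so are the parameter SDs
  expect_lt(max(fitm$param_sd), 1e-10)
})

test_that("fitted residuals are orthogonal to the regressors", {
  set.seed(7)
  u <- rep(c(0.3, 0.5, 0.8, 1.2, 1.5, 2), 3)
  id <- rep(c(60, 70, 80), each = 6)
  mg <- data.frame(d_over_ab = u, id_percent = id,
                   bcf = eval_bcf_marginal(u, id, 4e-4, -0.05, 2e-3, 0.8) +
                     rnorm(length(u), sd = 0.01))
  fit <- fit_bcf(mg, "marginal")
  X <- cbind(id * log(u), log(u), id, 1)
  expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8)
  # round trip: predictions at the sample abscissae equal the projection
  expect_equal(unname(mg$bcf - fit$residuals),
               unname(predict(fit, u, id)), tolerance = 1e-12)
})

test_that("fit_bcf cross-checks against lm on the same design", {
  set.seed(11)
  u <- rep(c(0.3, 0.6, 1, 1.6, 2), 3)
  y <- eval_bcf_point(u, -0.07, 0.8) + rnorm(length(u), sd = 0.02)
  fit <- fit_bcf(data.frame(d_over_ab = u, bcf = y), "point")
  ref <- stats::lm(y ~ log(u))
  expect_equal(unname(fit$params), unname(rev(stats::coef(ref))),
               tolerance = 1e-10)
  expect_equal(unname(fit$param_sd),
               unname(rev(summary(ref)$coefficients[, "Std. Error"])),
               tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with a named deficiency", {
  u <- c(0.3, 0.5, 1, 2)
  mg <- data.frame(d_over_ab = u, id_percent = 80,
                   bcf = eval_bcf_marginal(u, 80, 4e-4, -0.05, 2e-3, 0.8))
  expect_error(fit_bcf(mg, "marginal"), "2 distinct isodose levels")
  one <- data.frame(d_over_ab = rep(1, 5), bcf = rep(0.8, 5))
  expect_error(fit_bcf(one, "point"), "rank-deficient")
  expect_error(fit_bcf(one[1, ], "point"), "at least 2 samples")
})

test_that("pooled_bcf_stats returns the mean and SD/sqrt(n) per group", {
  s <- data.frame(d_over_ab = 1, bcf = c(0.78, 0.80, 0.82))
  out <- pooled_bcf_stats(s)
  expect_equal(out$mean_bcf, 0.80)
  expect_equal(out$sem, 0.02 / sqrt(3))
  expect_equal(out$n, 3L)
  # three equal values: SEM 0
  expect_equal(pooled_bcf_stats(data.frame(d_over_ab = 1,
                                           bcf = rep(0.9, 3)))$sem, 0)
  # singleton group: mean returned, SEM flagged missing
  single <- pooled_bcf_stats(data.frame(d_over_ab = 2, bcf = 0.7))
  expect_equal(single$mean_bcf, 0.7)
  expect_true(is.na(single$sem))
  # groups keyed by style/ID/abscissa
  multi <- pooled_bcf_stats(data.frame(
    style = rep(c("point", "marginal"), each = 3),
    id_percent = rep(c(NA, 80), each = 3),
    d_over_ab = 1, bcf = c(0.7, 0.72, 0.74, 0.9, 0.92, 0.94)))
  expect_equal(nrow(multi), 2L)
  expect_setequal(multi$mean_bcf, c(0.72, 0.92))
})
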