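make_radial_dose <- function(grid, fn, quantity = "physical") {
  cc <- axis_coords(grid)
  rho <- sqrt(outer(outer(cc[[1]]^2, cc[[2]]^2, "+"), cc[[3]]^2, "+"))
  dose_grid(array(fn(rho), dim = grid$shape), grid, quantity)
}

test_that("dvh_quantile implements the voxel-count convention", {
  g <- grid_spec(c(100, 1, 1), 1, 0)
  d <- dose_grid(array(as.numeric(1:100), c(100, 1, 1)), g)
  mask <- array(TRUE, c(100, 1, 1))
  # 95 voxels receive >= 6 Gy
  expect_equal(dvh_quantile(d, mask, 0.95), 6)
  # q -> 1 returns the masked minimum
  expect_equal(dvh_quantile(d, mask, 1), 1)
  # constant field
  du <- dose_grid(array(48, c(100, 1, 1)), g)
  expect_equal(dvh_quantile(du, mask, 0.95), 48)
  expect_error(dvh_quantile(d, array(FALSE, c(100, 1, 1))), "no voxels")
})

test_that("shifted_d95: identity, mirror symmetry, radial monotonicity", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  d <- generate_dose(dose_profile_params("marginal", isodose_level = 70),
                     ph, grid)
  expect_equal(shifted_d95(d, ph$CTV, c(0, 0, 0)),
               dvh_quantile(d, ph$CTV, 0.95))
  for (s in c(3, 7, 12)) {
    expect_equal(shifted_d95(d, ph$CTV, c(s, 0, 0)),
                 shifted_d95(d, ph$CTV, c(-s, 0, 0)), tolerance = 1e-12)
  }
  scan <- vapply(0:20, function(s) shifted_d95(d, ph$CTV, c(0, s, 0)),
                 numeric(1))
  expect_true(all(diff(scan) <= 1e-12))
  expect_error(shifted_d95(d, ph$CTV, c(50, 0, 0)), "exits the grid")
})

test_that("translating the structure equals translating the isocenter", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  d <- generate_dose(dose_profile_params("marginal", isodose_level = 60),
                     ph, grid)
  shift <- c(4, 0, 0)
  # move the dose frame instead: same values on a grid whose origin moved +s
  moved <- dose_grid(d$values, grid_spec(grid$shape, grid$spacing,
                                         grid$origin + shift), "physical")
  expect_equal(shifted_d95(d, ph$CTV, shift),
               shifted_d95(moved, ph$CTV, c(0, 0, 0)), tolerance = 1e-12)
})

test_that("dosimetric_margin handles never-failing and always-failing fields", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  crit <- coverage_criterion()
  hot <- make_radial_dose(grid, function(r) rep(48, length(r)))
  m <- dosimetric_margin(hot, ph$CTV, "LR", crit, 48)
  expect_equal(m$margin_mm, 20)
  expect_equal(m$positive_extent_mm, 20)
  expect_identical(m$status, "ok")
  cold <- make_radial_dose(grid, function(r) rep(0, length(r)))
  expect_warning(m0 <- dosimetric_margin(cold, ph$CTV, "LR", crit, 48),
                 "fails at zero shift")
  expect_equal(m0$margin_mm, 0)
  expect_identical(m0$status, "criterion_fails_at_zero_shift")
})

test_that("step dose with known 90% radius matches the brute-force oracle", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  crit <- coverage_criterion()
  for (r90 in c(12, 16, 19)) {
    d <- make_radial_dose(grid, function(r) ifelse(r <= r90, 48, 10))
    m <- dosimetric_margin(d, ph$CTV, "CC", crit, 48)
    o <- oracle_margin(d, ph$CTV, "CC", crit, 48)
    expect_equal(m$margin_mm, o)
    expect_lte(abs(m$margin_mm - o), crit$shift_step)
  }
})

test_that("precomputed shift masks reproduce the direct scan", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  crit <- coverage_criterion()
  masks <- precompute_shift_masks(grid, ph$CTV, crit)
  d <- generate_dose(dose_profile_params("marginal", isodose_level = 80),
                     ph, grid)
  for (ax in c("LR", "AP", "CC")) {
    direct <- dosimetric_margin(d, ph$CTV, ax, crit, 48)
    cached <- dosimetric_margin(d, ph$CTV, ax, crit, 48, shift_masks = masks)
    expect_equal(cached$margin_mm, direct$margin_mm)
    expect_equal(cached$profile$d95, direct$profile$d95)
  }
})

test_that("margins are isotropic on the isotropic phantom", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  crit <- coverage_criterion()
  d <- generate_dose(dose_profile_params("point"), ph, grid)
  m <- vapply(c("LR", "AP", "CC"), function(ax) {
    dosimetric_margin(d, ph$CTV, ax, crit, 48)$margin_mm
  }, numeric(1))
  expect_lte(max(m) - min(m), crit$shift_step)
})

test_that("margin_pair: BDM never exceeds PDM and deepens with dose per fraction", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  crit <- coverage_criterion()
  d <- generate_dose(dose_profile_params("marginal", isodose_level = 70),
                     ph, grid)
  bdm <- sapply(list(fractionation_scheme(15, 3), fractionation_scheme(4, 12),
                     fractionation_scheme(3, 20)), function(sch) {
    pr <- margin_pair(d, ph$CTV, sch, 10, crit, "LR")
    expect_lte(pr$BDM$margin_mm, pr$PDM$margin_mm)
    pr$BDM$margin_mm
  })
  # monotone contraction in d: BDM(4x12) <= BDM(15x3), BDM(3x20) <= BDM(4x12)
  expect_true(all(diff(bdm) <= 1e-12))
})

test_that("PDM is invariant to the fractionation scheme", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  crit <- coverage_criterion(interpolate = TRUE)
  d <- generate_dose(dose_profile_params("point"), ph, grid)
  pdms <- vapply(list(fractionation_scheme(15, 3), fractionation_scheme(3, 20)),
                 function(sch) {
    margin_pair(d, ph$CTV, sch, 10, crit, "AP")$PDM$margin_mm
  }, numeric(1))
  expect_equal(pdms[1], pdms[2], tolerance = 1e-12)
})

test_that("sub-step interpolation refines but never exceeds the next scan step", {
  grid <- default_grid()
  ph <- make_phantom(phantom_spec(), grid)
  d <- generate_dose(dose_profile_params("marginal", isodose_level = 60),
                     ph, grid)
  coarse <- dosimetric_margin(d, ph$CTV, "LR", coverage_criterion(), 48)
  fine <- dosimetric_margin(d, ph$CTV, "LR",
                            coverage_criterion(interpolate = TRUE), 48)
  expect_gte(fine$margin_mm, coarse$margin_mm)
  expect_lte(fine$margin_mm, coarse$margin_mm + 1)
  expect_true(fine$interpolated)
})
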