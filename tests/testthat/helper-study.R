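# Shared fixtures, built once per test run.

default_phantom <- function() make_phantom(phantom_spec(), default_grid())

# Headline study sweep: reference density, both alpha/beta values, all four
# prescription styles, the 11 schemes, all three axes. Memoized because
# several test files assert different properties of the same sweep.
cached_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_study(study_config(densities = 1.0))
    cache
  }
})

# Independent brute-force margin oracle: enumerates every scanned shift,
# rebuilds the shifted sphere from explicit voxel-centre coordinate vectors,
# and tests the coverage criterion by counting voxels at or above threshold
# (no DVH quantile, no shared mask code). Whole scan steps only.
oracle_margin <- function(dose, ctv, axis, criterion, prescribed_value) {
  grid <- dose$grid
  cc <- lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a]
  })
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X <- rep(cc[[1]], times = ny * nz)
  Y <- rep(rep(cc[[2]], each = nx), times = nz)
  Z <- rep(cc[[3]], each = nx * ny)
  vals <- as.vector(dose$values)
  thr <- criterion$threshold_fraction * prescribed_value * (1 - 1e-12)
  unit <- c(LR = 1L, AP = 2L, CC = 3L)[[axis]]
  m <- floor(criterion$shift_range / criterion$shift_step)
  accepted_at <- function(s) {
    ctr <- ctv$center
    ctr[unit] <- ctr[unit] - s
    inside <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <= ctv$radius^2
    n_in <- sum(inside)
    sum(vals[inside] >= thr) >= ceiling(criterion$quantile * n_in)
  }
  if (!accepted_at(0)) return(0)
  walk <- function(dir) {
    k <- 0L
    while (k < m && accepted_at(dir * (k + 1L) * criterion$shift_step)) {
      k <- k + 1L
    }
    k * criterion$shift_step
  }
  min(walk(+1L), walk(-1L))
}

# Random profile parameters for the oracle-equivalence sweep.
random_profile <- function() {
  if (runif(1) < 0.5) {
    dose_profile_params("point",
                        plateau_radius = runif(1, 10, 16),
                        penumbra_width = runif(1, 2, 8),
                        core_gradient = runif(1, 0.003, 0.012),
                        core_range = runif(1, 8, 20),
                        shoulder_exponent = sample(c(0.5, 1), 1))
  } else {
    dose_profile_params("marginal",
                        isodose_level = runif(1, 60, 80),
                        penumbra_width = runif(1, 2, 8),
                        shoulder_exponent = sample(c(0.5, 1), 1))
  }
}
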