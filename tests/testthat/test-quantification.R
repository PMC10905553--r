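simple_masks <- function(n = 10, spacing = 0.5) {
  grid <- volume3d(array(0, c(n, n, n)), rep(spacing, 3))
  body <- array(TRUE, c(n, n, n))
  lung <- array(FALSE, c(n, n, n))
  lung[2:5, 2:5, 2:5] <- TRUE
  list(grid = grid, body = body, lung = lung)
}

test_that("SEI reproduces its defining arithmetic", {
  # lung_sum 10, body_sum 100, V_lung 0.5 cm^3 -> SEI 0.2
  g <- volume3d(array(0, c(10, 10, 10)), c(1, 1, 1))
  body <- array(TRUE, dim(g$data))
  lung <- array(FALSE, dim(g$data))
  lung[1:5, 1:10, 1:10] <- TRUE   # 500 voxels x 1 mm^3 = 0.5 cm^3
  x <- g
  x$data[lung] <- 10 / 500
  x$data[!lung] <- 90 / 500
  ms <- mask_set(lung, body, g)
  res <- compute_sei(x, ms)
  expect_equal(res$sei_cm3, (10 / 100) / 0.5, tolerance = 1e-12)
  expect_equal(res$lung_sum, 10, tolerance = 1e-12)
  expect_equal(res$body_sum, 100, tolerance = 1e-12)

  # all in-body signal inside a 1 cm^3 lung -> SEI = 1 (the upper bound)
  lung2 <- array(FALSE, dim(g$data)); lung2[1:10, 1:10, 1:10] <- FALSE
  lung2[1:10, 1:10, 1:10][seq_len(1000)] <- TRUE
  x2 <- g; x2$data[] <- 0; x2$data[lung2] <- 1
  res2 <- compute_sei(x2, mask_set(lung2, body, g))
  expect_equal(res2$sei_cm3, 1, tolerance = 1e-12)

  # zero lung signal -> SEI 0
  x3 <- g; x3$data[] <- 0; x3$data[!lung] <- 1
  expect_equal(compute_sei(x3, ms)$sei_cm3, 0)
})

test_that("clamping and exclusion are applied to the sums", {
  sm <- simple_masks()
  x <- sm$grid
  x$data[] <- 1
  x$data[6, 6, 6] <- -5           # in body, negative
  excl <- array(FALSE, dim(x$data)); excl[8:10, 8:10, 8:10] <- TRUE
  ms <- mask_set(sm$lung, sm$body, sm$grid, exclusion = excl)
  res <- compute_sei(x, ms)
  expect_equal(res$clamped_voxel_count, 1L)
  expect_equal(res$body_sum, 1000 - 27 - 1)    # exclusion + clamped voxel
  expect_equal(res$lung_sum, 64)
  x0 <- sm$grid; x0$data[] <- 0
  expect_error(compute_sei(x0, ms), "no in-body signal")
})

test_that("SEI is scale invariant and bounded by 1/V_lung", {
  set.seed(41)
  for (rep in 1:100) {
    n <- 8
    grid <- volume3d(array(0, c(n, n, n)),
                     rep(runif(1, 0.2, 1), 3))
    body <- array(runif(n^3) < 0.8, c(n, n, n))
    body[2:7, 2:7, 2:7] <- TRUE
    lung <- array(FALSE, c(n, n, n))
    lung[2:4, 2:4, 2:4] <- runif(27) < 0.7
    if (!any(lung)) lung[3, 3, 3] <- TRUE
    x <- grid
    x$data[] <- rnorm(n^3, mean = 1)
    ms <- mask_set(lung, body, grid)
    res <- compute_sei(x, ms)
    scaled <- x; scaled$data <- x$data * 37.5
    res_s <- compute_sei(scaled, ms)
    expect_equal(res_s$sei_cm3, res$sei_cm3, tolerance = 1e-12)
    expect_gte(res$sei_cm3, 0)
    expect_lte(res$sei_cm3, 1 / ms$lung_volume_cm3 + 1e-12)
    expect_lte(res$lung_sum, res$body_sum)
  }
})

test_that("calibration fit recovers exact lines and near-unity R^2 under noise", {
  conc <- c(0, 5, 10, 20, 40, 80, 160)
  fit <- fit_calibration(conc, 2 * conc + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  two <- fit_calibration(c(1, 3), c(4, 10))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)

  set.seed(12)
  noisy <- (3.2 * conc + 0.4) * (1 + rnorm(7, 0, 0.01))
  fitn <- fit_calibration(conc, noisy)
  expect_gt(fitn$r_squared, 0.995)
  expect_error(fit_calibration(rep(5, 4), 1:4), "degenerate")
  expect_error(fit_calibration(1:3, 1:2), "paired")
})

test_that("signal-to-iron inversion is the calibration's exact inverse", {
  curve <- fit_calibration(c(0, 1, 2, 4), 2 * c(0, 1, 2, 4) + 3)
  expect_equal(signal_to_iron(curve$intercept, curve), 0)
  expect_equal(signal_to_iron(curve$intercept + curve$slope, curve), 1,
               tolerance = 1e-12)
  iron <- c(0.3, 1.7, 42)
  expect_equal(as.numeric(signal_to_iron(curve$slope * iron + curve$intercept,
                                         curve)),
               iron, tolerance = 1e-12)
  below <- signal_to_iron(curve$intercept - 1, curve)
  expect_equal(as.numeric(below), 0)
  expect_true(attr(below, "clamped"))
})

test_that("leakage map partitions the lung signal and flags heterogeneity", {
  hom <- make_phantom(small_config(seed = 29, heterogeneity = 0,
                                   psf_fwhm_mm = 0, mpi_noise_sd = 0))
  tr <- hom$truth
  masks <- mask_set(tr$mpi_lung_mask, tr$mpi_body_mask, tr$mpi_deposition,
                    exclusion = tr$mpi_fiducial_mask)
  map_hom <- leakage_map(tr$mpi_deposition, masks, block_mm = 2)
  dens <- map_hom$data[!is.na(map_hom$data)]
  expect_lt(sd(dens) / mean(dens), 0.05)
  sei <- compute_sei(tr$mpi_deposition, masks)
  expect_equal(sum(attr(map_hom, "block_signal")), sei$lung_sum,
               tolerance = 1e-9)

  het <- make_phantom(small_config(seed = 29, heterogeneity = 1.5,
                                   psf_fwhm_mm = 0, mpi_noise_sd = 0))
  trh <- het$truth
  masks_h <- mask_set(trh$mpi_lung_mask, trh$mpi_body_mask,
                      trh$mpi_deposition, exclusion = trh$mpi_fiducial_mask)
  map_het <- leakage_map(trh$mpi_deposition, masks_h, block_mm = 2)
  dens_h <- map_het$data[!is.na(map_het$data)]
  expect_gt(sd(dens_h) / mean(dens_h), sd(dens) / mean(dens))
  expect_error(leakage_map(trh$mpi_deposition, masks_h, block_mm = 0.1),
               "voxel pitch")
})
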