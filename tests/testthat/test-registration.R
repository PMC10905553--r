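test_that("fiducial detection recovers phantom marker centres", {
  ph <- make_phantom(small_config(seed = 6, mpi_noise_sd = 0))
  fs <- detect_fiducials(ph$mpi)
  expect_s3_class(fs, "fiducial_set")
  expect_equal(nrow(fs$points), 3L)
  truth <- ph$truth$fiducial_centers_mm$mpi
  err <- apply(fs$points, 1, function(p)
    min(sqrt(rowSums(sweep(truth, 2, p)^2))))
  expect_lt(max(err), 0.5 * max(ph$mpi$spacing))
})

test_that("detection survives noise at 5% of the fiducial peak", {
  quiet <- make_phantom(small_config(seed = 6, mpi_noise_sd = 0))
  peak <- max(quiet$mpi$data)
  noisy <- make_phantom(small_config(seed = 6, mpi_noise_sd = 0.05 * peak))
  fs <- detect_fiducials(noisy$mpi)
  expect_equal(nrow(fs$points), 3L)
  truth <- noisy$truth$fiducial_centers_mm$mpi
  err <- apply(fs$points, 1, function(p)
    min(sqrt(rowSums(sweep(truth, 2, p)^2))))
  expect_lt(max(err), 2 * max(noisy$mpi$spacing))
})

test_that("detection failure modes are explicit", {
  zero <- volume3d(array(0, c(20, 20, 20)), c(0.5, 0.5, 0.5))
  expect_error(detect_fiducials(zero), "insufficient fiducials")
  two_spots <- zero
  two_spots$data[5, 5, 5] <- 1
  two_spots$data[15, 15, 15] <- 1
  expect_error(detect_fiducials(two_spots, expected_count = 3),
               "insufficient fiducials")
  # interleaved components whose intensity-weighted centroids fall closer
  # than two voxels: a U-shaped blob with a separate spur inside its mouth
  merged <- zero
  for (x in 5:9) merged$data[x, 5, 5] <- 1
  for (y in 6:8) { merged$data[5, y, 5] <- 1; merged$data[9, y, 5] <- 1 }
  for (y in 7:9) merged$data[7, y, 5] <- 1
  merged$data[15, 15, 15] <- 1
  expect_error(detect_fiducials(merged, expected_count = 3), "merged")
})

scalene <- rbind(c(0, 0, 0), c(10, 0, 0), c(3, 5, 0))

test_that("distance-signature matching recovers permuted correspondences", {
  R <- mpileak:::axis_angle_rotation(c(0, 0, 1), 0.4)
  moved <- apply_rigid(rigid_transform(R, c(5, -2, 1)), scalene)
  for (perm in list(c(2, 3, 1), c(3, 1, 2), c(2, 1, 3))) {
    moving <- fiducial_set(moved[perm, ], frame = "MPI")
    fixed <- fiducial_set(scalene, frame = "CT")
    got <- match_fiducials(moving, fixed)
    # oracle: the permutation minimising the post-fit residual over all 3!
    perms <- mpileak:::permutations(3)
    fres <- apply(perms, 1, function(p) {
      fiducial_registration_error(
        estimate_rigid(moving, fiducial_set(scalene[p, ], frame = "CT")),
        moving, fiducial_set(scalene[p, ], frame = "CT"))
    })
    expect_equal(got, perms[which.min(fres), ])
  }
})

test_that("identity motion yields the identity correspondence", {
  fs <- fiducial_set(scalene, frame = "MPI")
  expect_equal(match_fiducials(fs, fiducial_set(scalene, frame = "CT")),
               1:3)
})

test_that("symmetric placements raise an ambiguity error, never a guess", {
  eq <- rbind(c(0, 0, 0), c(10, 0, 0), c(5, 5 * sqrt(3), 0))
  expect_error(match_fiducials(fiducial_set(eq, frame = "MPI"),
                               fiducial_set(eq, frame = "CT")),
               "ambiguous")
  far <- rbind(c(0, 0, 0), c(40, 0, 0), c(3, 7, 0))
  expect_error(match_fiducials(fiducial_set(scalene, frame = "MPI"),
                               fiducial_set(far, frame = "CT")),
               "no consistent")
})

test_that("closed-form rigid estimate recovers known transforms", {
  fs <- fiducial_set(scalene, frame = "MPI")
  t_id <- estimate_rigid(fs, fiducial_set(scalene, frame = "CT"))
  expect_lt(max(abs(t_id$rotation - diag(3))), 1e-9)
  expect_lt(max(abs(t_id$translation)), 1e-9)

  R30 <- mpileak:::axis_angle_rotation(c(0, 0, 1), 30 * pi / 180)
  truth <- rigid_transform(R30, c(1, 2, 3))
  fixed <- fiducial_set(apply_rigid(truth, scalene), frame = "CT")
  est <- estimate_rigid(fs, fixed)
  expect_lt(max(abs(est$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(est$translation - truth$translation)), 1e-9)

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0))
  expect_error(fiducial_set(collinear, frame = "MPI"), "collinear")
})

test_that("estimator matches reflection-free brute force on a 4-point set", {
  set.seed(19)
  pts <- matrix(runif(12, -10, 10), 4, 3)
  R <- random_rotation()
  truth <- rigid_transform(R, c(2, -1, 4))
  fixed <- apply_rigid(truth, pts)
  est <- estimate_rigid(fiducial_set(pts, frame = "MPI"),
                        fiducial_set(fixed, frame = "CT"))
  bf <- brute_force_rigid(pts, fixed)
  expect_lt(rotation_angle_between(est$rotation, bf$rotation), 5e-3)
  # the closed form is optimal: its SSE cannot exceed the grid search's
  sse_est <- sum((apply_rigid(est, pts) - fixed)^2)
  expect_lte(sse_est, bf$sse + 1e-9)
})

test_that("forward and reverse estimates are mutually inverse", {
  set.seed(23)
  for (rep in 1:5) {
    pts <- matrix(runif(12, -10, 10), 4, 3)
    truth <- rigid_transform(random_rotation(), runif(3, -5, 5))
    fixed <- apply_rigid(truth, pts)
    fwd <- estimate_rigid(fiducial_set(pts, frame = "MPI"),
                          fiducial_set(fixed, frame = "CT"))
    rev <- estimate_rigid(fiducial_set(fixed, frame = "CT"),
                          fiducial_set(pts, frame = "MPI"))
    comp <- compose_rigid(rev, fwd)
    expect_lt(max(abs(comp$rotation - diag(3))), 1e-8)
    expect_lt(max(abs(comp$translation)), 1e-8)
  }
})

test_that("FRE is zero for perfect recovery and bounded under noise", {
  fs <- fiducial_set(scalene, frame = "MPI")
  truth <- rigid_transform(mpileak:::axis_angle_rotation(c(1, 1, 0), 0.3),
                           c(1, 2, 3))
  fixed <- fiducial_set(apply_rigid(truth, scalene), frame = "CT")
  est <- estimate_rigid(fs, fixed)
  expect_lt(fiducial_registration_error(est, fs, fixed), 1e-10)

  set.seed(31)
  sigma <- 0.2
  fres <- replicate(100, {
    noisy <- fixed$points + matrix(rnorm(9, 0, sigma), 3, 3)
    nf <- fiducial_set(noisy, frame = "CT")
    fiducial_registration_error(estimate_rigid(fs, nf), fs, nf)
  })
  expect_true(all(fres > 0))
  expect_gt(mean(fres < 3 * sigma), 0.95)

  # a swapped correspondence inflates the residual on a scalene set
  swapped <- fiducial_set(fixed$points[c(2, 1, 3), ], frame = "CT")
  expect_gt(fiducial_registration_error(estimate_rigid(fs, swapped), fs,
                                        swapped),
            10 * fiducial_registration_error(est, fs, fixed) + 0.1)
})

test_that("mask resampling: identity, pure translation, and phantom truth", {
  grid <- volume3d(array(0, c(24, 24, 24)), c(0.5, 0.5, 0.5))
  mask <- array(FALSE, c(24, 24, 24))
  mask[8:16, 9:15, 7:17] <- TRUE
  ident <- rigid_transform(diag(3))
  expect_identical(resample_mask_to_grid(mask, grid, ident, grid), mask)

  shift <- rigid_transform(diag(3), c(0.5, 0, 0))  # exactly one voxel pitch
  out <- resample_mask_to_grid(mask, grid, shift, grid)
  expect_equal(sum(out), sum(mask))               # block is interior
  expect_identical(out[7:15, 9:15, 7:17], mask[8:16, 9:15, 7:17])

  # cardinality changes under arbitrary translation are bounded by the
  # surface voxel count
  surf <- sum(mask & !mpileak:::binary_erode(mask))
  t_frac <- rigid_transform(diag(3), c(0.21, -0.17, 0.33))
  out2 <- resample_mask_to_grid(mask, grid, t_frac, grid)
  expect_lte(abs(sum(out2) - sum(mask)), surf)

  far <- rigid_transform(diag(3), c(100, 0, 0))
  expect_warning(out3 <- resample_mask_to_grid(mask, grid, far, grid),
                 "empty")
  expect_true(attr(out3, "empty"))

  ph <- make_phantom(small_config(seed = 8))
  lung_mpi <- resample_mask_to_grid(ph$truth$lung_mask, ph$ct,
                                    ph$truth$true_rigid, ph$mpi)
  expect_gt(dice_overlap(lung_mpi, ph$truth$mpi_lung_mask), 0.95)
})

test_that("transforms and fiducial tables round-trip through disk", {
  t <- rigid_transform(mpileak:::axis_angle_rotation(c(0.2, 1, -0.5), 0.7),
                       c(1.5, -2.25, 0.125))
  path <- tempfile(fileext = ".json")
  write_transform(t, path, fre_mm = 0.042)
  t2 <- read_transform(path)
  expect_equal(t2$rotation, t$rotation, tolerance = 1e-12)
  expect_equal(t2$translation, t$translation, tolerance = 1e-12)
  expect_equal(attr(t2, "fre_mm"), 0.042)

  fs <- fiducial_set(scalene + 0.123, frame = "CT")
  csv <- tempfile(fileext = ".csv")
  write_fiducial_csv(fs, csv)
  fs2 <- read_fiducial_csv(csv)
  expect_equal(fs2$points, fs$points, tolerance = 1e-9)
})
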