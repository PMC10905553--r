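#' Configuration for the digital mouse-torso phantom
#'
#' Defines the simulated imaging session: grid geometry, tracer
#' biodistribution at imaging time, scanner blur and noise, and fiducial
#' layout. The anatomy (body, two lung lobes, heart, liver, spleen, bed
#' fiducials) is built from analytic ellipsoids/spheres anchored at the
#' grid centre, with sizes fixed in mm, so any grid that covers the scene
#' produces the same animal.
#'
#' Biodistribution defaults reflect a dextran-coated SPIO bolus 8 h after
#' tail-vein injection: the reticuloendothelial system dominates (liver
#' 0.80 and spleen 0.12 of the injected signal), a small residual fraction
#' is spread through the remaining soft tissue, and `leakage_fraction` of
#' the signal has extravasated into lung tissue through the disrupted
#' endothelial barrier. Presets `"oa"` (acute oleic-acid-like injury,
#' leakage 0.045) and `"ctr"` (healthy control, leakage 0.010) reproduce the
#' in vivo SEI scale of roughly 0.09 and 0.02 per cm^3 at a 0.5 cm^3 lung.
#'
#' @param grid_shape integer length-3 voxel counts (default 96 x 96 x 128).
#' @param voxel_spacing_mm positive length-3 voxel pitch (default 0.3 mm
#'   isotropic; set `c(0.144, 0.144, 0.144)` for micro-CT-fidelity runs).
#' @param leakage_fraction fraction of injected signal deposited in lung
#'   tissue, in [0, 1].
#' @param liver_fraction,spleen_fraction fractions deposited in liver and
#'   spleen; `leakage + liver + spleen` must not exceed 1. The remainder is
#'   spread uniformly through the rest of the body.
#' @param lung_volume_cm3 target anatomical lung volume (both lobes).
#' @param psf_fwhm_mm isotropic Gaussian PSF FWHM applied to the MPI
#'   volume (scanner resolution stand-in).
#' @param mpi_noise_sd additive Gaussian noise SD on the MPI volume
#'   (arbitrary units; the injected total is `injected_total`).
#' @param ct_noise_sd_hu additive Gaussian noise SD on the CT volume (HU).
#' @param n_fiducials number of bed fiducials (3 to 5; placements are
#'   pre-defined and scalene so correspondence is unambiguous).
#' @param fiducial_signal MPI signal per fiducial (stock-solution tracer,
#'   much brighter than any in-body depot).
#' @param heterogeneity patchiness of the lung deposition (>= 0); the lung
#'   weight field is `exp(heterogeneity * G)` for a smooth seeded random
#'   field `G`, renormalised so the deposited lung fraction is unchanged.
#' @param injected_total total in-body MPI signal (gain x dose), arbitrary
#'   units.
#' @param seed integer RNG seed; identical configs give bit-identical
#'   phantoms.
#' @param preset optional `"oa"` or `"ctr"`; overrides `leakage_fraction`.
#' @return a validated `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(96L, 96L, 128L),
                           voxel_spacing_mm = c(0.3, 0.3, 0.3),
                           leakage_fraction = 0.045,
                           liver_fraction = 0.80,
                           spleen_fraction = 0.12,
                           lung_volume_cm3 = 0.5,
                           psf_fwhm_mm = 0.7,
                           mpi_noise_sd = 5e-4,
                           ct_noise_sd_hu = 20,
                           n_fiducials = 3L,
                           fiducial_signal = 50,
                           heterogeneity = 0.5,
                           injected_total = 1000,
                           seed = 1L,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("oa", "ctr"))
    leakage_fraction <- switch(preset, oa = 0.045, ctr = 0.010)
  }
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_spacing_mm = as.numeric(voxel_spacing_mm),
              leakage_fraction = leakage_fraction,
              liver_fraction = liver_fraction,
              spleen_fraction = spleen_fraction,
              lung_volume_cm3 = lung_volume_cm3,
              psf_fwhm_mm = psf_fwhm_mm,
              mpi_noise_sd = mpi_noise_sd,
              ct_noise_sd_hu = ct_noise_sd_hu,
              n_fiducials = as.integer(n_fiducials),
              fiducial_signal = fiducial_signal,
              heterogeneity = heterogeneity,
              injected_total = injected_total,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  with(cfg, {
    if (length(grid_shape) != 3L || any(grid_shape < 8L))
      stop("`grid_shape` must be 3 integers >= 8", call. = FALSE)
    if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
      stop("all voxel spacings must be > 0", call. = FALSE)
    if (leakage_fraction < 0 || leakage_fraction > 1)
      stop("`leakage_fraction` must be in [0, 1]", call. = FALSE)
    if (liver_fraction < 0 || liver_fraction > 1 ||
        spleen_fraction < 0 || spleen_fraction > 1)
      stop("organ fractions must be in [0, 1]", call. = FALSE)
    if (leakage_fraction + liver_fraction + spleen_fraction > 1)
      stop("leakage_fraction + liver_fraction + spleen_fraction must be <= 1",
           call. = FALSE)
    if (lung_volume_cm3 <= 0 || lung_volume_cm3 > 1.2)
      stop("`lung_volume_cm3` must be in (0, 1.2] to fit the thorax",
           call. = FALSE)
    if (psf_fwhm_mm < 0) stop("`psf_fwhm_mm` must be >= 0", call. = FALSE)
    if (mpi_noise_sd < 0 || ct_noise_sd_hu < 0)
      stop("noise SDs must be >= 0", call. = FALSE)
    if (n_fiducials < 3L || n_fiducials > 5L)
      stop("`n_fiducials` must be between 3 and 5", call. = FALSE)
    if (fiducial_signal < 0) stop("`fiducial_signal` must be >= 0", call. = FALSE)
    if (heterogeneity < 0) stop("`heterogeneity` must be >= 0", call. = FALSE)
    if (injected_total <= 0) stop("`injected_total` must be > 0", call. = FALSE)
  })
  invisible(cfg)
}

# Scene layout: compartment centres are offsets (mm) from the grid centre;
# semi-axes in mm. HU values are representative micro-CT tissue numbers.
phantom_scene <- function(cfg) {
  v_lobe <- cfg$lung_volume_cm3 * 1000 / 2          # mm^3 per lobe
  ratio <- c(1, 1.1, 1.4)                           # lobe shape
  s <- (v_lobe / (4 / 3 * pi * prod(ratio)))^(1 / 3)
  lung_semi <- s * ratio
  if (-6.2 + lung_semi[3] > 0.3)
    stop("lung_volume_cm3 too large: lobes would reach the liver", call. = FALSE)
  fid_xz <- rbind(c(-8.4, -10.2), c(-0.4, 7.8), c(8.6, -5.2),
                  c(4.6, -12.7), c(-12.4, 3.3))
  list(
    body   = list(centre = c(0, -1.4, 0),    semi = c(10, 9, 16),   hu = 40),
    lung1  = list(centre = c(-5, -1.9, -6.2), semi = lung_semi,     hu = -650),
    lung2  = list(centre = c(5, -1.9, -6.2),  semi = lung_semi,     hu = -650),
    heart  = list(centre = c(0, -1.9, -4.7), semi = c(1.4, 2.2, 2.6), hu = 45),
    liver  = list(centre = c(0, -1.4, 7.0),  semi = c(7, 6.5, 5.2), hu = 60),
    spleen = list(centre = c(-6.8, -1.4, 10.5), semi = c(2.0, 2.0, 2.6), hu = 55),
    fiducial_radius = 0.782,                        # 2 uL sphere
    fiducial_offsets = cbind(fid_xz[seq_len(cfg$n_fiducials), 1, drop = FALSE],
                             11.1,
                             fid_xz[seq_len(cfg$n_fiducials), 2, drop = FALSE]),
    fiducial_hu = 300)
}

inside_ellipsoid <- function(ca, centre, semi) {
  ((ca$x - centre[1]) / semi[1])^2 +
    ((ca$y - centre[2]) / semi[2])^2 +
    ((ca$z - centre[3]) / semi[3])^2 <= 1
}

# Smooth seeded random field: sum of Gaussian bumps, evaluated analytically
# at arbitrary world coordinates so both frames see the same field.
bump_field <- function(ca, bumps) {
  g <- 0
  for (i in seq_len(nrow(bumps))) {
    g <- g + bumps[i, "amp"] *
      exp(-((ca$x - bumps[i, "cx"])^2 + (ca$y - bumps[i, "cy"])^2 +
              (ca$z - bumps[i, "cz"])^2) / (2 * bumps[i, "sigma"]^2))
  }
  g
}

#' Generate a paired CT/MPI phantom with known ground truth
#'
#' Builds the CT volume (HU) on its native grid and the MPI volume on a
#' separate grid whose world frame is related to the CT frame by a small
#' seeded rigid motion (the "animal repositioned between scanners" offset).
#' The MPI volume is the deposited tracer distribution plus the bed
#' fiducials, blurred by the Gaussian PSF and degraded with additive
#' Gaussian noise; negative voxels are left as-is so downstream clamping is
#' exercised.
#'
#' The returned `truth` carries compartment masks on both grids, the
#' noiseless pre-PSF deposition volume, the generating rigid transform
#' (MPI frame to CT frame), fiducial centres in both frames, and
#' `true_sei_cm3` computed directly from the deposited grids.
#'
#' @param config a `phantom_config`.
#' @return list with elements `ct`, `mpi` (both `volume3d`) and `truth`.
#' @export
make_phantom <- function(config) {
  cfg <- validate_phantom_config(config)
  scene <- phantom_scene(cfg)
  set.seed(cfg$seed)

  grid <- volume3d(array(0, cfg$grid_shape), cfg$voxel_spacing_mm)
  extent <- cfg$grid_shape * cfg$voxel_spacing_mm
  centre <- extent / 2

  # seeded rigid offset between frames (rotation about the scene centre)
  axis <- rnorm(3)
  angle <- runif(1, -3, 3) * pi / 180
  delta <- runif(3, -1, 1)
  R <- axis_angle_rotation(axis, angle)
  true_rigid <- rigid_transform(R, centre - as.vector(R %*% centre) + delta)

  # heterogeneity bumps inside the lung bounding box (CT world)
  lb <- rbind(centre + scene$lung1$centre, centre + scene$lung2$centre)
  lo <- apply(lb, 2, min) - scene$lung1$semi
  hi <- apply(lb, 2, max) + scene$lung1$semi
  n_bumps <- 12L
  bumps <- cbind(cx = runif(n_bumps, lo[1], hi[1]),
                 cy = runif(n_bumps, lo[2], hi[2]),
                 cz = runif(n_bumps, lo[3], hi[3]),
                 sigma = runif(n_bumps, 1.5, 3),
                 amp = rnorm(n_bumps))

  fid_centres_ct <- sweep(scene$fiducial_offsets, 2, centre, `+`)
  check_scene_fits(cfg, scene, grid, true_rigid, fid_centres_ct)

  rasterise <- function(ca) {
    body <- inside_ellipsoid(ca, centre + scene$body$centre, scene$body$semi)
    lung <- (inside_ellipsoid(ca, centre + scene$lung1$centre, scene$lung1$semi) |
               inside_ellipsoid(ca, centre + scene$lung2$centre, scene$lung2$semi)) & body
    heart <- inside_ellipsoid(ca, centre + scene$heart$centre, scene$heart$semi) &
      body & !lung
    liver <- inside_ellipsoid(ca, centre + scene$liver$centre, scene$liver$semi) &
      body & !lung & !heart
    spleen <- inside_ellipsoid(ca, centre + scene$spleen$centre, scene$spleen$semi) &
      body & !lung & !heart & !liver
    fid <- array(FALSE, dim(ca$x))
    for (i in seq_len(nrow(fid_centres_ct))) {
      fc <- fid_centres_ct[i, ]
      fid <- fid | (((ca$x - fc[1])^2 + (ca$y - fc[2])^2 + (ca$z - fc[3])^2)
                    <= scene$fiducial_radius^2)
    }
    list(body = body, lung = lung, heart = heart, liver = liver,
         spleen = spleen, fiducial = fid)
  }

  # ---- CT frame ----
  ca_ct <- coordinate_arrays(grid)
  m_ct <- rasterise(ca_ct)
  if (!any(m_ct$lung))
    stop("grid too small: lung compartment does not rasterise", call. = FALSE)
  if (any(m_ct$fiducial & m_ct$body))
    stop("fiducials intersect the body; scene invalid", call. = FALSE)
  ct_img <- array(-1000, cfg$grid_shape)
  ct_img[m_ct$body] <- scene$body$hu
  ct_img[m_ct$lung] <- scene$lung1$hu
  ct_img[m_ct$heart] <- scene$heart$hu
  ct_img[m_ct$liver] <- scene$liver$hu
  ct_img[m_ct$spleen] <- scene$spleen$hu
  ct_img[m_ct$fiducial] <- scene$fiducial_hu
  if (cfg$ct_noise_sd_hu > 0)
    ct_img <- ct_img + array(rnorm(length(ct_img), 0, cfg$ct_noise_sd_hu),
                             cfg$grid_shape)
  ct <- volume3d(ct_img, cfg$voxel_spacing_mm)

  # ---- MPI frame: evaluate the same scene at rigidly mapped coordinates ----
  ca_m <- coordinate_arrays(grid)
  Rm <- true_rigid$rotation; tv <- true_rigid$translation
  ca_mpi <- list(
    x = Rm[1, 1] * ca_m$x + Rm[1, 2] * ca_m$y + Rm[1, 3] * ca_m$z + tv[1],
    y = Rm[2, 1] * ca_m$x + Rm[2, 2] * ca_m$y + Rm[2, 3] * ca_m$z + tv[2],
    z = Rm[3, 1] * ca_m$x + Rm[3, 2] * ca_m$y + Rm[3, 3] * ca_m$z + tv[3])
  m_mpi <- rasterise(ca_mpi)

  dep <- array(0, cfg$grid_shape)
  total <- cfg$injected_total
  # lung: heterogeneous deposition, renormalised to the exact fraction
  if (cfg$leakage_fraction > 0) {
    w <- exp(cfg$heterogeneity * bump_field(ca_mpi, bumps))[m_mpi$lung]
    dep[m_mpi$lung] <- cfg$leakage_fraction * total * w / sum(w)
  }
  if (sum(m_mpi$liver) == 0L || sum(m_mpi$spleen) == 0L)
    stop("grid too small: liver/spleen compartments do not rasterise",
         call. = FALSE)
  dep[m_mpi$liver] <- cfg$liver_fraction * total / sum(m_mpi$liver)
  dep[m_mpi$spleen] <- cfg$spleen_fraction * total / sum(m_mpi$spleen)
  bg <- m_mpi$body & !m_mpi$lung & !m_mpi$liver & !m_mpi$spleen
  bg_fraction <- 1 - cfg$leakage_fraction - cfg$liver_fraction - cfg$spleen_fraction
  dep[bg] <- bg_fraction * total / sum(bg)
  fid_centres_mpi <- apply_rigid(invert_rigid(true_rigid), fid_centres_ct)
  if (cfg$fiducial_signal > 0) {
    for (i in seq_len(nrow(fid_centres_mpi))) {
      fc <- fid_centres_mpi[i, ]
      sphere <- ((ca_m$x - fc[1])^2 + (ca_m$y - fc[2])^2 +
                   (ca_m$z - fc[3])^2) <= scene$fiducial_radius^2
      dep[sphere] <- dep[sphere] + cfg$fiducial_signal / sum(sphere)
    }
  }
  deposition <- volume3d(dep, cfg$voxel_spacing_mm)

  mpi <- apply_psf(deposition, cfg$psf_fwhm_mm)
  if (cfg$mpi_noise_sd > 0)
    mpi$data <- mpi$data + array(rnorm(length(dep), 0, cfg$mpi_noise_sd),
                                 cfg$grid_shape)

  v_lung_cm3 <- sum(m_mpi$lung) * voxel_volume_cm3(grid)
  lung_sum <- sum(dep[m_mpi$lung])
  body_sum <- sum(dep[m_mpi$body])
  truth <- list(
    body_mask = m_ct$body, lung_mask = m_ct$lung, liver_mask = m_ct$liver,
    fiducial_mask = m_ct$fiducial,
    mpi_body_mask = m_mpi$body, mpi_lung_mask = m_mpi$lung,
    mpi_liver_mask = m_mpi$liver, mpi_fiducial_mask = m_mpi$fiducial,
    mpi_deposition = deposition,
    true_sei_cm3 = (lung_sum / body_sum) / v_lung_cm3,
    lung_volume_cm3 = v_lung_cm3,
    injected_total = total,
    true_rigid = true_rigid,
    fiducial_centers_mm = list(ct = fid_centres_ct, mpi = fid_centres_mpi))
  list(ct = ct, mpi = mpi, truth = truth, config = cfg)
}

check_scene_fits <- function(cfg, scene, grid, true_rigid, fid_centres_ct) {
  extent <- cfg$grid_shape * cfg$voxel_spacing_mm
  centre <- extent / 2
  b <- scene$body
  lo <- pmin(centre + b$centre - b$semi,
             apply(fid_centres_ct, 2, min) - scene$fiducial_radius)
  hi <- pmax(centre + b$centre + b$semi,
             apply(fid_centres_ct, 2, max) + scene$fiducial_radius)
  corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                   c(lo[3], hi[3])))
  mapped <- apply_rigid(invert_rigid(true_rigid), corners)
  all_pts <- rbind(corners, mapped)
  if (any(sweep(all_pts, 2, rep(0, 3), `<`)) ||
      any(sweep(all_pts, 2, extent, `>`)))
    stop(sprintf(
      "grid too small: scene spans [%s]-[%s] mm but grid extent is [%s] mm",
      paste(signif(apply(all_pts, 2, min), 3), collapse = ", "),
      paste(signif(apply(all_pts, 2, max), 3), collapse = ", "),
      paste(signif(extent, 3), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Write a phantom to disk
#'
#' Emits `ct.nii.gz`, `mpi.nii.gz`, truth masks as uint8 NIfTI, truth
#' scalars and fiducial centres as `truth.json`, and the CT-frame fiducial
#' table as `fiducials_ct.csv`.
#' @param phantom result of [make_phantom()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- phantom$ct$spacing
  write_volume(phantom$ct, file.path(dir, "ct.nii.gz"))
  write_volume(phantom$mpi, file.path(dir, "mpi.nii.gz"))
  for (nm in c("body_mask", "lung_mask", "liver_mask", "fiducial_mask"))
    write_volume(volume3d(array(as.integer(phantom$truth[[nm]]),
                                dim(phantom$ct$data)), sp),
                 file.path(dir, paste0(nm, ".nii.gz")))
  tr <- phantom$truth
  jsonlite::write_json(
    list(true_sei_cm3 = tr$true_sei_cm3,
         lung_volume_cm3 = tr$lung_volume_cm3,
         injected_total = tr$injected_total,
         rotation_row_major = as.vector(t(tr$true_rigid$rotation)),
         translation_mm = tr$true_rigid$translation,
         fiducial_centers_ct = tr$fiducial_centers_mm$ct,
         fiducial_centers_mpi = tr$fiducial_centers_mm$mpi),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_fiducial_csv(
    fiducial_set(tr$fiducial_centers_mm$ct, frame = "CT"),
    file.path(dir, "fiducials_ct.csv"))
  invisible(dir)
}
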