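#' SPIO extravasation index (SEI)
#'
#' Quantifies tracer leakage into the lung as the lung-to-body signal
#' ratio normalised by the lung volume:
#' \deqn{SEI = \frac{\sum_{lung} PXLI_{i,j,k}}{\sum_{body} PXLI_{i,j,k}} \cdot \frac{1}{V_{lung}}}
#' with units 1/cm^3. The index is the fraction of circulating tracer that
#' has extravasated per unit lung volume, so it is invariant to the
#' arbitrary MPI gain. Negative reconstructed voxels are clamped to zero
#' before summation (count reported), and the exclusion mask (fiducials,
#' bed) is removed from both sums. Sums are taken on the MPI native grid
#' with masks transformed onto it, never by interpolating MPI intensities.
#'
#' @param mpi a `volume3d` of MPI signal on the quantification grid.
#' @param masks a `mask_set` on the same grid.
#' @param provenance optional character vector recorded in the result
#'   (input names, transform id).
#' @return object of class `sei_result` with fields `sei_cm3`, `lung_sum`,
#'   `body_sum`, `lung_volume_cm3`, `clamped_voxel_count`, `provenance`.
#' @export
compute_sei <- function(mpi, masks, provenance = NULL) {
  stopifnot(inherits(mpi, "volume3d"), inherits(masks, "mask_set"))
  if (!identical(dim(mpi$data), dim(masks$lung)))
    stop("masks are not on the MPI grid", call. = FALSE)
  x <- mpi$data
  body_sel <- masks$body & !masks$exclusion
  lung_sel <- masks$lung & !masks$exclusion
  clamped <- sum(x < 0 & body_sel)
  x[x < 0] <- 0
  body_sum <- sum(x[body_sel])
  lung_sum <- sum(x[lung_sel])
  if (body_sum <= 0)
    stop("no in-body signal: whole-body sum is zero after clamping",
         call. = FALSE)
  structure(list(
    sei_cm3 = (lung_sum / body_sum) / masks$lung_volume_cm3,
    lung_sum = lung_sum,
    body_sum = body_sum,
    lung_volume_cm3 = masks$lung_volume_cm3,
    clamped_voxel_count = as.integer(clamped),
    provenance = provenance), class = "sei_result")
}

#' @export
print.sei_result <- function(x, ...) {
  cat(sprintf(
    "<sei_result> SEI = %.4g /cm^3 (lung %.6g / body %.6g, V_lung %.4g cm^3, %d voxels clamped)\n",
    x$sei_cm3, x$lung_sum, x$body_sum, x$lung_volume_cm3,
    x$clamped_voxel_count))
  invisible(x)
}

#' Fit the tracer linearity calibration
#'
#' Ordinary least-squares line of MPI signal against iron concentration,
#' as used to establish that signal is proportional to tracer amount.
#'
#' @param concentrations iron concentrations (e.g. ug Fe/mL).
#' @param signals MPI signal values, same length.
#' @return object of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared` (1 - SS_res/SS_tot) and `n_points`.
#' @export
fit_calibration <- function(concentrations, signals) {
  concentrations <- as.numeric(concentrations)
  signals <- as.numeric(signals)
  if (length(concentrations) != length(signals) || length(signals) < 2L)
    stop("need >= 2 paired points", call. = FALSE)
  if (max(concentrations) - min(concentrations) <= 0)
    stop("degenerate calibration: concentrations are all equal", call. = FALSE)
  fit <- lm(signals ~ concentrations)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((signals - mean(signals))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, n_points = length(signals)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> signal = %.6g x conc + %.6g (R^2 = %.4f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Invert a calibration curve: signal to iron amount
#'
#' Maps a summed MPI signal back to tracer amount via
#' `(signal - intercept) / slope`. The caller owns the unit bookkeeping
#' (signal sums over voxels correspond to concentration x voxel volume);
#' the returned value carries the curve's concentration unit. Negative
#' inferred amounts are clamped to 0 with attribute `clamped = TRUE`.
#'
#' @param signal_sum numeric signal value(s).
#' @param curve a `calibration_curve`.
#' @return numeric iron amount(s), clamped at zero.
#' @export
signal_to_iron <- function(signal_sum, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero", call. = FALSE)
  out <- (signal_sum - curve$intercept) / curve$slope
  clamped <- any(out < 0)
  out[out < 0] <- 0
  if (clamped) attr(out, "clamped") <- TRUE
  out
}

#' Block-wise lung leakage map
#'
#' Partitions the lung mask into axis-aligned cubic blocks of edge
#' `block_mm` (aligned to the volume corner) and reports the lung signal
#' density (signal per cm^3 of lung) per block, exposing the spatial
#' heterogeneity of vascular leakage that a single whole-lung index hides.
#' Negative voxels are clamped as in [compute_sei()], so the block signals
#' sum exactly to the SEI numerator.
#'
#' @param mpi a `volume3d` on the quantification grid.
#' @param masks a `mask_set` on the same grid.
#' @param block_mm block edge length (>= the largest voxel pitch).
#' @return a coarse `volume3d` of block densities (NA outside the lung),
#'   with attributes `block_signal` and `block_lung_cm3` (same shape).
#' @export
leakage_map <- function(mpi, masks, block_mm = 2) {
  stopifnot(inherits(mpi, "volume3d"), inherits(masks, "mask_set"))
  if (block_mm < max(mpi$spacing))
    stop("`block_mm` must be >= the voxel pitch", call. = FALSE)
  d <- dim(mpi$data)
  x <- mpi$data
  x[x < 0] <- 0
  sel <- which(masks$lung & !masks$exclusion)
  idx <- arrayInd(sel, d)
  # block index per axis from the voxel-centre offset to the volume corner
  nb <- integer(3)
  bidx <- matrix(0L, nrow(idx), 3)
  for (a in 1:3) {
    pos <- (idx[, a] - 0.5) * mpi$spacing[a]
    bidx[, a] <- pmin(floor(pos / block_mm), ceiling(d[a] * mpi$spacing[a] / block_mm) - 1) + 1L
    nb[a] <- ceiling(d[a] * mpi$spacing[a] / block_mm)
  }
  key <- (bidx[, 3] - 1L) * nb[1] * nb[2] + (bidx[, 2] - 1L) * nb[1] + bidx[, 1]
  sig <- array(0, nb)
  cnt <- array(0L, nb)
  sig[seq_len(prod(nb))] <- 0
  agg_sig <- rowsum(x[sel], key)
  agg_cnt <- rowsum(rep(1L, length(sel)), key)
  keys <- as.integer(rownames(agg_sig))
  sig[keys] <- agg_sig[, 1]
  cnt[keys] <- agg_cnt[, 1]
  vox_cm3 <- voxel_volume_cm3(mpi)
  dens <- array(NA_real_, nb)
  nz <- cnt > 0
  dens[nz] <- sig[nz] / (cnt[nz] * vox_cm3)
  out <- volume3d(dens, spacing_mm = rep(block_mm, 3),
                  origin_mm = rep(block_mm / 2, 3))
  attr(out, "block_signal") <- sig
  attr(out, "block_lung_cm3") <- cnt * vox_cm3
  out
}
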