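#' Segment the animal body from a CT volume
#'
#' Thresholds at `threshold_hu` (default -300 HU, between soft tissue and
#' lung parenchyma), keeps the largest 26-connected component, and fills
#' internal cavities so the air-filled lungs lie inside the body mask.
#' Small radio-visible objects off the animal (fiducial capsules, bed
#' hardware) are discarded by the largest-component step.
#'
#' @param ct a `volume3d` in Hounsfield units.
#' @param threshold_hu lower HU bound for tissue.
#' @return logical array (body mask) on the CT grid.
#' @export
segment_body <- function(ct, threshold_hu = -300) {
  stopifnot(inherits(ct, "volume3d"))
  bin <- ct$data >= threshold_hu
  body <- largest_component(bin, connectivity = 26L)
  if (is.null(body) || !any(body))
    stop("no body found: nothing above ", threshold_hu, " HU", call. = FALSE)
  fill_holes(body)
}

#' Segment the lungs from a CT volume within a body mask
#'
#' Selects voxels inside the body with HU in `hu_window` (default
#' [-900, -200], aerated parenchyma), applies a morphological opening of
#' `opening_radius` voxels to remove thin airway-like structures, and keeps
#' 26-connected components larger than `min_component_cm3`. An empty result
#' inside a nonempty body (e.g. fully consolidated lung) is returned with a
#' warning and attribute `warning = "empty lung"` rather than an error.
#'
#' The defaults are standard micro-CT heuristics; manual reference masks
#' can be supplied through [load_mask()] instead.
#'
#' @param ct a `volume3d` in Hounsfield units.
#' @param body logical body mask from [segment_body()].
#' @param hu_window length-2 HU window for lung parenchyma.
#' @param opening_radius structuring radius (voxels) of the opening.
#' @param min_component_cm3 minimum retained component volume.
#' @return logical lung mask on the CT grid.
#' @export
segment_lung <- function(ct, body, hu_window = c(-900, -200),
                         opening_radius = 1L, min_component_cm3 = 0.01) {
  stopifnot(inherits(ct, "volume3d"), is.array(body))
  if (!any(body)) stop("body mask is empty", call. = FALSE)
  cand <- body & ct$data >= hu_window[1] & ct$data <= hu_window[2]
  if (opening_radius > 0) cand <- binary_opening(cand, opening_radius)
  lab <- label_components(cand, connectivity = 26L)
  sizes <- component_sizes(lab)
  vox_cm3 <- voxel_volume_cm3(ct)
  keep <- which(sizes * vox_cm3 > min_component_cm3)
  lung <- array(lab %in% keep, dim(body))
  lung <- lung & body  # opening's dilation step may cross the body surface
  if (!any(lung)) {
    warning("empty lung mask inside a nonempty body (consolidated lung?)")
    attr(lung, "warning") <- "empty lung"
  }
  lung
}

#' Load an externally drawn mask
#'
#' Import path for manually selected regions of interest. The file grid
#' must match the reference geometry (dims exactly, spacing and origin to
#' 1e-4 mm); any nonzero voxel becomes `TRUE`.
#'
#' @param path NIfTI mask file.
#' @param grid reference `volume3d`.
#' @return logical array on the reference grid.
#' @export
load_mask <- function(path, grid) {
  vol <- read_volume(path)
  stop_if_geometry_mismatch(vol, grid, what = "mask")
  vol$data != 0
}

#' Mask bundle for quantification
#'
#' Packages the lung, body and exclusion masks on a stated grid, checking
#' the containment invariants (`lung` within `body`, `lung` disjoint from
#' `exclusion`) and computing the lung volume exactly as voxel count times
#' voxel volume (no partial-volume weighting).
#'
#' @param lung,body logical arrays on `grid`.
#' @param grid `volume3d` supplying the geometry (data ignored).
#' @param exclusion optional logical array removed from all sums (fiducials
#'   and bed); defaults to empty.
#' @return object of class `mask_set` with `lung_volume_cm3`.
#' @export
mask_set <- function(lung, body, grid, exclusion = NULL) {
  stopifnot(is.array(lung), is.array(body), inherits(grid, "volume3d"))
  if (!identical(dim(lung), dim(grid$data)) ||
      !identical(dim(body), dim(grid$data)))
    stop("mask dimensions do not match the grid", call. = FALSE)
  if (is.null(exclusion)) exclusion <- array(FALSE, dim(lung))
  lung <- lung != 0; body <- body != 0; exclusion <- exclusion != 0
  if (any(lung & !body))
    stop("invariant violation: lung mask extends outside the body mask",
         call. = FALSE)
  if (any(lung & exclusion))
    stop("invariant violation: lung mask overlaps the exclusion mask",
         call. = FALSE)
  n_lung <- sum(lung)
  if (n_lung == 0L)
    stop("lung mask is empty; cannot define a lung volume", call. = FALSE)
  structure(list(lung = lung, body = body, exclusion = exclusion,
                 spacing = grid$spacing, origin = grid$origin,
                 lung_volume_cm3 = n_lung * voxel_volume_cm3(grid)),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf(
    "<mask_set> lung %d vox (%.4f cm^3), body %d vox, exclusion %d vox @ %.3g mm\n",
    sum(x$lung), x$lung_volume_cm3, sum(x$body), sum(x$exclusion),
    x$spacing[1]))
  invisible(x)
}

#' Build a sphere-union exclusion mask around detected fiducials
#'
#' @param grid `volume3d` defining the output grid.
#' @param centers_mm n x 3 matrix of fiducial centres (same frame as grid).
#' @param radius_mm exclusion radius per fiducial; generous by default so
#'   PSF-blurred fiducial signal cannot enter the body sums.
#' @return logical array.
#' @export
fiducial_exclusion_mask <- function(grid, centers_mm, radius_mm = 2.5) {
  ca <- coordinate_arrays(grid)
  out <- array(FALSE, dim(grid$data))
  centers_mm <- matrix(centers_mm, ncol = 3)
  for (i in seq_len(nrow(centers_mm))) {
    fc <- centers_mm[i, ]
    out <- out | (((ca$x - fc[1])^2 + (ca$y - fc[2])^2 +
                     (ca$z - fc[3])^2) <= radius_mm^2)
  }
  out
}
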