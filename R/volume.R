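#' 3D scalar volume with world geometry
#'
#' A `volume3d` couples a numeric 3D array with its voxel spacing (mm) and
#' the world coordinate (mm) of the centre of voxel `[1, 1, 1]`. Axes are
#' world-aligned: world position of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`. This is the common geometry of
#' reconstructed preclinical MPI and micro-CT volumes once oblique
#' orientation has been resolved; oblique direction matrices are out of
#' scope.
#'
#' @param data numeric 3D array of voxel values (CT in Hounsfield units,
#'   MPI in arbitrary signal units).
#' @param spacing_mm positive numeric length-3, voxel pitch in mm.
#' @param origin_mm numeric length-3, world position (mm) of the centre of
#'   the first voxel. Defaults to `spacing_mm / 2` so the volume occupies
#'   `[0, dim * spacing]` in each axis.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing_mm, origin_mm = spacing_mm / 2) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite values", call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite values", call. = FALSE)
  structure(list(data = data, spacing = spacing_mm, origin = origin_mm),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (mm): %.3f %.3f %.3f | range: [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume in mm^3 and cm^3
#' @param vol a `volume3d` (or a `mask_set` reference geometry list).
#' @return scalar voxel volume.
#' @export
voxel_volume_mm3 <- function(vol) prod(vol$spacing)

#' @rdname voxel_volume_mm3
#' @export
voxel_volume_cm3 <- function(vol) prod(vol$spacing) / 1000

#' World coordinates of all voxel centres
#'
#' Returns the three coordinate arrays (same shape as the volume) giving the
#' world x, y, z of each voxel centre. Kept as arrays (not an N x 3 matrix)
#' so analytic solids can be evaluated vectorised.
#' @param vol a `volume3d`.
#' @return list of arrays `x`, `y`, `z`.
#' @keywords internal
coordinate_arrays <- function(vol) {
  d <- dim(vol$data)
  xs <- vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1]
  ys <- vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2]
  zs <- vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3]
  list(x = array(xs, d),
       y = array(rep(ys, each = d[1]), d),
       z = array(rep(zs, each = d[1] * d[2]), d))
}

index_to_world <- function(vol, idx) {
  idx <- matrix(idx, ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

world_to_index <- function(vol, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(sweep(xyz, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} that preserve voxel spacing and origin
#' through the sform. Only axis-aligned geometries are produced; on read,
#' spacing is taken from the header pixdim and the origin from the stored
#' transform translation.
#'
#' @param vol a `volume3d`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; `read_volume` returns a
#'   `volume3d`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(4)
  diag(m)[1:3] <- vol$spacing
  m[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(d), " dimensions",
         call. = FALSE)
  pd <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) pd / 2 else abs(xf[1:3, 4]) * 0 + xf[1:3, 4]
  volume3d(array(as.numeric(img), dim = d), spacing_mm = abs(pd),
           origin_mm = origin)
}

stop_if_geometry_mismatch <- function(a, b, what = "volume", tol = 1e-4) {
  ok <- identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
  if (!ok)
    stop(sprintf(
      "%s geometry mismatch: [%s] @ [%s] mm origin [%s] vs [%s] @ [%s] mm origin [%s]",
      what,
      paste(dim(a$data), collapse = "x"), paste(signif(a$spacing, 6), collapse = ", "),
      paste(signif(a$origin, 6), collapse = ", "),
      paste(dim(b$data), collapse = "x"), paste(signif(b$spacing, 6), collapse = ", "),
      paste(signif(b$origin, 6), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
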