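#' Labelled fiducial landmark set
#'
#' World-coordinate (mm) landmark points used for point-based rigid
#' co-registration of the MPI and CT frames. At least three non-collinear
#' points are required; collinearity is tested on the singular values of
#' the centred point matrix (smallest > 1e-9 x largest).
#'
#' @param points numeric matrix, n x 3, world mm.
#' @param labels character vector of length n (default `fid1..fidn`).
#' @param frame `"MPI"` or `"CT"`.
#' @return object of class `fiducial_set`.
#' @export
fiducial_set <- function(points, labels = NULL, frame = c("MPI", "CT")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  if (ncol(points) != 3L || nrow(points) < 3L)
    stop("`points` must be an n x 3 matrix with n >= 3", call. = FALSE)
  if (any(!is.finite(points)))
    stop("fiducial coordinates must be finite", call. = FALSE)
  if (is.null(labels)) labels <- paste0("fid", seq_len(nrow(points)))
  sv <- svd(scale(points, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[2] <= 1e-9 * sv[1])
    stop("degenerate fiducial set: points are collinear", call. = FALSE)
  structure(list(points = unname(points), labels = as.character(labels),
                 frame = frame),
            class = "fiducial_set")
}

#' @export
print.fiducial_set <- function(x, ...) {
  cat(sprintf("<fiducial_set> %d points in %s frame\n", nrow(x$points), x$frame))
  print(data.frame(label = x$labels, x_mm = x$points[, 1],
                   y_mm = x$points[, 2], z_mm = x$points[, 3]))
  invisible(x)
}

#' Rigid (rotation + translation) transform between world frames
#'
#' Maps moving-frame coordinates to fixed-frame coordinates as
#' `x_fixed = R x_moving + t`. The rotation must be proper orthogonal
#' (R'R = I and det R = +1, each to 1e-9).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation_mm numeric length 3, mm.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation_mm = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)))
    stop("`rotation` must be 3 x 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("`rotation` is not orthogonal (R'R != I)", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("`rotation` must be proper (det = +1)", call. = FALSE)
  structure(list(rotation = unname(rotation),
                 translation = as.numeric(translation_mm)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

rotation_angle_deg <- function(R) {
  c_ang <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_ang))) * 180 / pi
}

axis_angle_rotation <- function(axis, angle_rad) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle_rad) * K + (1 - cos(angle_rad)) * (K %*% K)
}

#' Apply, invert and compose rigid transforms
#' @param t,a,b `rigid_transform` objects.
#' @param points n x 3 matrix of moving-frame coordinates (mm).
#' @return `apply_rigid`: n x 3 matrix of fixed-frame coordinates;
#'   `invert_rigid`: the inverse transform; `compose_rigid`: `a` then `b`
#'   applied after it (i.e. `b %o% a`).
#' @export
apply_rigid <- function(t, points) {
  points <- matrix(points, ncol = 3)
  sweep(points %*% t(t$rotation), 2, t$translation, `+`)
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(t) {
  Rt <- t(t$rotation)
  rigid_transform(Rt, -as.vector(Rt %*% t$translation))
}

#' @rdname apply_rigid
#' @export
compose_rigid <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.vector(b$rotation %*% a$translation) + b$translation)
}

#' Detect tracer-filled fiducial markers in an MPI volume
#'
#' Voxels at or above `threshold_fraction` of the volume maximum are grouped
#' into 26-connected components; the `expected_count` largest components
#' (outside `body_mask`, if supplied) yield intensity-weighted centroids in
#' world mm. Fiducials are bright tracer depots, so a relative threshold is
#' robust to the arbitrary MPI signal scale.
#'
#' @param volume a `volume3d` (MPI frame).
#' @param threshold_fraction fraction of the volume maximum in (0, 1].
#' @param expected_count number of fiducials to find (>= 3).
#' @param body_mask optional logical array on the same grid; components
#'   overlapping it are ignored (in-body hotspots such as the liver).
#' @param frame frame label for the returned set.
#' @return a `fiducial_set`, ordered by decreasing component signal.
#' @export
detect_fiducials <- function(volume, threshold_fraction = 0.5,
                             expected_count = 3L, body_mask = NULL,
                             frame = "MPI") {
  stopifnot(inherits(volume, "volume3d"))
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction > 1)
    stop("`threshold_fraction` must be in (0, 1]", call. = FALSE)
  if (expected_count < 3L)
    stop("`expected_count` must be >= 3", call. = FALSE)
  if (any(!is.finite(volume$data)))
    stop("volume contains non-finite values", call. = FALSE)
  mx <- max(volume$data)
  if (mx <= 0)
    stop("insufficient fiducials: volume has no positive signal", call. = FALSE)
  bin <- volume$data >= threshold_fraction * mx
  if (!is.null(body_mask)) bin <- bin & !body_mask
  lab <- label_components(bin, connectivity = 26L)
  sizes <- component_sizes(lab)
  if (length(sizes) < expected_count)
    stop(sprintf("insufficient fiducials: found %d components, expected %d",
                 length(sizes), expected_count), call. = FALSE)
  # rank components by total signal, not voxel count
  signal <- vapply(seq_along(sizes),
                   function(l) sum(volume$data[lab == l]), numeric(1))
  keep <- order(signal, decreasing = TRUE)[seq_len(expected_count)]
  centroids <- t(vapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    w <- volume$data[lab == l]
    colSums(index_to_world(volume, idx) * w) / sum(w)
  }, numeric(3)))
  dmin <- min(dist(centroids))
  if (dmin < 2 * max(volume$spacing))
    stop(sprintf("merged fiducials: centroids only %.3f mm apart", dmin),
         call. = FALSE)
  fiducial_set(centroids, frame = frame)
}

#' Match fiducials between frames by inter-point distance signature
#'
#' Rigid motion preserves pairwise distances, so the correct correspondence
#' is the permutation under which the two distance matrices agree. For three
#' points this is matching of the triangle side lengths. If more than one
#' permutation is consistent within `tol_mm` (e.g. a near-isosceles
#' placement), matching is ambiguous and an error is raised rather than a
#' silent guess; if none is consistent the sets are incompatible.
#'
#' @param moving,fixed `fiducial_set`s with equal point counts (n <= 7).
#' @param tol_mm distance-agreement tolerance in mm.
#' @return integer permutation `p`: moving point `i` corresponds to fixed
#'   point `p[i]`.
#' @export
match_fiducials <- function(moving, fixed, tol_mm = 0.25) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  n <- nrow(moving$points)
  if (nrow(fixed$points) != n)
    stop("fiducial sets have different sizes", call. = FALSE)
  if (n > 7L)
    stop("signature matching supports at most 7 fiducials", call. = FALSE)
  Dm <- as.matrix(dist(moving$points))
  Df <- as.matrix(dist(fixed$points))
  perms <- permutations(n)
  dev <- apply(perms, 1, function(p) max(abs(Dm - Df[p, p, drop = FALSE])))
  feasible <- which(dev < tol_mm)
  if (length(feasible) == 0L)
    stop(sprintf(
      "no consistent fiducial correspondence within %.3g mm (best deviation %.3g mm)",
      tol_mm, min(dev)), call. = FALSE)
  if (length(feasible) > 1L)
    stop(sprintf(
      "ambiguous fiducial correspondence: %d permutations agree within %.3g mm; use asymmetric fiducial placement",
      length(feasible), tol_mm), call. = FALSE)
  perms[feasible, ]
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Closed-form least-squares rigid registration (Kabsch)
#'
#' Estimates the rotation and translation minimising
#' `sum_i || R m_i + t - f_i ||^2` over matched landmark pairs, via SVD of
#' the cross-covariance of the centred point sets. A reflection solution is
#' corrected by flipping the sign of the smallest singular direction, so the
#' result is always a proper rotation (det = +1); no scaling is estimated
#' (both modalities are assumed metrically calibrated).
#'
#' @param moving,fixed matched `fiducial_set`s (same order, equal counts).
#' @return a `rigid_transform` mapping moving-frame to fixed-frame mm.
#' @export
estimate_rigid <- function(moving, fixed) {
  stopifnot(inherits(moving, "fiducial_set"), inherits(fixed, "fiducial_set"))
  M <- moving$points
  F_ <- fixed$points
  if (nrow(M) != nrow(F_))
    stop("point counts differ", call. = FALSE)
  cm <- colMeans(M)
  cf <- colMeans(F_)
  Mc <- sweep(M, 2, cm)
  Fc <- sweep(F_, 2, cf)
  sv <- svd(crossprod(Mc, Fc))  # H = sum m_c f_c'
  if (sv$d[2] <= 1e-12 * max(sv$d[1], .Machine$double.eps))
    stop("degenerate (collinear) fiducial configuration", call. = FALSE)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  # polish orthogonality to keep the constructor's 1e-9 contract
  pol <- svd(R)
  R <- pol$u %*% t(pol$v)
  rigid_transform(R, cf - as.vector(R %*% cm))
}

#' Fiducial registration error (FRE)
#'
#' Root-mean-square residual distance between transformed moving landmarks
#' and their fixed counterparts; the standard quality-control metric
#' reported for every registration.
#'
#' @param t a `rigid_transform`.
#' @param moving,fixed matched `fiducial_set`s.
#' @return RMS residual in mm.
#' @export
fiducial_registration_error <- function(t, moving, fixed) {
  res <- apply_rigid(t, moving$points) - fixed$points
  sqrt(mean(rowSums(res^2)))
}

#' Resample a binary mask onto another grid through a rigid transform
#'
#' Pulls a CT-grid mask back onto the target (MPI) grid: each target voxel
#' centre is mapped through `t` (moving/target frame to mask frame) and
#' takes the value of the nearest mask voxel. Nearest-neighbour sampling
#' keeps the output strictly binary; MPI intensities are never interpolated,
#' so ratio sums are unbiased.
#'
#' @param mask logical 3D array on `mask_grid`.
#' @param mask_grid `volume3d` (or geometry list) the mask lives on.
#' @param t `rigid_transform` mapping target-frame mm to mask-frame mm.
#' @param target `volume3d` defining the output grid.
#' @return logical array on the target grid; attribute `empty` is `TRUE`
#'   (with a warning) if the transform maps the mask fully outside the
#'   target grid.
#' @export
resample_mask_to_grid <- function(mask, mask_grid, t, target) {
  stopifnot(is.array(mask), inherits(t, "rigid_transform"),
            inherits(target, "volume3d"))
  d <- dim(target$data)
  ca <- coordinate_arrays(target)
  pts <- cbind(as.vector(ca$x), as.vector(ca$y), as.vector(ca$z))
  mapped <- apply_rigid(t, pts)
  idx <- round(world_to_index(mask_grid, mapped))
  dm <- dim(mask)
  inb <- idx[, 1] >= 1 & idx[, 1] <= dm[1] &
    idx[, 2] >= 1 & idx[, 2] <= dm[2] &
    idx[, 3] >= 1 & idx[, 3] <= dm[3]
  out <- rep(FALSE, prod(d))
  if (any(inb))
    out[inb] <- mask[idx[inb, , drop = FALSE]] != 0
  out <- array(out, d)
  if (!any(out) && any(mask != 0)) {
    warning("resampled mask is empty: transform maps the mask outside the target grid")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Read and write rigid transforms as JSON
#'
#' The JSON stores the rotation row-major, the translation in mm, and
#' optionally the fiducial registration error, so registrations are
#' auditable.
#' @param t a `rigid_transform`.
#' @param path JSON file path.
#' @param fre_mm optional FRE to record.
#' @export
write_transform <- function(t, path, fre_mm = NULL) {
  obj <- list(rotation_row_major = as.vector(t(t$rotation)),
              translation_mm = t$translation)
  if (!is.null(fre_mm)) obj$fre_mm <- fre_mm
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  t <- rigid_transform(matrix(obj$rotation_row_major, 3, 3, byrow = TRUE),
                       obj$translation_mm)
  attr(t, "fre_mm") <- obj$fre_mm
  t
}

#' Read and write fiducial coordinate tables (CSV: label,x_mm,y_mm,z_mm)
#' @param fs a `fiducial_set`.
#' @param path CSV path.
#' @param frame frame label on read.
#' @export
write_fiducial_csv <- function(fs, path) {
  write.csv(data.frame(label = fs$labels, x_mm = fs$points[, 1],
                       y_mm = fs$points[, 2], z_mm = fs$points[, 3]),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fiducial_csv
#' @export
read_fiducial_csv <- function(path, frame = "CT") {
  tab <- read.csv(path)
  fiducial_set(as.matrix(tab[, c("x_mm", "y_mm", "z_mm")]),
               labels = tab$label, frame = frame)
}
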