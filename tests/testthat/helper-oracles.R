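# Independent oracles and shared fixtures, kept free of the code paths they
# check.

# Compact phantom (same mm-scale scene on a coarser grid) for unit tests.
small_config <- function(...) {
  phantom_config(grid_shape = c(72L, 72L, 96L),
                 voxel_spacing_mm = c(0.4, 0.4, 0.4), ...)
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Exact two-sided Mann-Whitney p by full enumeration of C(n1+n2, n1) group
# labelings (midranks for generality).
enum_mann_whitney_p <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - offset
  labelings <- utils::combn(length(pooled), n1)
  us <- apply(labelings, 2, function(ix) sum(r[ix]) - offset)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

euler_zyx <- function(a, b, c) {
  Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(c), sin(c), 0, -sin(c), cos(c)), 3, 3)
  Rz %*% Ry %*% Rx
}

# Brute-force rigid fit: coarse-to-fine grid search over ZYX Euler angles
# (translation solved in closed form per rotation via centroids), refined
# below 1e-3 rad. Independent of the SVD estimator it cross-checks.
brute_force_rigid <- function(moving, fixed, final_step = 2e-4) {
  Mc <- scale(moving, center = TRUE, scale = FALSE)
  Fc <- scale(fixed, center = TRUE, scale = FALSE)
  sse <- function(p) {
    R <- euler_zyx(p[1], p[2], p[3])
    sum((Mc %*% t(R) - Fc)^2)
  }
  best <- NULL
  best_val <- Inf
  for (a in seq(-pi, pi, by = 0.25))
    for (b in seq(-pi / 2, pi / 2, by = 0.25))
      for (c in seq(-pi, pi, by = 0.25)) {
        v <- sse(c(a, b, c))
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
  step <- 0.25
  while (step > final_step) {
    step <- step / 4
    grid <- expand.grid(a = best[1] + step * (-4:4),
                        b = best[2] + step * (-4:4),
                        c = best[3] + step * (-4:4))
    vals <- apply(grid, 1, sse)
    best_val <- min(vals)
    best <- as.numeric(grid[which.min(vals), ])
  }
  R <- euler_zyx(best[1], best[2], best[3])
  list(rotation = R,
       translation = colMeans(fixed) - as.vector(R %*% colMeans(moving)),
       sse = best_val)
}

rotation_angle_between <- function(R1, R2) {
  c_ang <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(min(1, max(-1, c_ang)))
}

random_rotation <- function() {
  qr_res <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
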