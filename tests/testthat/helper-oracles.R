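# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (per-pixel loops, literal refits, pseudoinverse)
# so they share no code with the implementation they check.

# Brute-force Gaussian splatting: loop over every pixel and every voxel.
brute_force_compound <- function(frames, spec, sigma, trunc = 2) {
  nvox <- prod(spec$dims)
  wv <- numeric(nvox)
  w <- numeric(nvox)
  centers <- voxel_centers_oracle(spec)
  r <- trunc * sigma
  for (frm in frames) {
    pos <- pixel_world_positions(frm)
    vals <- as.vector(frm$swv)
    for (i in seq_along(vals)) {
      if (is.na(vals[i])) next
      d2 <- (centers[, 1] - pos[i, 1])^2 + (centers[, 2] - pos[i, 2])^2 +
        (centers[, 3] - pos[i, 3])^2
      hit <- d2 <= r^2
      wk <- exp(-d2[hit] / (2 * sigma^2))
      wv[hit] <- wv[hit] + wk * vals[i]
      w[hit] <- w[hit] + wk
    }
  }
  out <- ifelse(w > 1e-12, wv / w, NA_real_)
  list(values = array(out, spec$dims), weights = array(w, spec$dims))
}

# Voxel centers recomputed from first principles (x fastest).
voxel_centers_oracle <- function(spec) {
  n <- prod(spec$dims)
  idx <- seq_len(n) - 1L
  ix <- idx %% spec$dims[1]
  iy <- (idx %/% spec$dims[1]) %% spec$dims[2]
  iz <- idx %/% (spec$dims[1] * spec$dims[2])
  cbind(spec$origin[1] + ix * spec$spacing[1],
        spec$origin[2] + iy * spec$spacing[2],
        spec$origin[3] + iz * spec$spacing[3])
}

# OLS via SVD pseudoinverse, with textbook-formula standard errors.
pinv_ols <- function(y, X) {
  s <- svd(X)
  beta <- s$v %*% ((t(s$u) %*% y) / s$d)
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  covb <- s$v %*% diag(1 / s$d^2, length(s$d)) %*% t(s$v) * sigma2
  list(beta = as.vector(beta), se = sqrt(diag(covb)))
}

# Literal leave-one-out: refit n times, predict the held-out point.
literal_loo_press <- function(y, x) {
  x <- as.data.frame(x)
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    Xi <- cbind(1, as.matrix(x[-i, , drop = FALSE]))
    beta <- qr.coef(qr(Xi), y[-i])
    pred <- sum(c(1, as.numeric(x[i, ])) * beta)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Reference xyz Euler rotation (Rz Ry Rx), built from scratch.
euler_rot_oracle <- function(ax, ay, az) {
  cx <- cos(ax); sx <- sin(ax); cy <- cos(ay); sy <- sin(ay)
  cz <- cos(az); sz <- sin(az)
  rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1)) %*%
    rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy)) %*%
    rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
}

# Hand-built frame: value matrix + pose, for constructing tiny sweeps.
make_frame <- function(swv, pose = rigid_pose(), pixel_spacing = 1,
                       bmode = NULL) {
  if (is.null(bmode)) bmode <- array(1, dim(swv))
  frm <- list(bmode = bmode, swv = swv, pixel_spacing = pixel_spacing,
              pose = pose)
  class(frm) <- "sweep_frame"
  frm
}

# Small default phantom + noise-free sweep used by several tests.
small_phantom <- function(...) {
  tendon_phantom(proximal_landmark = c(0, 0, 0),
                 distal_landmark = c(45, 0, 0),
                 radii = c(8, 2.5), ...)
}

noise_free_sweep <- function(phantom, n_frames = 11, pixel_spacing = 0.6,
                             seed = 1) {
  traj <- linear_sweep_trajectory(phantom, n_frames, pixel_spacing,
                                  margin = 2)
  simulate_sweep(phantom, sweep_config(traj, pixel_spacing, seed = seed))
}
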