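# Digital patellar-tendon phantom and freehand sweep simulation.
#
# The phantom is a tube with elliptical cross-section around the straight
# (optionally bowed) line between the two insertion landmarks. Its shear
# wave velocity (SWV) field is piecewise constant in three axial regions —
# proximal, mid-portion, distal — separated by cuts 10 mm from each
# insertion, the same geometry the regional analysis uses.

#' Physical SWV bounds (m/s) used throughout the package
#'
#' Shear wave velocities outside this range are treated as non-physical;
#' simulated values are clipped to it and parsers reject values outside it.
#' @return numeric length-2 vector, lower and upper bound in m/s.
#' @export
swv_bounds <- function() c(0.5, 16)

#' Construct a digital tendon phantom
#'
#' The tendon solid is an elliptical-cross-section tube around the
#' centerline from `proximal_landmark` to `distal_landmark`; a single `bow`
#' parameter (mm) optionally bends the centerline into a shallow circular
#' arc in the plane of the first transverse axis. The true SWV field takes
#' one value per axial region (cuts at `cut_distance` mm from each
#' landmark) inside the tendon and `background_swv` outside.
#'
#' @param proximal_landmark,distal_landmark 3-vectors, mm, world
#'   coordinates of the patellar apex and tibial tuberosity insertions.
#'   Must be more than `2 * cut_distance` apart so all three regions exist.
#' @param radii length-2 positive vector, mm: semi-axes of the elliptical
#'   cross-section (first = width direction, second = thickness direction).
#' @param swv_true named numeric vector with entries `proximal`, `mid`,
#'   `distal` (m/s), the regional plateau values.
#' @param background_swv SWV (m/s) outside the tendon; default 2.0, chosen
#'   distinctly softer than tendon so mask leakage is detectable.
#' @param bmode_tendon_intensity,bmode_background_intensity B-mode
#'   intensities (unitless, >= 0) inside/outside the tendon.
#' @param bow centerline bow (mm), sagitta of the arc at mid-length; 0
#'   gives a straight centerline.
#' @param cut_distance axial distance (mm) of each region cut from its
#'   insertion landmark; default 10.
#' @return an object of class `tendon_phantom`.
#' @examples
#' ph <- tendon_phantom()
#' swv_at(ph, rbind(c(23, 0, 0), c(5, 0, 0), c(0, 40, 0)))
#' @export
tendon_phantom <- function(proximal_landmark = c(0, 0, 0),
                           distal_landmark = c(46, 0, 0),
                           radii = c(12, 2.5),
                           swv_true = c(proximal = 10, mid = 9, distal = 11),
                           background_swv = 2.0,
                           bmode_tendon_intensity = 1.0,
                           bmode_background_intensity = 0.1,
                           bow = 0,
                           cut_distance = 10) {
  proximal_landmark <- as.numeric(proximal_landmark)
  distal_landmark <- as.numeric(distal_landmark)
  stopifnot(length(proximal_landmark) == 3, length(distal_landmark) == 3,
            all(is.finite(proximal_landmark)), all(is.finite(distal_landmark)))
  L <- sqrt(sum((distal_landmark - proximal_landmark)^2))
  if (L <= 2 * cut_distance)
    stop("landmark separation must exceed ", 2 * cut_distance,
         " mm (both end regions plus a nonempty mid-portion must exist)")
  radii <- as.numeric(radii)
  if (length(radii) == 1) radii <- rep(radii, 2)
  stopifnot(length(radii) == 2, all(radii > 0))
  swv_true <- swv_true[c("proximal", "mid", "distal")]
  if (anyNA(swv_true))
    stop("swv_true needs named entries 'proximal', 'mid', 'distal'")
  b <- swv_bounds()
  if (any(swv_true < b[1] | swv_true > b[2]))
    stop("swv_true outside physical bounds [", b[1], ", ", b[2], "] m/s")
  stopifnot(background_swv >= b[1], background_swv <= b[2],
            bmode_tendon_intensity >= 0, bmode_background_intensity >= 0,
            is.finite(bow))

  axis <- (distal_landmark - proximal_landmark) / L
  # transverse frame: v1 = width direction, v2 = thickness direction
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  v2 <- ref - sum(ref * axis) * axis
  v2 <- v2 / sqrt(sum(v2^2))
  v1 <- c(axis[2] * v2[3] - axis[3] * v2[2],
          axis[3] * v2[1] - axis[1] * v2[3],
          axis[1] * v2[2] - axis[2] * v2[1])

  structure(list(proximal_landmark = proximal_landmark,
                 distal_landmark = distal_landmark,
                 length = L, axis = axis, v1 = v1, v2 = v2,
                 radii = radii, swv_true = swv_true,
                 background_swv = background_swv,
                 bmode_tendon_intensity = bmode_tendon_intensity,
                 bmode_background_intensity = bmode_background_intensity,
                 bow = bow, cut_distance = cut_distance),
            class = "tendon_phantom")
}

#' @export
print.tendon_phantom <- function(x, ...) {
  cat("Digital tendon phantom\n")
  cat(sprintf("  length        : %.1f mm (landmark distance)\n", x$length))
  cat(sprintf("  cross-section : %.1f x %.1f mm semi-axes%s\n",
              x$radii[1], x$radii[2],
              if (x$bow != 0) sprintf(", bow %.1f mm", x$bow) else ""))
  cat(sprintf("  SWV (m/s)     : proximal %.2f | mid %.2f | distal %.2f | background %.2f\n",
              x$swv_true["proximal"], x$swv_true["mid"], x$swv_true["distal"],
              x$background_swv))
  invisible(x)
}

# Axial coordinate s (mm from proximal landmark) and transverse elliptical
# radius rho (<= 1 inside) for an n x 3 matrix of points. The bow displaces
# the centerline by bow * 4*s*(L-s)/L^2 along v2 (parabolic sagitta).
phantom_coords <- function(phantom, points) {
  points <- rbind(points)
  d <- sweep(points, 2, phantom$proximal_landmark)
  s <- as.vector(d %*% phantom$axis)
  off <- phantom$bow * 4 * s * (phantom$length - s) / phantom$length^2
  p1 <- as.vector(d %*% phantom$v1)
  p2 <- as.vector(d %*% phantom$v2) - off
  rho <- sqrt((p1 / phantom$radii[1])^2 + (p2 / phantom$radii[2])^2)
  list(s = s, rho = rho)
}

#' Classify points into phantom regions
#'
#' @param phantom a [tendon_phantom()].
#' @param points n x 3 matrix (or 3-vector) of world coordinates, mm.
#' @return integer vector: 0 = background, 1 = proximal, 2 = mid,
#'   3 = distal. Ties at the cut planes go to the end regions
#'   (`s <= cut` proximal, `s >= L - cut` distal).
#' @export
phantom_region <- function(phantom, points) {
  co <- phantom_coords(phantom, points)
  inside <- co$s >= 0 & co$s <= phantom$length & co$rho <= 1
  cut <- phantom$cut_distance
  reg <- integer(length(co$s))
  reg[inside] <- 2L
  reg[inside & co$s <= cut] <- 1L
  reg[inside & co$s >= phantom$length - cut] <- 3L
  reg
}

#' True SWV of the phantom at given points
#'
#' Total on finite points: returns the regional plateau value inside the
#' tendon solid and `background_swv` outside.
#'
#' @inheritParams phantom_region
#' @return numeric vector of SWV values, m/s.
#' @export
swv_at <- function(phantom, points) {
  reg <- phantom_region(phantom, points)
  vals <- c(phantom$background_swv, unname(phantom$swv_true))
  vals[reg + 1L]
}

bmode_at <- function(phantom, points) {
  reg <- phantom_region(phantom, points)
  ifelse(reg > 0L, phantom$bmode_tendon_intensity,
         phantom$bmode_background_intensity)
}

#' Construct a rigid pose (frame-to-world transform)
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation 3-vector, mm.
#' @param tol orthonormality tolerance (default 1e-9).
#' @return object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0),
                       tol = 1e-9) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3, all(is.finite(rotation)),
            all(is.finite(translation)))
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > tol)
    stop(sprintf("rotation not orthonormal: max |R'R - I| = %.3g > %.3g",
                 err, tol))
  dt <- det(rotation)
  if (abs(dt - 1) > tol)
    stop(sprintf("rotation determinant %.9f != +1 (reflection?)", dt))
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat("Rigid pose (frame -> world)\n  t =",
      sprintf("%.3f", x$translation), "mm\n")
  print(round(x$rotation, 6))
  invisible(x)
}

# Rotation from small xyz Euler angles (radians); used for pose jitter.
euler_rotation <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Nominal linear sweep trajectory over a phantom
#'
#' Frames are parallel to the world x-y plane (probe frame mapped by an
#' identity rotation) and swept along z through the tendon thickness; the
#' frame is sized to cover the tendon plus `margin` mm on all sides. This
#' stands in for the freehand scan of a tracked transducer.
#'
#' @param phantom a [tendon_phantom()] whose axis is close to the world x
#'   axis (the default phantom).
#' @param n_frames number of frames in the sweep.
#' @param pixel_spacing pixel pitch, mm.
#' @param margin extra coverage beyond the tendon extent, mm.
#' @return list with `poses` (list of [rigid_pose()]), `frame_rows`,
#'   `frame_cols`.
#' @export
linear_sweep_trajectory <- function(phantom, n_frames = 15,
                                    pixel_spacing = 0.5, margin = 3) {
  x0 <- min(phantom$proximal_landmark[1], phantom$distal_landmark[1]) - margin
  x1 <- max(phantom$proximal_landmark[1], phantom$distal_landmark[1]) + margin
  y0 <- -phantom$radii[1] - margin
  y1 <- phantom$radii[1] + margin
  z_span <- phantom$radii[2] + margin / 2
  zs <- if (n_frames == 1) 0 else seq(-z_span, z_span, length.out = n_frames)
  frame_cols <- ceiling((x1 - x0) / pixel_spacing) + 1L
  frame_rows <- ceiling((y1 - y0) / pixel_spacing) + 1L
  poses <- lapply(zs, function(z) rigid_pose(diag(3), c(x0, y0, z)))
  list(poses = poses, frame_rows = frame_rows, frame_cols = frame_cols)
}

#' Sweep configuration
#'
#' @param trajectory nominal poses, as returned by
#'   [linear_sweep_trajectory()] or a list with the same fields.
#' @param pixel_spacing pixel pitch, mm.
#' @param pose_noise_sd length-2 vector: SD of the rotational jitter
#'   (degrees, per Euler axis) and translational jitter (mm, per axis)
#'   applied independently to each frame's nominal pose.
#' @param swv_noise_sd additive Gaussian SWV noise per pixel, m/s.
#' @param bmode_noise_sd additive Gaussian B-mode noise per pixel.
#' @param invalid_fraction fraction of SWV pixels voided at random (the
#'   device's invalid areas); default 0.
#' @param seed integer RNG seed; the sweep is bitwise reproducible given it.
#' @return object of class `sweep_config`.
#' @export
sweep_config <- function(trajectory, pixel_spacing = 0.5,
                         pose_noise_sd = c(0, 0), swv_noise_sd = 0,
                         bmode_noise_sd = 0, invalid_fraction = 0,
                         seed = 1L) {
  stopifnot(length(trajectory$poses) >= 1, pixel_spacing > 0,
            length(pose_noise_sd) == 2, all(pose_noise_sd >= 0),
            swv_noise_sd >= 0, bmode_noise_sd >= 0,
            invalid_fraction >= 0, invalid_fraction < 1)
  structure(list(trajectory = trajectory, pixel_spacing = pixel_spacing,
                 pose_noise_sd = as.numeric(pose_noise_sd),
                 swv_noise_sd = swv_noise_sd,
                 bmode_noise_sd = bmode_noise_sd,
                 invalid_fraction = invalid_fraction,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

#' Simulate a pose-tracked 2D SWE sweep over a phantom
#'
#' Each frame's pose is its nominal trajectory pose perturbed by Gaussian
#' pose jitter; each SWV pixel samples the phantom's true field at the
#' pixel-center world position plus additive Gaussian noise, clipped to
#' [swv_bounds()]; B-mode pixels sample the intensity field likewise
#' (floored at 0). Invalid SWV pixels are `NA`.
#'
#' @param phantom a [tendon_phantom()].
#' @param cfg a [sweep_config()].
#' @return list of `sweep_frame` objects, each with fields `bmode`
#'   (rows x cols matrix), `swv` (matrix, m/s, `NA` = invalid),
#'   `pixel_spacing` and `pose`.
#' @export
simulate_sweep <- function(phantom, cfg) {
  stopifnot(inherits(phantom, "tendon_phantom"), inherits(cfg, "sweep_config"))
  set.seed(cfg$seed)
  rows <- cfg$trajectory$frame_rows
  cols <- cfg$trajectory$frame_cols
  b <- swv_bounds()
  any_tendon <- FALSE
  frames <- lapply(cfg$trajectory$poses, function(nominal) {
    pose <- nominal
    if (any(cfg$pose_noise_sd > 0)) {
      ang <- rnorm(3, 0, cfg$pose_noise_sd[1]) * pi / 180
      R <- euler_rotation(ang[1], ang[2], ang[3]) %*% nominal$rotation
      t <- nominal$translation + rnorm(3, 0, cfg$pose_noise_sd[2])
      pose <- rigid_pose(R, t, tol = 1e-6)
    }
    frm <- list(bmode = matrix(0, rows, cols), swv = matrix(0, rows, cols),
                pixel_spacing = cfg$pixel_spacing, pose = pose)
    class(frm) <- "sweep_frame"
    pos <- pixel_world_positions(frm)
    reg <- phantom_region(phantom, pos)
    any_tendon <<- any_tendon || any(reg > 0L)
    vals <- c(phantom$background_swv, unname(phantom$swv_true))[reg + 1L]
    if (cfg$swv_noise_sd > 0) vals <- vals + rnorm(length(vals), 0, cfg$swv_noise_sd)
    vals <- pmin(pmax(vals, b[1]), b[2])
    bm <- ifelse(reg > 0L, phantom$bmode_tendon_intensity,
                 phantom$bmode_background_intensity)
    if (cfg$bmode_noise_sd > 0) bm <- bm + rnorm(length(bm), 0, cfg$bmode_noise_sd)
    bm <- pmax(bm, 0)
    if (cfg$invalid_fraction > 0)
      vals[stats::runif(length(vals)) < cfg$invalid_fraction] <- NA_real_
    # vals is ordered like pixel_world_positions: column-major, row fastest
    frm$swv <- matrix(vals, rows, cols)
    frm$bmode <- matrix(bm, rows, cols)
    frm
  })
  if (!any_tendon)
    stop("empty sweep: no frame intersects the tendon")
  frames
}

#' @export
print.sweep_frame <- function(x, ...) {
  cat(sprintf("SWE sweep frame: %d x %d px at %.3g mm, %d invalid SWV px\n",
              nrow(x$swv), ncol(x$swv), x$pixel_spacing, sum(is.na(x$swv))))
  invisible(x)
}
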