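# Weighted-average compounding of pose-tracked 2D frames into 3D volumes.
#
# Each valid pixel is projected to world coordinates through its frame's
# rigid pose and deposits (weight * value, weight) into nearby voxels; the
# final voxel value is the weight-normalized average. The weighting kernel
# is Gaussian in pixel-to-voxel-center distance with sigma equal to the
# voxel spacing, truncated at 2 sigma — a standard forward-splatting
# choice. Voxels receiving (almost) no weight stay undefined (NA).

#' Voxel grid specification
#'
#' World coordinates are right-handed, in mm; voxel `(0,0,0)` has its
#' center at `origin`, and the grid is indexed (x, y, z) with x fastest.
#'
#' @param origin 3-vector, mm: world position of the first voxel center.
#' @param spacing voxel spacing, mm; scalar (isotropic) or per-axis.
#' @param dims integer 3-vector of voxel counts per axis.
#' @return object of class `voxel_grid_spec`.
#' @export
voxel_grid_spec <- function(origin, spacing, dims) {
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  dims <- as.integer(dims)
  stopifnot(length(origin) == 3, length(spacing) == 3, length(dims) == 3,
            all(is.finite(origin)), all(spacing > 0), all(dims >= 1))
  structure(list(origin = origin, spacing = spacing, dims = dims),
            class = "voxel_grid_spec")
}

#' @export
print.voxel_grid_spec <- function(x, ...) {
  cat(sprintf("Voxel grid: %d x %d x %d at (%.3g, %.3g, %.3g) mm, origin (%.3g, %.3g, %.3g)\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) && max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$spacing - b$spacing)) <= tol
}

# World coordinates of all voxel centers, dims-prod x 3, x fastest.
voxel_centers <- function(spec) {
  ix <- seq_len(spec$dims[1]) - 1L
  iy <- seq_len(spec$dims[2]) - 1L
  iz <- seq_len(spec$dims[3]) - 1L
  g <- expand.grid(x = ix, y = iy, z = iz, KEEP.OUT.ATTRS = FALSE)
  cbind(spec$origin[1] + g$x * spec$spacing[1],
        spec$origin[2] + g$y * spec$spacing[2],
        spec$origin[3] + g$z * spec$spacing[3])
}

new_voxel_volume <- function(spec, values, weights, finalized = FALSE,
                             eps = 1e-12) {
  structure(list(spec = spec, values = values, weights = weights,
                 finalized = finalized, eps = eps),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  nd <- if (x$finalized) sum(!is.na(x$values)) else sum(x$weights > x$eps)
  cat(sprintf("Voxel volume (%s): %d x %d x %d, %d defined voxels\n",
              if (x$finalized) "finalized" else "accumulating",
              x$spec$dims[1], x$spec$dims[2], x$spec$dims[3], nd))
  if (x$finalized && nd > 0)
    cat(sprintf("  value range: [%.3f, %.3f]\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' World positions of all pixel centers of a frame
#'
#' Pixel `(r, c)` (0-based) maps to
#' `pose$rotation %*% c(c * spacing, r * spacing, 0) + pose$translation`
#' — the frame plane is the x-y plane of the probe frame, pixel centers
#' define the positions.
#'
#' @param frame a `sweep_frame` (see [simulate_sweep()]).
#' @return n x 3 matrix of world coordinates (mm), ordered column-major
#'   over the pixel grid (row index fastest), matching `as.vector(frame$swv)`.
#' @export
pixel_world_positions <- function(frame) {
  rows <- nrow(frame$swv)
  cols <- ncol(frame$swv)
  r <- rep(seq_len(rows) - 1L, times = cols)
  c <- rep(seq_len(cols) - 1L, each = rows)
  local <- cbind(c * frame$pixel_spacing, r * frame$pixel_spacing, 0)
  sweep(local %*% t(frame$pose$rotation), 2, frame$pose$translation, `+`)
}

#' Grid spec covering a list of frames
#'
#' Bounding box of all pixel positions, padded by `pad` mm, at the given
#' spacing (default 0.5 mm isotropic).
#' @param frames list of sweep frames.
#' @param spacing voxel spacing, mm.
#' @param pad padding, mm.
#' @return a [voxel_grid_spec()].
#' @export
grid_spec_for_frames <- function(frames, spacing = 0.5, pad = 1) {
  rng <- sapply(1:3, function(a) {
    r <- range(sapply(frames, function(f) range(pixel_world_positions(f)[, a])))
    r + c(-pad, pad)
  })
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  dims <- pmax(1L, as.integer(floor((rng[2, ] - rng[1, ]) / spacing)) + 1L)
  voxel_grid_spec(rng[1, ], spacing, dims)
}

#' Compound 2D frames into 3D SWE and B-mode volumes
#'
#' Projects every pixel into world space and accumulates a Gaussian
#' forward-splatting weighted average on the voxel grid. Invalid SWV
#' pixels (`NA`) carry zero weight and are skipped (not zero-filled).
#' Frame order does not affect the result beyond floating-point
#' associativity.
#'
#' @param frames nonempty list of sweep frames.
#' @param spec a [voxel_grid_spec()]; default covers the frames at 0.5 mm.
#' @param kernel list with `sigma` (mm; default = mean voxel spacing) and
#'   `trunc` (truncation radius in sigmas; default 2).
#' @param finalize normalize and mark undefined voxels (default TRUE).
#' @return list with elements `swe` and `bmode`, both `voxel_volume`.
#' @export
compound <- function(frames, spec = grid_spec_for_frames(frames),
                     kernel = list(), finalize = TRUE) {
  if (length(frames) < 1) stop("empty frame list")
  sigma <- if (is.null(kernel$sigma)) mean(spec$spacing) else kernel$sigma
  trunc <- if (is.null(kernel$trunc)) 2 else kernel$trunc
  stopifnot(sigma > 0, trunc > 0)
  nvox <- prod(spec$dims)
  acc <- list(swe = list(wv = numeric(nvox), w = numeric(nvox)),
              bmode = list(wv = numeric(nvox), w = numeric(nvox)))
  lo <- spec$origin - trunc * sigma
  hi <- spec$origin + (spec$dims - 1L) * spec$spacing + trunc * sigma
  touched <- FALSE
  for (frm in frames) {
    pos <- pixel_world_positions(frm)
    inb <- pos[, 1] >= lo[1] & pos[, 1] <= hi[1] &
           pos[, 2] >= lo[2] & pos[, 2] <= hi[2] &
           pos[, 3] >= lo[3] & pos[, 3] <= hi[3]
    if (!any(inb)) next
    touched <- TRUE
    p <- pos[inb, , drop = FALSE]
    sv <- as.vector(frm$swv)[inb]
    bm <- as.vector(frm$bmode)[inb]
    ones <- rep(1, nrow(p))
    .splat_accumulate(p, sv, ones, spec$origin, spec$spacing, spec$dims,
                      sigma, trunc * sigma, acc$swe$wv, acc$swe$w)
    .splat_accumulate(p, bm, ones, spec$origin, spec$spacing, spec$dims,
                      sigma, trunc * sigma, acc$bmode$wv, acc$bmode$w)
  }
  if (!touched) warning("no overlap: grid spec covers no pixel")
  mk <- function(a) {
    vol <- new_voxel_volume(spec, array(a$wv, spec$dims), array(a$w, spec$dims))
    if (finalize) finalize_volume(vol) else vol
  }
  list(swe = mk(acc$swe), bmode = mk(acc$bmode))
}

#' Normalize an accumulated volume and mark undefined voxels
#'
#' Divides accumulated weighted sums by the weights; voxels with total
#' weight <= `eps` become `NA` (undefined) and are excluded from all
#' downstream statistics. Idempotent.
#'
#' @param volume a `voxel_volume`.
#' @return finalized `voxel_volume`.
#' @export
finalize_volume <- function(volume) {
  stopifnot(inherits(volume, "voxel_volume"))
  if (volume$finalized) return(volume)
  def <- volume$weights > volume$eps
  vals <- array(NA_real_, volume$spec$dims)
  vals[def] <- volume$values[def] / volume$weights[def]
  new_voxel_volume(volume$spec, vals, volume$weights, finalized = TRUE,
                   eps = volume$eps)
}

#' Count of defined voxels
#' @param volume a finalized `voxel_volume`.
#' @return integer.
#' @export
defined_count <- function(volume) {
  stopifnot(volume$finalized)
  sum(!is.na(volume$values))
}
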