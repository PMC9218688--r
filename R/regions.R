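# Landmark-based regional analysis of a masked SWE volume.
#
# The tendon mask restricts the volume to tendon voxels; two cuts,
# perpendicular to the straight proximal-to-distal landmark axis and
# placed 10 mm from each insertion, split it into proximal, mid-portion
# and distal regions. Regional summaries are arithmetic means over the
# defined voxels of each region.

#' Construct a tendon mask
#'
#' @param spec the [voxel_grid_spec()] the mask lives on.
#' @param mask logical 3D array on `spec` (TRUE = tendon).
#' @param proximal_landmark,distal_landmark insertion landmarks, mm world
#'   coordinates (patellar apex / tibial tuberosity).
#' @return object of class `tendon_mask`.
#' @export
tendon_mask <- function(spec, mask, proximal_landmark, distal_landmark) {
  stopifnot(inherits(spec, "voxel_grid_spec"),
            identical(dim(mask), as.integer(spec$dims)))
  mask <- array(as.logical(mask), spec$dims)
  if (!any(mask)) stop("empty mask")
  proximal_landmark <- as.numeric(proximal_landmark)
  distal_landmark <- as.numeric(distal_landmark)
  stopifnot(all(is.finite(proximal_landmark)), all(is.finite(distal_landmark)),
            length(proximal_landmark) == 3, length(distal_landmark) == 3)
  structure(list(spec = spec, mask = mask,
                 proximal_landmark = proximal_landmark,
                 distal_landmark = distal_landmark),
            class = "tendon_mask")
}

#' @export
print.tendon_mask <- function(x, ...) {
  cat(sprintf("Tendon mask: %d voxels, landmark separation %.1f mm\n",
              sum(x$mask),
              sqrt(sum((x$distal_landmark - x$proximal_landmark)^2))))
  invisible(x)
}

#' Ground-truth mask of a phantom on a voxel grid
#'
#' Voxel centers inside the phantom solid, with the phantom's landmarks.
#' @param phantom a [tendon_phantom()].
#' @param spec a [voxel_grid_spec()].
#' @return a [tendon_mask()].
#' @export
phantom_mask <- function(phantom, spec) {
  reg <- phantom_region(phantom, voxel_centers(spec))
  tendon_mask(spec, array(reg > 0L, spec$dims),
              phantom$proximal_landmark, phantom$distal_landmark)
}

#' Mask an SWE volume to the tendon
#'
#' Voxels outside the mask become undefined; inside-mask voxels are
#' unchanged.
#'
#' @param swe a finalized `voxel_volume`.
#' @param mask a [tendon_mask()] on the same grid.
#' @return masked `voxel_volume`.
#' @export
apply_mask <- function(swe, mask) {
  stopifnot(inherits(swe, "voxel_volume"), inherits(mask, "tendon_mask"))
  if (!swe$finalized) swe <- finalize_volume(swe)
  if (!same_grid(swe$spec, mask$spec)) stop("grid mismatch between volume and mask")
  vals <- swe$values
  vals[!mask$mask] <- NA_real_
  w <- swe$weights
  w[!mask$mask] <- 0
  new_voxel_volume(swe$spec, vals, w, finalized = TRUE, eps = swe$eps)
}

#' Partition a tendon mask into proximal / mid / distal regions
#'
#' Each in-mask voxel is labeled by the scalar projection `s` of its center
#' onto the unit vector from the proximal to the distal landmark, measured
#' from the proximal landmark: `s <= cut_distance` is proximal,
#' `s >= L - cut_distance` is distal, otherwise mid (L = landmark
#' distance). Cut planes are perpendicular to the landmark axis; boundary
#' voxels go to the end regions (deterministic `<=` / `>=` tie-break).
#'
#' @param mask a [tendon_mask()].
#' @param cut_distance distance of each cut from its insertion, mm
#'   (default 10).
#' @return integer 3D array: 0 outside mask, 1 proximal, 2 mid, 3 distal.
#' @export
partition_regions <- function(mask, cut_distance = 10) {
  stopifnot(inherits(mask, "tendon_mask"), cut_distance >= 0)
  d <- mask$distal_landmark - mask$proximal_landmark
  L <- sqrt(sum(d^2))
  if (cut_distance > 0 && L <= 2 * cut_distance)
    stop("tendon too short for three regions: landmark separation ",
         sprintf("%.1f", L), " mm <= 2 x ", cut_distance, " mm")
  u <- d / L
  s <- as.vector(sweep(voxel_centers(mask$spec), 2,
                       mask$proximal_landmark) %*% u)
  lab <- integer(length(s))
  inm <- as.vector(mask$mask)
  lab[inm] <- 2L
  lab[inm & s <= cut_distance] <- 1L
  lab[inm & s >= L - cut_distance] <- 3L
  array(lab, mask$spec$dims)
}

#' Regional mean SWV summary
#'
#' Arithmetic means of the defined voxel values of each region, plus the
#' overall mean over all defined in-mask voxels (not the mean of the three
#' regional means), with voxel counts. An empty region is reported as `NA`
#' with a warning.
#'
#' @param swe masked, finalized `voxel_volume` (see [apply_mask()]).
#' @param labels region-label array from [partition_regions()].
#' @param mask the [tendon_mask()] (for landmark distance).
#' @return object of class `regional_swv`: fields `overall`, `proximal`,
#'   `mid`, `distal` (m/s), `counts`, `tendon_length` (mm).
#' @export
regional_means <- function(swe, labels, mask = NULL) {
  stopifnot(inherits(swe, "voxel_volume"), swe$finalized,
            identical(dim(labels), as.integer(swe$spec$dims)))
  vals <- as.vector(swe$values)
  lab <- as.vector(labels)
  def <- !is.na(vals) & lab > 0L
  reg_mean <- function(k) {
    v <- vals[def & lab == k]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  m <- c(proximal = reg_mean(1L), mid = reg_mean(2L), distal = reg_mean(3L))
  counts <- c(proximal = sum(def & lab == 1L), mid = sum(def & lab == 2L),
              distal = sum(def & lab == 3L))
  if (any(counts == 0))
    warning("empty region(s): ",
            paste(names(counts)[counts == 0], collapse = ", "),
            " — reported as NA and excluded downstream")
  overall <- if (any(def)) mean(vals[def]) else NA_real_
  tl <- if (!is.null(mask))
    sqrt(sum((mask$distal_landmark - mask$proximal_landmark)^2)) else NA_real_
  structure(list(overall = overall, proximal = m[["proximal"]],
                 mid = m[["mid"]], distal = m[["distal"]],
                 counts = counts, tendon_length = tl),
            class = "regional_swv")
}

#' @export
print.regional_swv <- function(x, ...) {
  cat("Regional mean SWV (m/s)\n")
  cat(sprintf("  overall  %6.3f  (%d voxels)\n", x$overall, sum(x$counts)))
  for (r in c("proximal", "mid", "distal"))
    cat(sprintf("  %-8s %6.3f  (%d voxels)\n", r, x[[r]], x$counts[[r]]))
  if (is.finite(x$tendon_length))
    cat(sprintf("  tendon length %.1f mm\n", x$tendon_length))
  invisible(x)
}

# Vectorized 6-neighbour flood fill; labels connected components of a
# logical 3D array. Returns integer array (0 = background).
label_components <- function(fg) {
  dims <- dim(fg)
  lab <- array(0L, dims)
  shift_or <- function(frontier) {
    out <- array(FALSE, dims)
    n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
    out[-1, , ] <- out[-1, , ] | frontier[-n1, , ]
    out[-n1, , ] <- out[-n1, , ] | frontier[-1, , ]
    out[, -1, ] <- out[, -1, ] | frontier[, -n2, ]
    out[, -n2, ] <- out[, -n2, ] | frontier[, -1, ]
    out[, , -1] <- out[, , -1] | frontier[, , -n3]
    out[, , -n3] <- out[, , -n3] | frontier[, , -1]
    out
  }
  k <- 0L
  repeat {
    seed <- which(fg & lab == 0L)
    if (length(seed) == 0) break
    k <- k + 1L
    frontier <- array(FALSE, dims)
    frontier[seed[1]] <- TRUE
    lab[seed[1]] <- k
    repeat {
      frontier <- shift_or(frontier) & fg & lab == 0L
      if (!any(frontier)) break
      lab[frontier] <- k
    }
  }
  lab
}

#' Threshold-based tendon segmentation of a B-mode volume
#'
#' Convenience segmentation for phantom data, where the tendon is brighter
#' than the background: thresholds the B-mode volume, keeps the largest
#' 6-connected component, and places the insertion landmarks at the
#' extremal component voxels along the component's first principal axis.
#' The axis sign is fixed so the proximal landmark is the endpoint with
#' the smaller x coordinate (the default phantom's proximal side).
#'
#' @param bmode finalized B-mode `voxel_volume`.
#' @param threshold intensity cut; default midpoint between the min and
#'   max defined intensities.
#' @return a [tendon_mask()].
#' @export
segment_bmode <- function(bmode, threshold = NULL) {
  stopifnot(inherits(bmode, "voxel_volume"))
  if (!bmode$finalized) bmode <- finalize_volume(bmode)
  vals <- bmode$values
  if (all(is.na(vals))) stop("no component above threshold: empty volume")
  if (is.null(threshold))
    threshold <- (min(vals, na.rm = TRUE) + max(vals, na.rm = TRUE)) / 2
  fg <- !is.na(vals) & vals > threshold
  if (!any(fg)) stop("no component above threshold")
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  comp <- lab == which.max(sizes)
  ctr <- voxel_centers(bmode$spec)[as.vector(comp), , drop = FALSE]
  cm <- colMeans(ctr)
  ax <- prcomp(ctr, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (ax[which.max(abs(ax))] < 0) ax <- -ax
  s <- as.vector(sweep(ctr, 2, cm) %*% ax)
  # centroid of the extremal end face (one voxel deep) rather than a
  # single corner voxel: stable against the tube's flat end caps
  tol <- min(bmode$spec$spacing)
  p1 <- colMeans(ctr[s <= min(s) + tol, , drop = FALSE])
  p2 <- colMeans(ctr[s >= max(s) - tol, , drop = FALSE])
  if (p1[1] <= p2[1]) tendon_mask(bmode$spec, comp, p1, p2)
  else tendon_mask(bmode$spec, comp, p2, p1)
}

#' Erode a tendon mask
#'
#' Removes in-mask voxels within `radius` mm of any out-of-mask voxel
#' (6-neighbour iterated erosion at voxel resolution). Used to evaluate
#' interior voxels away from partial-volume effects at the tendon surface.
#'
#' @param mask a [tendon_mask()].
#' @param radius erosion radius, mm.
#' @return eroded [tendon_mask()].
#' @export
erode_mask <- function(mask, radius) {
  steps <- ceiling(radius / min(mask$spec$spacing))
  m <- mask$mask
  dims <- dim(m)
  for (i in seq_len(steps)) {
    keep <- m
    n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
    keep[1, , ] <- FALSE; keep[n1, , ] <- FALSE
    keep[, 1, ] <- FALSE; keep[, n2, ] <- FALSE
    keep[, , 1] <- FALSE; keep[, , n3] <- FALSE
    keep[-1, , ] <- keep[-1, , ] & m[-n1, , ]
    keep[-n1, , ] <- keep[-n1, , ] & m[-1, , ]
    keep[, -1, ] <- keep[, -1, ] & m[, -n2, ]
    keep[, -n2, ] <- keep[, -n2, ] & m[, -1, ]
    keep[, , -1] <- keep[, , -1] & m[, , -n3]
    keep[, , -n3] <- keep[, , -n3] & m[, , -1]
    m <- keep
  }
  tendon_mask(mask$spec, m, mask$proximal_landmark, mask$distal_landmark)
}
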