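# File formats: NRRD volumes (canonical; text header + raw little-endian
# doubles), poses CSV, cohort CSV, landmarks JSON. All round-trips are
# lossless on the declared fields. NIfTI export is available through
# RNifti when installed.

#' Write a voxel volume as NRRD
#'
#' NRRD0004, `type: double`, `encoding: raw`, little endian, with spacing
#' and origin carried in `space directions` / `space origin`. Undefined
#' voxels are stored as NaN; the weight array is written alongside as
#' `<path>.weights.nrrd` when `with_weights = TRUE`.
#'
#' @param volume a `voxel_volume`.
#' @param path output file path.
#' @param with_weights also write the accumulated-weight volume.
#' @return `path`, invisibly.
#' @export
write_volume_nrrd <- function(volume, path, with_weights = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"))
  write_nrrd_array(volume$values, volume$spec, path,
                   extra = c(`tendonswe finalized` =
                               if (volume$finalized) "true" else "false"))
  if (with_weights)
    write_nrrd_array(volume$weights, volume$spec,
                     paste0(path, ".weights.nrrd"))
  invisible(path)
}

write_nrrd_array <- function(a, spec, path, extra = character(0)) {
  dims <- spec$dims
  hdr <- c("NRRD0004",
           "# Complete NRRD file format specification at:",
           "# http://teem.sourceforge.net/nrrd/format.html",
           "type: double",
           "dimension: 3",
           "space: right-anterior-superior",
           paste0("sizes: ", paste(dims, collapse = " ")),
           paste0("space directions: ",
                  sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                          spec$spacing[1], spec$spacing[2], spec$spacing[3])),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: raw",
           paste0("space origin: ",
                  sprintf("(%.17g,%.17g,%.17g)",
                          spec$origin[1], spec$origin[2], spec$origin[3])),
           if (length(extra)) paste0(names(extra), ": ", extra))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  v <- as.vector(a)
  v[is.na(v)] <- NaN
  writeBin(v, con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NRRD volume
#'
#' Supports the dialect written by [write_volume_nrrd()] (3D, raw-encoded
#' doubles or floats, axis-aligned space directions). NaN voxels become
#' `NA` (undefined).
#'
#' @param path NRRD file path.
#' @return a finalized `voxel_volume` (weights 1 where defined, 0
#'   elsewhere, unless a `.weights.nrrd` companion exists).
#' @export
read_volume_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!startsWith(magic, "NRRD"))
    stop("malformed header: not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0) stop("malformed header: no end-of-header blank line")
    if (line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed header line: ", line)
    fields[[kv[1]]] <- kv[2]
  }
  need <- c("type", "dimension", "sizes", "encoding")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("malformed header: missing ", paste(miss, collapse = ", "))
  if (fields$dimension != "3") stop("only 3D NRRD supported")
  if (fields$encoding != "raw") stop("only raw encoding supported")
  size <- switch(fields$type, double = 8, float = 4,
                 stop("unsupported type: ", fields$type))
  dims <- as.integer(strsplit(fields$sizes, " +")[[1]])
  parse_vecs <- function(s) {
    m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
    vecs <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  spacing <- c(0.5, 0.5, 0.5)
  if (!is.null(fields$`space directions`)) {
    dirs <- parse_vecs(fields$`space directions`)
    spacing <- sapply(dirs, function(v) sqrt(sum(v^2)))
  } else if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(fields$spacings, " +")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields$`space origin`))
    origin <- parse_vecs(fields$`space origin`)[[1]]
  endian <- if (is.null(fields$endian)) "little" else fields$endian
  v <- readBin(con, "double", n = prod(dims), size = size, endian = endian)
  if (length(v) != prod(dims)) stop("shape mismatch: truncated data block")
  v[is.nan(v)] <- NA_real_
  spec <- voxel_grid_spec(origin, spacing, dims)
  wpath <- paste0(path, ".weights.nrrd")
  w <- if (file.exists(wpath)) read_volume_nrrd(wpath)$values
       else array(as.numeric(!is.na(v)), dims)
  w[is.na(w)] <- 0
  new_voxel_volume(spec, array(v, dims), array(w, dims), finalized = TRUE)
}

#' Write a sweep as an NRRD frame stack plus poses CSV
#'
#' The SWV frames are stacked into one 3D NRRD (frame index = slowest
#' axis); poses go to a CSV with columns `frame_index`, `r11..r33`
#' (row-major rotation) and `tx, ty, tz`.
#'
#' @param frames list of sweep frames (equal shapes).
#' @param stack_path NRRD output path.
#' @param poses_path CSV output path.
#' @param what `"swv"` (default) or `"bmode"`.
#' @return invisibly, the two paths.
#' @export
write_sweep <- function(frames, stack_path, poses_path, what = "swv") {
  rows <- nrow(frames[[1]][[what]])
  cols <- ncol(frames[[1]][[what]])
  arr <- array(NA_real_, c(rows, cols, length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]][[what]]
  spec <- voxel_grid_spec(c(0, 0, 0),
                          c(frames[[1]]$pixel_spacing,
                            frames[[1]]$pixel_spacing, 1),
                          dim(arr))
  write_nrrd_array(arr, spec, stack_path)
  write_poses_csv(lapply(frames, `[[`, "pose"), poses_path)
  invisible(c(stack_path, poses_path))
}

#' Read a sweep from an NRRD frame stack plus poses CSV
#' @param stack_path,poses_path paths written by [write_sweep()].
#' @return list of `sweep_frame` objects (SWV only; B-mode empty).
#' @export
read_sweep <- function(stack_path, poses_path) {
  vol <- read_volume_nrrd(stack_path)
  poses <- read_poses_csv(poses_path)
  if (length(poses) != vol$spec$dims[3])
    stop("shape mismatch: ", vol$spec$dims[3], " frames vs ",
         length(poses), " poses")
  lapply(seq_along(poses), function(i) {
    frm <- list(bmode = vol$values[, , i] * NA, swv = vol$values[, , i],
                pixel_spacing = vol$spec$spacing[1], pose = poses[[i]])
    class(frm) <- "sweep_frame"
    frm
  })
}

#' Write frame poses to CSV
#' @param poses list of [rigid_pose()] objects.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_poses_csv <- function(poses, path) {
  rows <- t(sapply(poses, function(p)
    c(as.vector(t(p$rotation)), p$translation)))
  colnames(rows) <- c("r11", "r12", "r13", "r21", "r22", "r23",
                      "r31", "r32", "r33", "tx", "ty", "tz")
  df <- data.frame(frame_index = seq_along(poses) - 1L, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read frame poses from CSV, validating orthonormality
#' @param path CSV path with the [write_poses_csv()] dialect.
#' @param tol orthonormality tolerance for validation (default 1e-6).
#' @return list of [rigid_pose()] objects, ordered by `frame_index`.
#' @export
read_poses_csv <- function(path, tol = 1e-6) {
  df <- read.csv(path)
  need <- c("frame_index", "r11", "r12", "r13", "r21", "r22", "r23",
            "r31", "r32", "r33", "tx", "ty", "tz")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed poses CSV: missing column(s) ",
         paste(miss, collapse = ", "))
  if (!all(sapply(df[need], is.numeric)) || !all(is.finite(as.matrix(df[need]))))
    stop("malformed poses CSV: non-finite values")
  df <- df[order(df$frame_index), ]
  lapply(seq_len(nrow(df)), function(i) {
    R <- matrix(as.numeric(df[i, c("r11", "r12", "r13", "r21", "r22",
                                   "r23", "r31", "r32", "r33")]),
                3, 3, byrow = TRUE)
    rigid_pose(R, as.numeric(df[i, c("tx", "ty", "tz")]), tol = tol)
  })
}

cohort_columns <- c("id", "group", "sex", "age", "weight", "height",
                    "bmi", "tendon_length", "csa", "swv_overall",
                    "swv_proximal", "swv_mid", "swv_distal")

#' Write a cohort table to CSV (fixed column order)
#' @param cohort cohort data frame (see [simulate_cohort()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(all(cohort_columns %in% names(cohort)))
  write.csv(cohort[, cohort_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV, validating the BMI identity
#'
#' Warns if any row's BMI disagrees with `weight / (height/100)^2` by more
#' than 1e-6 and errors on non-finite values, unknown group/sex levels or
#' SWV outside [swv_bounds()].
#' @param path CSV path.
#' @return cohort data frame of class `swv_cohort`.
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_columns, names(df))
  if (length(miss))
    stop("malformed cohort CSV: missing column(s) ",
         paste(miss, collapse = ", "))
  df <- df[, cohort_columns]
  num <- setdiff(cohort_columns, c("id", "group", "sex"))
  if (!all(is.finite(as.matrix(df[num]))))
    stop("malformed cohort CSV: non-finite values")
  if (!all(df$group %in% c("control", "skier")))
    stop("malformed cohort CSV: unknown group level")
  if (!all(df$sex %in% c("female", "male")))
    stop("malformed cohort CSV: unknown sex level")
  b <- swv_bounds()
  swv <- as.matrix(df[c("swv_overall", "swv_proximal", "swv_mid",
                        "swv_distal")])
  if (any(swv < b[1] | swv > b[2]))
    stop("malformed cohort CSV: SWV outside physical bounds")
  dev <- abs(df$bmi - df$weight / (df$height / 100)^2)
  if (any(dev > 1e-6))
    warning(sprintf("BMI inconsistent with weight/height in %d row(s) (max dev %.3g)",
                    sum(dev > 1e-6), max(dev)))
  class(df) <- c("swv_cohort", "data.frame")
  df
}

#' Write / read insertion landmarks as JSON
#'
#' JSON object `{"proximal": [x,y,z], "distal": [x,y,z]}` in mm world
#' coordinates.
#' @param landmarks list with `proximal` and `distal` 3-vectors.
#' @param path JSON path.
#' @return `path` invisibly (write); the landmarks list (read).
#' @export
write_landmarks_json <- function(landmarks, path) {
  stopifnot(length(landmarks$proximal) == 3, length(landmarks$distal) == 3)
  jsonlite::write_json(lapply(landmarks[c("proximal", "distal")],
                              as.numeric),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("proximal", "distal") %in% names(lm)) ||
      length(lm$proximal) != 3 || length(lm$distal) != 3 ||
      !all(is.finite(c(lm$proximal, lm$distal))))
    stop("malformed landmarks JSON: need finite 3-vectors 'proximal', 'distal'")
  lm[c("proximal", "distal")]
}

#' Export a volume as NIfTI (optional, requires RNifti)
#' @param volume a `voxel_volume`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti not installed; NIfTI export unavailable")
  img <- volume$values
  RNifti::writeNifti(RNifti::asNifti(img, pixdim = volume$spec$spacing),
                     path)
  invisible(path)
}
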