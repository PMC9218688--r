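# Masking, region partitioning and regional means.

setup_volume <- function(seed = 1) {
  ph <- small_phantom()
  frames <- noise_free_sweep(ph, n_frames = 9, pixel_spacing = 0.8,
                             seed = seed)
  vols <- compound(frames)
  list(ph = ph, swe = vols$swe, bmode = vols$bmode)
}

test_that("apply_mask keeps inside voxels and undefines the rest", {
  sv <- setup_volume()
  mask <- phantom_mask(sv$ph, sv$swe$spec)
  all_on <- tendon_mask(sv$swe$spec,
                        array(TRUE, sv$swe$spec$dims),
                        mask$proximal_landmark, mask$distal_landmark)
  # all-ones mask is the identity
  m1 <- apply_mask(sv$swe, all_on)
  expect_identical(m1$values, sv$swe$values)
  # arbitrary mask: defined set equals the set intersection oracle
  m2 <- apply_mask(sv$swe, mask)
  expect_identical(!is.na(m2$values), !is.na(sv$swe$values) & mask$mask)
  expect_equal(m2$values[mask$mask & !is.na(sv$swe$values)],
               sv$swe$values[mask$mask & !is.na(sv$swe$values)])
  # all-zeros mask is rejected at construction
  expect_error(tendon_mask(sv$swe$spec, array(FALSE, sv$swe$spec$dims),
                           c(0, 0, 0), c(45, 0, 0)), "empty mask")
  # grid mismatch
  other <- voxel_grid_spec(c(0, 0, 0), 1, c(4, 4, 4))
  expect_error(apply_mask(sv$swe,
                          tendon_mask(other, array(TRUE, c(4, 4, 4)),
                                      c(0, 0, 0), c(45, 0, 0))),
               "grid mismatch")
})

test_that("cuts 10 mm from each insertion give the published axial extents", {
  # L = 45 mm: proximal 10, mid 25, distal 10 mm of axial extent
  spec <- voxel_grid_spec(c(0, 0, 0), c(0.5, 1, 1), c(91, 1, 1))
  mask <- tendon_mask(spec, array(TRUE, c(91, 1, 1)),
                      c(0, 0, 0), c(45, 0, 0))
  lab <- partition_regions(mask, 10)
  s <- (0:90) * 0.5
  expect_identical(as.vector(lab),
                   ifelse(s <= 10, 1L, ifelse(s >= 35, 3L, 2L)))
  # voxel at s = 5 mm is proximal; boundary s = 10 goes to the end region
  expect_identical(lab[11, 1, 1], 1L)  # s = 5
  expect_identical(lab[21, 1, 1], 1L)  # s = 10 exactly
  expect_identical(lab[71, 1, 1], 3L)  # s = 35 exactly
})

test_that("partition labels match the phantom's own region classifier", {
  sv <- setup_volume()
  mask <- phantom_mask(sv$ph, sv$swe$spec)
  lab <- partition_regions(mask, 10)
  # oracle: classify every voxel center with the ground-truth field
  centers <- voxel_centers_oracle(sv$swe$spec)
  oracle <- phantom_region(sv$ph, centers)
  expect_identical(as.vector(lab), oracle)
})

test_that("region labels partition the mask", {
  sv <- setup_volume()
  mask <- phantom_mask(sv$ph, sv$swe$spec)
  lab <- partition_regions(mask, 10)
  expect_true(all((lab > 0L) == mask$mask))
})

test_that("cut_distance 0 labels everything mid except the landmark planes, and end regions grow with it", {
  sv <- setup_volume()
  mask <- phantom_mask(sv$ph, sv$swe$spec)
  lab0 <- partition_regions(mask, 0)
  expect_true(all(lab0[mask$mask] %in% c(1L, 2L, 3L)))
  expect_gt(mean(lab0[mask$mask] == 2L), 0.95)
  sizes <- sapply(c(2, 6, 10, 14), function(cd) {
    lab <- partition_regions(mask, cd)
    c(sum(lab == 1L), sum(lab == 3L))
  })
  expect_true(all(diff(sizes[1, ]) >= 0))
  expect_true(all(diff(sizes[2, ]) >= 0))
})

test_that("tendon too short for three regions is rejected", {
  spec <- voxel_grid_spec(c(0, 0, 0), 1, c(16, 1, 1))
  mask <- tendon_mask(spec, array(TRUE, c(16, 1, 1)),
                      c(0, 0, 0), c(15, 0, 0))
  expect_error(partition_regions(mask, 10), "too short")
})

test_that("regional means equal a brute-force loop oracle and handle constants", {
  sv <- setup_volume()
  mask <- phantom_mask(sv$ph, sv$swe$spec)
  lab <- partition_regions(mask, 10)
  masked <- apply_mask(sv$swe, mask)
  rs <- regional_means(masked, lab, mask)
  # loop oracle
  vals <- as.vector(masked$values)
  labv <- as.vector(lab)
  for (k in 1:3) {
    acc <- 0; n <- 0
    for (i in seq_along(vals))
      if (labv[i] == k && !is.na(vals[i])) { acc <- acc + vals[i]; n <- n + 1 }
    expect_equal(c(rs$proximal, rs$mid, rs$distal)[k], acc / n)
    expect_equal(unname(rs$counts[k]), n)
  }
  expect_equal(rs$overall,
               mean(vals[labv > 0 & !is.na(vals)]))
  expect_equal(rs$tendon_length, 45)
  # overall equals the count-weighted mean of the regional means
  expect_equal(rs$overall,
               sum(c(rs$proximal, rs$mid, rs$distal) * rs$counts) /
                 sum(rs$counts), tolerance = 1e-9)
  # constant field: all four means equal the constant
  const <- masked
  const$values[!is.na(const$values)] <- 4.25
  rc <- regional_means(const, lab, mask)
  expect_equal(c(rc$overall, rc$proximal, rc$mid, rc$distal), rep(4.25, 4))
  # {8, 10} averages to 9
  spec1 <- voxel_grid_spec(c(0, 0, 0), c(30, 1, 1), c(2, 1, 1))
  m1 <- tendon_mask(spec1, array(TRUE, c(2, 1, 1)), c(0, 0, 0), c(30, 0, 0))
  v1 <- tendonswe:::new_voxel_volume(spec1, array(c(8, 10), c(2, 1, 1)),
                                     array(1, c(2, 1, 1)), finalized = TRUE)
  lab1 <- array(2L, c(2, 1, 1))
  expect_equal(suppressWarnings(regional_means(v1, lab1, m1))$mid, 9)
})

test_that("empty regions are reported NA with a warning", {
  spec <- voxel_grid_spec(c(0, 0, 0), c(1, 1, 1), c(50, 1, 1))
  m <- array(FALSE, c(50, 1, 1)); m[1:12, 1, 1] <- TRUE  # proximal only
  mask <- tendon_mask(spec, m, c(0, 0, 0), c(45, 0, 0))
  lab <- partition_regions(mask, 10)
  vol <- tendonswe:::new_voxel_volume(spec, array(9, c(50, 1, 1)),
                                      array(1, c(50, 1, 1)),
                                      finalized = TRUE)
  expect_warning(rs <- regional_means(apply_mask(vol, mask), lab, mask),
                 "empty region")
  expect_true(is.na(rs$distal))
})

test_that("noise-free phantom recovery: interior regional bias below 0.1 m/s", {
  ph <- small_phantom(swv_true = c(proximal = 10, mid = 9, distal = 11))
  frames <- noise_free_sweep(ph, n_frames = 11, pixel_spacing = 0.6)
  vol <- compound(frames)$swe
  kernel_radius <- 2 * mean(vol$spec$spacing)  # trunc * sigma
  mask <- erode_mask(phantom_mask(ph, vol$spec), kernel_radius)
  lab <- partition_regions(mask, 10)
  # exclude voxels within one kernel radius of a cut plane
  centers <- voxel_centers_oracle(vol$spec)
  s <- (centers %*% (ph$axis))[, 1] -
    sum(ph$proximal_landmark * ph$axis)
  near_cut <- abs(s - 10) <= kernel_radius |
    abs(s - (ph$length - 10)) <= kernel_radius
  lab[array(near_cut, dim(lab))] <- 0L
  rs <- regional_means(apply_mask(vol, mask), lab, mask)
  expect_lt(abs(rs$proximal - 10), 0.1)
  expect_lt(abs(rs$mid - 9), 0.1)
  expect_lt(abs(rs$distal - 11), 0.1)
})

test_that("segment_bmode recovers the phantom mask (Dice > 0.95) and landmarks", {
  sv <- setup_volume()
  seg <- segment_bmode(sv$bmode)
  truth <- phantom_mask(sv$ph, sv$bmode$spec)
  inter <- sum(seg$mask & truth$mask)
  dice <- 2 * inter / (sum(seg$mask) + sum(truth$mask))
  expect_gt(dice, 0.95)
  expect_lt(sqrt(sum((seg$proximal_landmark - truth$proximal_landmark)^2)),
            5)
  expect_lt(sqrt(sum((seg$distal_landmark - truth$distal_landmark)^2)), 5)
  # all-background volume errors
  flat <- sv$bmode
  flat$values[] <- 0.1
  expect_error(segment_bmode(flat, threshold = 0.5),
               "no component above threshold")
  # threshold 0 on a positive-intensity volume keeps all defined voxels
  seg0 <- segment_bmode(sv$bmode, threshold = 0)
  expect_equal(sum(seg0$mask), sum(!is.na(sv$bmode$values)))
})
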