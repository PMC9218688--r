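# Pipeline driver: one reproducible run tying together phantom sweep
# simulation, compounding, regional analysis, cohort simulation and
# inference. A single global seed is expanded into per-stage seeds
# (seed + 1000 * stage index) so stages can be rerun independently.

#' Run configuration
#'
#' @param seed global integer seed; per-stage seeds are derived as
#'   `seed + 1000 * stage` (stage 1 = sweep, stage 2 = cohort).
#' @param phantom a [tendon_phantom()].
#' @param n_frames frames in the simulated sweep.
#' @param pixel_spacing pixel pitch, mm.
#' @param pose_noise_sd,swv_noise_sd sweep noise, see [sweep_config()].
#' @param voxel_spacing reconstruction voxel spacing, mm (default 0.5).
#' @param cut_distance regional cut distance, mm (default 10).
#' @param cohort a [cohort_params()]; default [study_cohort_params()].
#' @param criterion model-selection criterion, see [select_model()].
#' @param alpha significance level recorded with the fits (default 0.05).
#' @param use_segmentation segment the B-mode volume instead of using the
#'   phantom's ground-truth mask and landmarks (default FALSE).
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, phantom = tendon_phantom(),
                       n_frames = 15, pixel_spacing = 0.5,
                       pose_noise_sd = c(0.5, 0.25), swv_noise_sd = 0.3,
                       voxel_spacing = 0.5, cut_distance = 10,
                       cohort = study_cohort_params(seed = seed + 2000L),
                       criterion = "adjusted_r2", alpha = 0.05,
                       use_segmentation = FALSE) {
  stopifnot(voxel_spacing > 0, cut_distance >= 0, alpha > 0, alpha < 1)
  structure(list(seed = as.integer(seed), phantom = phantom,
                 n_frames = n_frames, pixel_spacing = pixel_spacing,
                 pose_noise_sd = pose_noise_sd, swv_noise_sd = swv_noise_sd,
                 voxel_spacing = voxel_spacing, cut_distance = cut_distance,
                 cohort = cohort, criterion = criterion, alpha = alpha,
                 use_segmentation = use_segmentation),
            class = "run_config")
}

#' Run the full pipeline into an output directory
#'
#' Stages: (1) simulate a pose-tracked sweep of the phantom and write the
#' frame stack + poses; (2) compound into SWE and B-mode volumes (NRRD);
#' (3) mask, partition and summarize regional SWV (CSV); (4) simulate a
#' cohort (CSV) and run the model-selection inference and regional-delta
#' tests (JSON). Every stage's seed and outputs are logged to `log.txt`;
#' errors are propagated with the stage name.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the regional summary, the inference
#'   results and the paths of all artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("tendonswe pipeline run\n", file = log_path)
  logf("global seed: %d", config$seed)
  stage <- function(name, expr) {
    logf("[%s] start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sweep_seed <- config$seed + 1000L
  frames <- stage("simulate_sweep", {
    logf("[simulate_sweep] seed: %d, %d frames", sweep_seed, config$n_frames)
    traj <- linear_sweep_trajectory(config$phantom, config$n_frames,
                                    config$pixel_spacing)
    simulate_sweep(config$phantom,
                   sweep_config(traj, config$pixel_spacing,
                                config$pose_noise_sd, config$swv_noise_sd,
                                seed = sweep_seed))
  })
  paths <- list(stack = file.path(out_dir, "frames.nrrd"),
                poses = file.path(out_dir, "poses.csv"),
                swe = file.path(out_dir, "swe.nrrd"),
                bmode = file.path(out_dir, "bmode.nrrd"),
                mask = file.path(out_dir, "mask.nrrd"),
                landmarks = file.path(out_dir, "landmarks.json"),
                regional = file.path(out_dir, "regional.csv"),
                cohort = file.path(out_dir, "cohort.csv"),
                fits = file.path(out_dir, "fits.json"),
                log = log_path)
  stage("write_sweep", write_sweep(frames, paths$stack, paths$poses))

  vols <- stage("reconstruct", {
    spec <- grid_spec_for_frames(frames, config$voxel_spacing)
    compound(frames, spec)
  })
  write_volume_nrrd(vols$swe, paths$swe)
  write_volume_nrrd(vols$bmode, paths$bmode)
  logf("[reconstruct] %d defined SWE voxels", defined_count(vols$swe))

  regional <- stage("regions", {
    mask <- if (config$use_segmentation) segment_bmode(vols$bmode)
            else phantom_mask(config$phantom, vols$swe$spec)
    write_volume_nrrd(new_voxel_volume(mask$spec,
                                       array(as.numeric(mask$mask),
                                             mask$spec$dims),
                                       array(1, mask$spec$dims),
                                       finalized = TRUE),
                      paths$mask)
    write_landmarks_json(list(proximal = mask$proximal_landmark,
                              distal = mask$distal_landmark),
                         paths$landmarks)
    labels <- partition_regions(mask, config$cut_distance)
    rs <- regional_means(apply_mask(vols$swe, mask), labels, mask)
    write.csv(data.frame(subject = "phantom", overall = rs$overall,
                         proximal = rs$proximal, mid = rs$mid,
                         distal = rs$distal,
                         tendon_length = rs$tendon_length),
              paths$regional, row.names = FALSE)
    rs
  })

  cohort_seed <- config$seed + 2000L
  inference <- stage("cohort_inference", {
    logf("[cohort] seed: %d", cohort_seed)
    cohort <- simulate_cohort(config$cohort, seed = cohort_seed)
    write_cohort_csv(cohort, paths$cohort)
    ci <- cohort_inference(cohort, "population", config$criterion)
    deltas <- regional_delta_test(cohort)
    jsonlite::write_json(
      list(alpha = config$alpha, criterion = config$criterion,
           population = inference_table(ci),
           regional_deltas = list(
             distal_minus_mid = list(
               group_means = as.list(deltas$distal_minus_mid$group_means),
               p_value = deltas$distal_minus_mid$test$p_value),
             proximal_minus_mid = list(
               group_means = as.list(deltas$proximal_minus_mid$group_means),
               p_value = deltas$proximal_minus_mid$test$p_value))),
      paths$fits, digits = NA, auto_unbox = TRUE, dataframe = "rows")
    list(selection = ci, deltas = deltas)
  })
  logf("done")
  invisible(list(regional = regional, inference = inference, paths = paths))
}
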