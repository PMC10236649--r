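# Config-driven end-to-end orchestration: synth -> build -> evaluate ->
# validate -> report, with a single root seed fanned out to named
# substreams for reproducibility.

#' Build a run configuration
#'
#' Serializable description of an end-to-end run. The default mirrors the
#' four study arms (female/male x left/right: 50, 50, 43, 43 subjects);
#' tests and examples use smaller arms.
#'
#' @param arms named list; each element a list of [population_spec()]
#'   arguments (without `seed`, which is fanned out from `seed`).
#' @param spacing_mm voxel spacing for mesh-to-image conversion.
#' @param smooth_sigma_mm Gaussian sigma of the registration
#'   pseudo-intensity.
#' @param intensity registration substrate: `"depth"` (default; smoothed
#'   occupancy blended with clamped interior depth) or `"occupancy"`.
#' @param depth_tau interior-depth clamp in mm for the depth substrate.
#' @param n_iterations template iterations.
#' @param train_fraction train split fraction.
#' @param seed root seed; every random operation derives its own stream
#'   from it.
#' @param outdir output directory.
#' @param reg_params registration parameters.
#' @param base_resolution,base_length_mm base-shape construction controls.
#' @return Object of class `run_config`.
#' @export
run_config <- function(arms = list(
                         female_left = list(n_subjects = 50L),
                         female_right = list(n_subjects = 50L),
                         male_left = list(n_subjects = 43L),
                         male_right = list(n_subjects = 43L)),
                       spacing_mm = 1, smooth_sigma_mm = 1,
                       intensity = "depth", depth_tau = 10,
                       n_iterations = 4L, train_fraction = 0.82,
                       seed = 1L, outdir = "bonatlas_run",
                       reg_params = default_reg_params(),
                       base_resolution = 2, base_length_mm = 300) {
  structure(list(arms = arms, spacing_mm = spacing_mm,
                 smooth_sigma_mm = smooth_sigma_mm,
                 intensity = intensity, depth_tau = depth_tau,
                 n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 outdir = outdir, reg_params = reg_params,
                 base_resolution = base_resolution,
                 base_length_mm = base_length_mm),
            class = "run_config")
}

#' Read/write a run configuration as JSON
#'
#' @param config a [run_config].
#' @param path JSON path.
#' @return `read_run_config` returns a [run_config]; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$arms <- lapply(x$arms, as.list)
  do.call(run_config, x)
}

# named sub-seed fanout from the root seed (kept well below 2^31)
sub_seed <- function(root, stream, index = 0L) {
  offs <- c(population = 11L, split = 23L, icp = 37L)
  s <- (as.integer(root) * 1009L + offs[[stream]] * 101L + as.integer(index))
  as.integer(abs(s) %% 2147483L + 1L)
}

arm_population <- function(config, arm_name, n_override = NULL) {
  idx <- match(arm_name, names(config$arms))
  if (is.na(idx)) stop("unknown arm: ", arm_name)
  args <- config$arms[[arm_name]]
  if (!is.null(n_override)) args$n_subjects <- n_override
  args$seed <- sub_seed(config$seed, "population", idx)
  spec <- do.call(population_spec, args)
  base <- make_base_shape(config$base_resolution, config$base_length_mm)
  make_population(base, spec)
}

# ICP-align every mesh to the first subject (the preprocessing step before
# mesh-to-image conversion), then voxelize on a per-subject grid
align_and_voxelize <- function(meshes, config) {
  fixed <- meshes[[1]]
  aligned <- vector("list", length(meshes))
  aligned[[1]] <- fixed
  for (i in seq_along(meshes)[-1]) {
    aligned[[i]] <- icp_align(meshes[[i]], fixed)$aligned
  }
  grid <- common_grid(aligned, config$spacing_mm, padding = 4)
  vols <- lapply(aligned, voxelize, smooth_sigma = config$smooth_sigma_mm,
                 intensity = config$intensity, depth_tau = config$depth_tau,
                 grid = grid)
  list(meshes = aligned, volumes = vols)
}

#' Generate the configured populations and write them to disk
#'
#' @param config a [run_config].
#' @return Named list of manifest paths, invisibly.
#' @export
cmd_synth <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)
  out <- lapply(names(config$arms), function(nm) {
    pop <- arm_population(config, nm)
    write_population(pop, file.path(config$outdir, "population", nm))
  })
  names(out) <- names(config$arms)
  invisible(out)
}

# full in-memory computation for one arm; the cmd_* wrappers persist it
run_arm <- function(config, arm_name, verbose = FALSE) {
  pop <- arm_population(config, arm_name)
  n <- length(pop$samples)
  split <- split_data(seq_len(n), config$train_fraction,
                      sub_seed(config$seed, "split",
                               match(arm_name, names(config$arms))))
  prep <- align_and_voxelize(lapply(pop$samples, `[[`, "mesh"), config)
  train_vols <- prep$volumes[split$train]
  tmpl <- build_template(train_vols, n_iterations = config$n_iterations,
                         reg_params = config$reg_params, verbose = verbose)
  mean_shape <- correspondence_mean_shape(prep$meshes[split$train],
                                          use_known_topology = TRUE)
  base_lm <- pop$base$landmarks
  tmpl_lm <- project_landmarks_to_surface(base_lm, tmpl$surface,
                                          frame = "template")
  mean_lm <- project_landmarks_to_surface(base_lm, mean_shape,
                                          frame = "mean_shape")
  clouds <- transfer_landmarks_to_training(tmpl_lm, tmpl$transforms)
  pca <- pca_explained_variance(clouds)
  list(arm = arm_name, population = pop, split = split,
       aligned_meshes = prep$meshes, volumes = prep$volumes,
       template = tmpl, mean_shape = mean_shape,
       template_landmarks = tmpl_lm, mean_shape_landmarks = mean_lm,
       clouds = clouds, pca = pca)
}

validate_arm <- function(config, arm_run) {
  split <- arm_run$split
  mean_vol <- voxelize(arm_run$mean_shape, spacing = config$spacing_mm,
                       padding = 4, smooth_sigma = config$smooth_sigma_mm,
                       intensity = config$intensity,
                       depth_tau = config$depth_tau)
  arms <- list(
    template = list(template_volume = arm_run$template$template,
                    template_landmarks = arm_run$template_landmarks),
    mean_shape = list(template_volume = mean_vol,
                      template_landmarks = arm_run$mean_shape_landmarks)
  )
  # ground truth comes from the generator, in the ICP-aligned frame: the
  # alignment applied to each subject's mesh is applied to its landmarks
  truth <- lapply(split$test, function(i) {
    orig <- arm_run$population$samples[[i]]
    tr <- kabsch_fit(orig$mesh$vertices, arm_run$aligned_meshes[[i]]$vertices)
    landmark_set(orig$landmarks$names, apply_rigid(tr, orig$landmarks$points),
                 frame = sprintf("subject_%03d_aligned", i))
  })
  validate_planning(arms, arm_run$volumes[split$test], truth,
                    reg_params = config$reg_params)
}

#' Build templates for every arm and persist the artifacts
#'
#' @param config a [run_config].
#' @param arm_names arms to run (default: all configured arms).
#' @param verbose print progress.
#' @return Named list of per-arm results (in memory), invisibly; artifacts
#'   (template NRRD, surface STL, iteration log CSV, landmarks, PCA CSV)
#'   are written under `config$outdir`.
#' @export
cmd_build <- function(config, arm_names = names(config$arms),
                      verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  runs <- lapply(arm_names, function(nm) {
    run <- run_arm(config, nm, verbose = verbose)
    dir <- file.path(config$outdir, nm)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_nrrd(run$template$template, file.path(dir, "template.nrrd"))
    write_stl(run$template$surface, file.path(dir, "template_surface.stl"))
    write_stl(run$mean_shape, file.path(dir, "mean_shape.stl"))
    write_landmarks(run$template_landmarks,
                    file.path(dir, "template_landmarks.csv"))
    log_df <- run$template$iteration_log
    write.csv(format(log_df, digits = 10, trim = TRUE),
              file.path(dir, "iteration_log.csv"), row.names = FALSE,
              quote = FALSE)
    write_pca_csv(run$pca, file.path(dir, "pca_explained_variance.csv"))
    run
  })
  names(runs) <- arm_names
  invisible(runs)
}

#' Evaluate and validate built arms, then write a combined report
#'
#' Runs the distance-model comparison between arms, the held-out landmark
#' validation, and writes per-arm CSVs, scree/histogram/RMSE figures and a
#' combined markdown report.
#'
#' @param config a [run_config].
#' @param runs result of [cmd_build()].
#' @return Named list of `validation_report`s, invisibly.
#' @export
cmd_validate <- function(config, runs) {
  reports <- lapply(names(runs), function(nm) {
    run <- runs[[nm]]
    dir <- file.path(config$outdir, nm)
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    dm <- compare_templates(run$template$surface, run$mean_shape)
    mids <- seq(dm$range_mm[1] - dm$bin_mm / 2, dm$range_mm[2] + dm$bin_mm / 2,
                by = dm$bin_mm)
    write.csv(data.frame(bin_center = mids, count = dm$counts),
              file.path(dir, "distance_histogram.csv"), row.names = FALSE,
              quote = FALSE)
    rep <- validate_arm(config, run)
    write.csv(format(rep$per_subject, digits = 10, trim = TRUE),
              file.path(dir, "validation_per_subject.csv"),
              row.names = FALSE, quote = FALSE)
    write.csv(format(rep$per_landmark, digits = 10, trim = TRUE),
              file.path(dir, "validation_per_landmark.csv"),
              row.names = FALSE, quote = FALSE)
    grDevices::png(file.path(dir, "scree.png"), width = 600, height = 400)
    plot(run$pca, main = paste("explained variation:", nm))
    grDevices::dev.off()
    grDevices::png(file.path(dir, "distance_histogram.png"), width = 600,
                   height = 400)
    plot(dm, main = paste("template vs mean shape:", nm))
    grDevices::dev.off()
    grDevices::png(file.path(dir, "rmse_bars.png"), width = 600, height = 400)
    plot(rep, main = paste("held-out landmark RMSE:", nm))
    grDevices::dev.off()
    rep
  })
  names(reports) <- names(runs)
  invisible(reports)
}

#' Write the combined markdown report
#'
#' @param config a [run_config].
#' @param runs result of [cmd_build()].
#' @param reports result of [cmd_validate()].
#' @return Report path, invisibly.
#' @export
cmd_report <- function(config, runs, reports) {
  lines <- c("# Average population model report", "")
  for (nm in names(runs)) {
    run <- runs[[nm]]
    rep <- reports[[nm]]
    k <- min(7L, length(run$pca$cumulative_fraction))
    lines <- c(lines,
               sprintf("## Arm: %s", nm),
               sprintf("- subjects: %d (train %d / test %d)",
                       length(run$population$samples),
                       length(run$split$train), length(run$split$test)),
               sprintf("- cumulative explained variance at mode %d: %.2f%%",
                       k, 100 * run$pca$cumulative_fraction[k]),
               sprintf("- template iterations: %d (final mean change %.5f)",
                       nrow(run$template$iteration_log),
                       tail(run$template$iteration_log$mean_abs_change, 1)),
               "")
    if (!is.null(rep$t_test)) {
      lines <- c(lines,
                 sprintf("- mean RMSE template arm: %.3f mm; correspondence-mean arm: %.3f mm",
                         rep$arm_summary$mean_rmse[1],
                         rep$arm_summary$mean_rmse[2]),
                 sprintf("- paired t-test p = %.4g; improvement %.1f%%",
                         rep$t_test$p, rep$improvement_pct),
                 "")
    }
  }
  path <- file.path(config$outdir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
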