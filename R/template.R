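# Iterative unbiased average-population template construction, plus the
# simplified correspondence mean-shape comparator arm.

#' Initialise the template grid and the voxel-wise average template
#'
#' The subject with the biggest occupancy volume provides the reference
#' coordinate system; its grid is padded so every subject's bounding box is
#' covered, every subject is resampled onto it, and the initial template is
#' their voxel-wise arithmetic mean.
#'
#' @param volumes non-empty list of [scalar_volume] objects (>= 2).
#' @return List with `grid`, `template` (initial [scalar_volume]),
#'   `resampled` (list of subject volumes on the grid) and
#'   `reference_index`.
#' @export
init_template <- function(volumes) {
  if (length(volumes) < 2L) stop("need at least 2 volumes")
  stopifnot(all(vapply(volumes, inherits, TRUE, "scalar_volume")))
  occ_vol <- vapply(volumes, function(v) sum(v$values) * prod(v$spacing),
                    numeric(1))
  ref <- which.max(occ_vol)
  spacing <- volumes[[ref]]$spacing
  lo <- volumes[[ref]]$origin
  hi <- volumes[[ref]]$origin + (volumes[[ref]]$dims - 1) * spacing
  for (v in volumes) {
    lo <- pmin(lo, v$origin)
    hi <- pmax(hi, v$origin + (v$dims - 1) * v$spacing)
  }
  # extend the reference grid by whole voxels so it stays aligned with it
  below <- ceiling(pmax(0, volumes[[ref]]$origin - lo) / spacing)
  above <- ceiling(pmax(0, hi - (volumes[[ref]]$origin +
                                   (volumes[[ref]]$dims - 1) * spacing)) /
                     spacing)
  origin <- volumes[[ref]]$origin - below * spacing
  dims <- as.integer(volumes[[ref]]$dims + below + above)
  grid <- list(origin = origin, spacing = spacing, dims = dims)
  resampled <- lapply(volumes, resample_volume_to_grid, grid = grid)
  mean_vals <- Reduce(`+`, lapply(resampled, `[[`, "values")) /
    length(resampled)
  list(grid = grid,
       template = scalar_volume(mean_vals, grid$origin, grid$spacing),
       resampled = resampled, reference_index = ref)
}

attach_pyramid <- function(vol, spacings) {
  pyr <- lapply(spacings, function(s) resample_to_spacing(vol, s))
  names(pyr) <- vapply(spacings, format, character(1))
  attr(vol, "pyramid") <- pyr
  vol
}

register_subject_to_template <- function(subject, template, reg_params,
                                         init = NULL) {
  # all image work happens inside the joint-support bounding box; the
  # margin covers the regularized deformation scale plus the near-identity
  # affine of an ICP-pre-aligned population
  margin <- ceiling(3 * reg_params$total_sigma / max(template$spacing)) + 4L
  if (same_grid(subject, template)) {
    crop <- crop_to_support(template, subject, margin_vox = margin)
  } else {
    # off-grid subject (e.g. a held-out volume on its own grid): crop the
    # template to its own support and keep the subject whole; the affine
    # bridges the grids
    crop <- list(fixed = crop_to_support(template, template,
                                         margin_vox = margin)$fixed,
                 moving = subject)
  }
  lv <- unique(c(reg_params$affine_levels, reg_params$deformable_levels))
  fixed_c <- attach_pyramid(crop$fixed,
                            lv[lv > max(template$spacing) * 1.01])
  aff <- affine_register(crop$moving, fixed_c,
                         levels = reg_params$affine_levels,
                         maxit = reg_params$affine_maxit,
                         init = if (!is.null(init)) init$affine)
  moved <- warp_volume(crop$moving, aff, grid = grid_of(crop$fixed))
  fld <- deformable_register(moved, fixed_c,
                             levels = reg_params$deformable_levels,
                             iters_per_level = reg_params$iters_per_level,
                             update_sigma = reg_params$update_sigma,
                             total_sigma = reg_params$total_sigma,
                             init_field = if (!is.null(init)) init$field)
  fld_full <- field_to_grid(fld, grid_of(template))
  for (a in c("ssd_initial", "ssd_final", "jacobian_positive_frac",
              "ssd_trace")) {
    attr(fld_full, a) <- attr(fld, a)
  }
  registered <- warp_volume(moved, fld_full, grid = grid_of(template))
  list(transform = subject_transform(aff, fld_full), registered = registered)
}

#' Default registration parameters
#'
#' The parameter set used by template building and landmark prediction:
#' two-level affine (4 and 2 mm) followed by three-level demons
#' (4, 2, 1 mm) with iteration caps distributed coarse-to-fine (most of
#' the displacement is recovered at the coarse levels; the fine level
#' refines surface detail and stops early on SSD stagnation).
#'
#' @return Named list of registration parameters.
#' @export
default_reg_params <- function() {
  list(affine_levels = c(4, 2), affine_maxit = c(30L, 12L),
       deformable_levels = c(4, 2, 1), iters_per_level = c(30L, 12L, 6L),
       update_sigma = 2, total_sigma = 1.5)
}

#' Build the iterative unbiased average-population template
#'
#' The central fitting step. Per iteration every subject image is
#' registered to the current template (affine then demons-style
#' deformable), the registered images are averaged into a candidate
#' template, the per-subject template-to-subject transforms are averaged,
#' and the candidate is warped a scaled step (default 0.25) along that
#' averaged transform so the template drifts toward the population's
#' barycenter instead of the initial reference. Iteration stops after
#' `n_iterations` or when the mean absolute voxel change falls below
#' `tol`. The per-subject transforms are re-estimated once against the
#' final template.
#'
#' @param volumes list of subject [scalar_volume] objects (>= 2), typically
#'   ICP-aligned and voxelized with a common smoothing sigma.
#' @param n_iterations number of template iterations (default 4).
#' @param reg_params registration parameter list as produced by
#'   `default_reg_params()` (affine levels/iterations, deformable levels,
#'   demons iterations and sigmas).
#' @param drift_step scale of the drift-correction step (default 0.25).
#' @param tol mean-absolute-voxel-change convergence tolerance (default
#'   1e-3).
#' @param final_pass re-estimate all subject transforms against the final
#'   template (default TRUE).
#' @param final_reg_params registration parameters for the final
#'   re-estimation pass (defaults to `reg_params`); expose a deeper
#'   schedule here when the transforms that carry landmarks should be
#'   fitted more tightly than the intermediate template updates.
#' @param surface_iso iso level of the template surface; defaults to the
#'   `surface_iso` attribute of the first input volume (0.25 for the
#'   depth pseudo-intensity, 0.5 for plain occupancy).
#' @param field_storage_spacing grid spacing (mm) at which per-subject
#'   displacement fields are stored between iterations and in the result;
#'   fields are regularized to a 1.5 mm scale, so storing them at twice the
#'   template spacing (the default) loses far less than the registration
#'   accuracy while bounding memory for large populations.
#' @param iteration_spacings voxel spacing (mm) used for each template
#'   iteration, recycled to `n_iterations`. The default runs the first half
#'   of the iterations at twice the native spacing and the rest at native
#'   resolution: the early iterations only have to move the template to the
#'   population barycenter, which is a coarse-scale task, while the later
#'   iterations sharpen it. The final transform re-estimation always runs
#'   at native resolution.
#' @param verbose print per-iteration progress.
#' @return Object of class `bone_template`: `template` ([scalar_volume]),
#'   `surface` ([triangle_mesh]), `transforms` (per-subject
#'   [subject_transform], template space to subject space),
#'   `iteration_log` (data.frame: iteration, mean_abs_change, mean_ssd),
#'   `grid`, `reference_index`.
#' @export
build_template <- function(volumes, n_iterations = 4L,
                           reg_params = default_reg_params(),
                           drift_step = 0.25, tol = 1e-3,
                           final_pass = TRUE,
                           final_reg_params = NULL,
                           field_storage_spacing = NULL,
                           surface_iso = NULL,
                           iteration_spacings = NULL,
                           verbose = FALSE) {
  if (is.null(surface_iso)) {
    surface_iso <- attr(volumes[[1]], "surface_iso")
    if (is.null(surface_iso)) surface_iso <- 0.5
  }
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (is.null(final_reg_params)) final_reg_params <- reg_params
  init <- init_template(volumes)
  template <- init$template
  grid <- init$grid
  subs <- init$resampled
  n <- length(subs)
  native_sp <- max(grid$spacing)
  if (is.null(iteration_spacings)) {
    n_coarse <- if (n_iterations >= 3L) floor(n_iterations / 2) else 0L
    iteration_spacings <- c(rep(2 * native_sp, n_coarse),
                            rep(native_sp, n_iterations - n_coarse))
  }
  iteration_spacings <- rep(iteration_spacings, length.out = n_iterations)
  # per-spacing copies of the subject volumes (downsampled once)
  sub_cache <- list()
  subs_at <- function(sp) {
    key <- format(sp)
    if (is.null(sub_cache[[key]])) {
      sub_cache[[key]] <<- if (abs(sp - native_sp) < 1e-9) subs else
        lapply(subs, resample_to_spacing, target_mm = sp)
    }
    sub_cache[[key]]
  }
  if (is.null(field_storage_spacing)) {
    field_storage_spacing <- 2 * max(grid$spacing)
  }
  store_grid <- {
    extent <- (grid$dims - 1) * grid$spacing
    sdims <- pmax(2L, as.integer(ceiling(extent / field_storage_spacing)) + 1L)
    list(origin = grid$origin, spacing = rep(field_storage_spacing, 3),
         dims = sdims)
  }
  shrink <- function(tr) {
    subject_transform(tr$affine, field_to_grid(tr$field, store_grid))
  }
  log_rows <- list()
  warm <- vector("list", n)
  homog <- function(a) rbind(cbind(a$linear, a$translation), c(0, 0, 0, 1))
  transforms <- NULL
  prev_spacing <- NA_real_
  for (it in seq_len(n_iterations)) {
    it_sp <- iteration_spacings[it]
    it_subs <- subs_at(it_sp)
    it_grid <- grid_of(it_subs[[1]])
    if (!identical(prev_spacing, it_sp)) {
      template <- resample_volume_to_grid(template, it_grid)
      prev_spacing <- it_sp
    }
    # incremental accumulation keeps memory flat in the population size:
    # per-subject full-resolution fields are transient
    sum_reg <- 0
    sum_u <- 0
    sum_log <- matrix(0, 4, 4)
    sum_hom <- matrix(0, 4, 4)
    log_ok <- TRUE
    ssd_sum <- 0
    for (i in seq_len(n)) {
      reg <- tryCatch(
        register_subject_to_template(it_subs[[i]], template, reg_params,
                                     init = warm[[i]]),
        error = function(e) {
          stop(sprintf("registration failed for subject %d: %s", i,
                       conditionMessage(e)))
        })
      sum_reg <- sum_reg + reg$registered$values
      sum_u <- sum_u + reg$transform$field$u
      lg <- tryCatch({
        l <- pracma::logm(homog(reg$transform$affine))
        if (any(!is.finite(l))) stop("log failed")
        Re(l)
      }, error = function(e) NULL)
      if (is.null(lg)) log_ok <- FALSE else sum_log <- sum_log + lg
      sum_hom <- sum_hom + homog(reg$transform$affine)
      ssd_sum <- ssd_sum + attr(reg$transform$field, "ssd_final")
      warm[[i]] <- shrink(reg$transform)
      rm(reg)
    }
    cand_vals <- sum_reg / n
    mean_ssd <- ssd_sum / n
    H <- if (log_ok) pracma::expm(sum_log / n) else sum_hom / n
    if (!log_ok) {
      warning("matrix log failed for an affine part; using arithmetic mean")
    }
    avg <- subject_transform(affine_transform(H[1:3, 1:3], H[1:3, 4]),
                             displacement_field(sum_u / n, it_grid$origin,
                                                it_grid$spacing))
    rm(sum_reg, sum_u)
    # drift correction: content moves a scaled step toward the population
    # barycenter; pulling back along -step * mean displacement moves the
    # template content along +step * mean displacement
    phi_minus_x <- subject_transform_displacement(avg, it_grid)
    rm(avg)
    cand <- scalar_volume(cand_vals, it_grid$origin, it_grid$spacing)
    fg <- cand$values > 0.1
    step_mm <- drift_step *
      mean(sqrt(phi_minus_x[, , , 1][fg]^2 + phi_minus_x[, , , 2][fg]^2 +
                  phi_minus_x[, , , 3][fg]^2))
    if (step_mm > 0.05 * max(it_grid$spacing)) {
      neg <- displacement_field(-drift_step * phi_minus_x, it_grid$origin,
                                it_grid$spacing)
      new_template <- warp_volume(cand, neg, grid = it_grid)
      rm(neg)
    } else {
      # a sub-5%-of-a-voxel step would only inject interpolation noise
      new_template <- cand
    }
    rm(phi_minus_x, cand)
    change <- mean(abs(new_template$values - template$values))
    log_rows[[it]] <- data.frame(iteration = it, mean_abs_change = change,
                                 mean_ssd = mean_ssd)
    if (verbose) {
      message(sprintf("template iteration %d: mean |dT| = %.5f, mean SSD = %.1f",
                      it, change, mean_ssd))
    }
    template <- new_template
    if (change < tol) break
  }
  # the template returns to (and the final transforms run at) native
  # resolution
  if (abs(iteration_spacings[length(iteration_spacings)] - native_sp) > 1e-9) {
    template <- resample_volume_to_grid(template, grid)
  }
  transforms <- warm
  if (final_pass) {
    for (i in seq_len(n)) {
      transforms[[i]] <- shrink(register_subject_to_template(
        subs[[i]], template, final_reg_params, init = warm[[i]])$transform)
    }
  }
  surface <- extract_surface(template, surface_iso)
  structure(list(template = template, surface = surface,
                 surface_iso = surface_iso,
                 transforms = transforms,
                 iteration_log = do.call(rbind, log_rows), grid = grid,
                 reference_index = init$reference_index,
                 n_subjects = n),
            class = "bone_template")
}

grid_world_coords <- function(grid, axis) {
  d <- grid$dims
  if (axis == 1) {
    array(rep.int(grid$origin[1] + grid$spacing[1] * (seq_len(d[1]) - 1L),
                  d[2] * d[3]), d)
  } else if (axis == 2) {
    array(rep.int(rep(grid$origin[2] + grid$spacing[2] * (seq_len(d[2]) - 1L),
                      each = d[1]), d[3]), d)
  } else {
    array(rep(grid$origin[3] + grid$spacing[3] * (seq_len(d[3]) - 1L),
              each = d[1] * d[2]), d)
  }
}

# phi(x) - x for a subject_transform evaluated on every grid voxel,
# returned as a [dims, 3] array
subject_transform_displacement <- function(transform, grid) {
  d <- grid$dims
  out <- array(0, c(d, 3L))
  L <- transform$affine$linear
  tt <- transform$affine$translation
  X <- grid_world_coords(grid, 1)
  Y <- grid_world_coords(grid, 2)
  Z <- grid_world_coords(grid, 3)
  if (!is.null(transform$field)) {
    fld <- field_to_grid(transform$field, grid)
    Xu <- X + fld$u[, , , 1]
    Yu <- Y + fld$u[, , , 2]
    Zu <- Z + fld$u[, , , 3]
  } else {
    Xu <- X; Yu <- Y; Zu <- Z
  }
  out[, , , 1] <- L[1, 1] * Xu + L[1, 2] * Yu + L[1, 3] * Zu + tt[1] - X
  out[, , , 2] <- L[2, 1] * Xu + L[2, 2] * Yu + L[2, 3] * Zu + tt[2] - Y
  out[, , , 3] <- L[3, 1] * Xu + L[3, 2] * Yu + L[3, 3] * Zu + tt[3] - Z
  out
}

#' @export
print.bone_template <- function(x, ...) {
  cat(sprintf("bone_template: %d subjects, %d iterations\n",
              x$n_subjects, nrow(x$iteration_log)))
  cat(sprintf("  grid %d x %d x %d @ %.2g mm; surface %d vertices\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              x$grid$spacing[1], nrow(x$surface$vertices)))
  cat(sprintf("  final mean |dT| = %.5f\n",
              tail(x$iteration_log$mean_abs_change, 1)))
  invisible(x)
}

#' @export
summary.bone_template <- function(object, ...) {
  print(object)
  cat("\niteration log:\n")
  print(object$iteration_log, row.names = FALSE)
  invisible(object$iteration_log)
}

#' @export
plot.bone_template <- function(x, ...) {
  graphics::plot(x$iteration_log$iteration, x$iteration_log$mean_abs_change,
                 type = "b", xlab = "iteration",
                 ylab = "mean |template change|", log = "y", ...)
  invisible(x)
}

#' Correspondence mean shape (comparator arm)
#'
#' A simplified stand-in for particle-based correspondence optimisation:
#' with `use_known_topology` (synthetic data sharing the base
#' triangulation) a generalized-Procrustes rigid alignment followed by the
#' vertex-wise mean; otherwise correspondence is established by
#' closest-point projection of the first mesh's vertices onto every other
#' mesh and the projections averaged.
#'
#' @param meshes list of ICP-aligned [triangle_mesh] objects.
#' @param use_known_topology logical; requires identical triangulations.
#' @param gpa_iter Procrustes iterations (known-topology mode).
#' @return A [triangle_mesh] mean shape.
#' @export
correspondence_mean_shape <- function(meshes, use_known_topology = TRUE,
                                      gpa_iter = 5L) {
  if (length(meshes) == 0L) stop("empty mesh list")
  stopifnot(all(vapply(meshes, inherits, TRUE, "triangle_mesh")))
  if (use_known_topology) {
    nv <- nrow(meshes[[1]]$vertices)
    same <- all(vapply(meshes, function(m) {
      nrow(m$vertices) == nv && identical(dim(m$faces),
                                          dim(meshes[[1]]$faces)) &&
        all(m$faces == meshes[[1]]$faces)
    }, TRUE))
    if (!same) stop("use_known_topology set but topologies differ")
    Vs <- lapply(meshes, `[[`, "vertices")
    mean_V <- Reduce(`+`, Vs) / length(Vs)
    for (it in seq_len(gpa_iter)) {
      Vs <- lapply(Vs, function(V) apply_rigid(kabsch_fit(V, mean_V), V))
      new_mean <- Reduce(`+`, Vs) / length(Vs)
      if (max(abs(new_mean - mean_V)) < 1e-10) {
        mean_V <- new_mean
        break
      }
      mean_V <- new_mean
    }
    out <- meshes[[1]]
    out$vertices <- mean_V
    out
  } else {
    ref <- meshes[[1]]
    acc <- ref$vertices
    for (m in meshes[-1]) {
      acc <- acc + closest_point_on_mesh(ref$vertices, m)$point
    }
    out <- ref
    out$vertices <- acc / length(meshes)
    out
  }
}
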