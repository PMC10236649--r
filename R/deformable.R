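# Deformable registration: a desk-scale, multi-resolution
# Gaussian-regularized demons-style method with Jacobian monitoring, plus
# displacement-field inversion, warping and transform averaging.

# crop two same-grid volumes to the bounding box of their joint support
crop_to_support <- function(fixed, moving, margin_vox = 6L, thresh = 1e-3) {
  d <- fixed$dims
  occ <- fixed$values > thresh | moving$values > thresh
  if (!any(occ)) return(list(fixed = fixed, moving = moving))
  # axis-wise occupancy via reshaped sums (cheap on megavoxel grids)
  a1 <- rowSums(matrix(occ, d[1])) > 0
  cs <- colSums(matrix(occ, d[1]))
  a2 <- rowSums(matrix(cs, d[2])) > 0
  a3 <- colSums(matrix(cs, d[2])) > 0
  lo <- pmax(1L, c(which(a1)[1], which(a2)[1], which(a3)[1]) - margin_vox)
  hi <- pmin(d, c(max(which(a1)), max(which(a2)), max(which(a3))) +
               margin_vox)
  if (all(lo == 1L) && all(hi == fixed$dims)) {
    return(list(fixed = fixed, moving = moving))
  }
  sub <- function(v) {
    scalar_volume(v$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                           drop = FALSE],
                  v$origin + (lo - 1L) * v$spacing, v$spacing)
  }
  list(fixed = sub(fixed), moving = sub(moving))
}

field_to_grid <- function(field, grid) {
  if (same_grid(field, grid)) return(field)
  comps <- lapply(1:3, function(c3) {
    cpp_resample(as.numeric(field$u[, , , c3]), as.integer(field$dims),
                 field$origin, field$spacing, as.integer(grid$dims),
                 grid$origin, grid$spacing)
  })
  # displacements queried outside the source grid fall to zero, which is
  # the right extrapolation for padded registration volumes
  u <- array(0, c(grid$dims, 3L))
  for (c3 in 1:3) u[, , , c3] <- comps[[c3]]
  displacement_field(u, grid$origin, grid$spacing)
}

#' Deformable (demons-style) registration of two scalar volumes
#'
#' Multi-resolution, Gaussian-regularized demons registration. The result
#' is a displacement field `u` on the fixed grid with the pull-back
#' meaning: the moving image resampled at `x + u(x)` matches the fixed
#' image. Both volumes must share a grid (affinely pre-align and resample
#' first).
#'
#' @param moving,fixed [scalar_volume] objects on the same grid.
#' @param levels coarse-to-fine spacings in mm (default `c(4, 2, 1)`).
#' @param iters_per_level demons iterations per level, recycled across
#'   levels (default 50; each level stops early when the SSD stagnates, so
#'   the cap mainly bounds the fine-level work).
#' @param update_sigma Gaussian sigma (mm) smoothing each update (fluid
#'   regularisation). Default 2 mm.
#' @param total_sigma Gaussian sigma (mm) smoothing the accumulated field
#'   (diffusion regularisation). Default 1.5 mm.
#' @param tol relative SSD stagnation tolerance for early stop.
#' @param init_field optional [displacement_field] warm start (resampled
#'   onto the coarsest level grid before iterating).
#' @return A [displacement_field] with attributes `ssd_initial`,
#'   `ssd_final`, `jacobian_positive_frac` and `ssd_trace`.
#' @export
deformable_register <- function(moving, fixed, levels = c(4, 2, 1),
                                iters_per_level = 50L, update_sigma = 2,
                                total_sigma = 1.5, tol = 2e-3,
                                init_field = NULL) {
  stopifnot(inherits(moving, "scalar_volume"), inherits(fixed, "scalar_volume"))
  if (!same_grid(moving, fixed)) {
    stop("moving and fixed must share a grid (resample after affine)")
  }
  if (sum(fixed$values) <= 0 && sum(moving$values) <= 0) {
    stop("empty (all-zero) volumes")
  }
  full_grid <- grid_of(fixed)
  # crop to the joint support (plus a smoothing margin): demons forces
  # vanish where both images are empty, so computation is confined to the
  # bounding box of the foreground
  crop <- crop_to_support(fixed, moving,
                          margin_vox = ceiling(3 * total_sigma /
                                                 max(fixed$spacing)) + 2L)
  fixed <- crop$fixed
  moving <- crop$moving
  if (!is.null(init_field)) init_field <- field_to_grid(init_field,
                                                        grid_of(fixed))
  extent <- max((fixed$dims - 1) * fixed$spacing)
  field <- init_field
  ssd_trace <- list()
  ssd0 <- NA_real_
  ssd1 <- NA_real_
  levels <- sort(levels, decreasing = TRUE)
  iters_per_level <- rep(as.integer(iters_per_level), length.out = length(levels))
  for (li in seq_along(levels)) {
    lev <- levels[li]
    if (lev >= max(fixed$spacing) * 1.01) {
      f <- resample_to_spacing(fixed, lev)
      m <- resample_to_spacing(moving, lev)
    } else {
      f <- fixed
      m <- moving
    }
    grid <- grid_of(f)
    u0 <- if (is.null(field)) zero_field(grid) else field_to_grid(field, grid)
    res <- cpp_demons(f$values, m$values,
                      u0$u, as.integer(grid$dims), grid$spacing,
                      iters_per_level[li], update_sigma, total_sigma,
                      tol, 2.0)
    field <- displacement_field(res$u, grid$origin, grid$spacing)
    ssd_trace[[length(ssd_trace) + 1]] <- res$ssd_trace
    # initial/final SSD of the finest level: the comparable pair
    ssd0 <- res$ssd_trace[1]
    ssd1 <- res$final_ssd
    if (field$max_mm > 0.5 * extent) {
      stop(sprintf("deformable_register: exploding field (max |u| %.1f mm over extent %.1f mm)",
                   field$max_mm, extent))
    }
  }
  field <- field_to_grid(field, grid_of(fixed))
  jfrac <- cpp_jacobian_positive_frac(field$u,
                                      as.integer(field$dims), field$spacing,
                                      fixed$values)
  # embed back into the full grid (zero displacement outside the support)
  field <- field_to_grid(field, full_grid)
  attr(field, "ssd_initial") <- ssd0
  attr(field, "ssd_final") <- ssd1
  attr(field, "jacobian_positive_frac") <- jfrac
  attr(field, "ssd_trace") <- ssd_trace
  field
}

#' Invert a displacement field
#'
#' Fixed-point iteration `v <- -u(x + v(x))`; errors if the mean
#' round-trip composition residual does not reach `tol`.
#'
#' @param field a [displacement_field] (regular: positive Jacobian).
#' @param iters maximum fixed-point iterations.
#' @param tol mean round-trip residual tolerance in mm.
#' @return The inverse [displacement_field], with attribute
#'   `roundtrip_mean_mm`.
#' @export
invert_field <- function(field, iters = 50L, tol = 0.05) {
  stopifnot(inherits(field, "displacement_field"))
  res <- cpp_invert_field(as.numeric(field$u), as.integer(field$dims),
                          field$spacing, as.integer(iters), tol / 10)
  if (res$roundtrip_mean_mm > tol) {
    stop(sprintf("invert_field: no convergence within %d iterations (mean residual %.4f mm > tol %.4f mm)",
                 iters, res$roundtrip_mean_mm, tol))
  }
  out <- displacement_field(res$v, field$origin, field$spacing)
  attr(out, "roundtrip_mean_mm") <- res$roundtrip_mean_mm
  out
}

transform_points <- function(transform, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (inherits(transform, "rigid_transform")) {
    return(apply_rigid(transform, points))
  }
  if (inherits(transform, "affine_transform")) {
    return(apply_affine(transform, points))
  }
  if (inherits(transform, "displacement_field")) {
    u <- field_displacement_at(transform, points)
    return(points + u)
  }
  if (inherits(transform, "subject_transform")) {
    p <- points
    if (!is.null(transform$field)) {
      p <- p + field_displacement_at(transform$field, p)
    }
    return(apply_affine(transform$affine, p))
  }
  stop("unknown transform type")
}

field_displacement_at <- function(field, points) {
  lo <- field$origin
  hi <- field$origin + (field$dims - 1) * field$spacing
  inside <- points[, 1] >= lo[1] & points[, 1] <= hi[1] &
    points[, 2] >= lo[2] & points[, 2] <= hi[2] &
    points[, 3] >= lo[3] & points[, 3] <= hi[3]
  u <- cpp_field_at_points(as.numeric(field$u), as.integer(field$dims),
                           field$origin, field$spacing, points)
  if (any(!inside)) {
    warning(sum(!inside), " point(s) outside the displacement-field domain; ",
            "affine-only extrapolation used there")
    u[!inside, ] <- 0
  }
  u
}

#' Transform points with any transform type
#'
#' Applies a rigid, affine, displacement-field or full subject transform to
#' world points. A [subject_transform] pushes template-space points into
#' subject space (`phi(x) = A(x + u(x))`); points outside the field domain
#' get affine-only extrapolation with a warning.
#'
#' @param points n x 3 matrix (mm).
#' @param transform a transform object.
#' @return n x 3 matrix of transformed points.
#' @export
warp_points <- function(points, transform) {
  transform_points(transform, points)
}

#' Resample a volume through a transform (pull-back)
#'
#' Output voxel `x` takes the value `vol(phi(x))` (trilinear, outside 0),
#' where `phi` is the transform and the output grid defaults to the field
#' grid of the transform (or the volume's own grid for affine-only input).
#'
#' @param vol a [scalar_volume].
#' @param transform [rigid_transform], [affine_transform],
#'   [displacement_field] or [subject_transform].
#' @param grid optional output grid `list(origin, spacing, dims)`.
#' @return A [scalar_volume] on the output grid.
#' @export
warp_volume <- function(vol, transform, grid = NULL) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (is.null(grid)) {
    if (inherits(transform, "subject_transform") && !is.null(transform$field)) {
      grid <- grid_of(transform$field)
    } else if (inherits(transform, "displacement_field")) {
      grid <- grid_of(transform)
    } else {
      grid <- grid_of(vol)
    }
  }
  d <- grid$dims
  # fast paths: pure affine / pure field warps stay in compiled code
  if (inherits(transform, "rigid_transform")) {
    transform <- affine_transform(transform$rotation, transform$translation)
  }
  if (inherits(transform, "affine_transform")) {
    vals <- cpp_warp_affine(vol$values, as.integer(vol$dims),
                            vol$origin, vol$spacing, as.integer(d),
                            grid$origin, grid$spacing, transform$linear,
                            transform$translation)
    return(scalar_volume(array(pmin(1, pmax(0, vals)), d), grid$origin,
                         grid$spacing))
  }
  if (inherits(transform, "displacement_field") && same_grid(transform, grid)) {
    vals <- cpp_warp_by_field(vol$values, as.integer(vol$dims),
                              vol$origin, vol$spacing,
                              as.numeric(transform$u), as.integer(d),
                              grid$origin, grid$spacing)
    return(scalar_volume(array(pmin(1, pmax(0, vals)), d), grid$origin,
                         grid$spacing))
  }
  pts <- cbind(
    rep.int(grid$origin[1] + grid$spacing[1] * (seq_len(d[1]) - 1L), d[2] * d[3]),
    rep.int(rep(grid$origin[2] + grid$spacing[2] * (seq_len(d[2]) - 1L),
                each = d[1]), d[3]),
    rep(grid$origin[3] + grid$spacing[3] * (seq_len(d[3]) - 1L),
        each = d[1] * d[2])
  )
  phi <- suppressWarnings(transform_points(transform, pts))
  vals <- cpp_interp_volume(vol$values, as.integer(vol$dims),
                            vol$origin, vol$spacing, phi)
  scalar_volume(array(pmin(1, pmax(0, vals)), d), grid$origin, grid$spacing)
}

#' Average a list of subject transforms
#'
#' Displacement fields are averaged component-wise on their shared grid;
#' affine parts are averaged in the log-Euclidean sense (matrix log/exp of
#' the homogeneous matrices), falling back to the arithmetic mean with a
#' warning if any matrix log fails.
#'
#' @param transforms non-empty list of [subject_transform] objects.
#' @return A [subject_transform].
#' @export
average_transforms <- function(transforms) {
  if (length(transforms) == 0L) stop("empty transform list")
  stopifnot(all(vapply(transforms, inherits, TRUE, "subject_transform")))
  homog <- function(a) rbind(cbind(a$linear, a$translation), c(0, 0, 0, 1))
  logs <- tryCatch(lapply(transforms, function(tr) {
    lg <- pracma::logm(homog(tr$affine))
    if (any(!is.finite(lg)) || max(abs(Im(as.complex(lg)))) > 1e-8) {
      stop("complex log")
    }
    Re(lg)
  }), error = function(e) NULL)
  if (is.null(logs)) {
    warning("matrix log failed for an affine part; using arithmetic mean")
    H <- Reduce(`+`, lapply(transforms, function(tr) homog(tr$affine))) /
      length(transforms)
  } else {
    H <- pracma::expm(Reduce(`+`, logs) / length(logs))
  }
  aff <- affine_transform(H[1:3, 1:3], H[1:3, 4])
  fields <- Filter(Negate(is.null), lapply(transforms, `[[`, "field"))
  fld <- NULL
  if (length(fields) > 0L) {
    g0 <- grid_of(fields[[1]])
    if (!all(vapply(fields, function(f) same_grid(f, g0), TRUE))) {
      stop("displacement fields are not on the same grid")
    }
    if (length(fields) != length(transforms)) {
      stop("either all or none of the transforms may carry a field")
    }
    u <- Reduce(`+`, lapply(fields, `[[`, "u")) / length(fields)
    fld <- displacement_field(u, g0$origin, g0$spacing)
  }
  subject_transform(aff, fld)
}
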