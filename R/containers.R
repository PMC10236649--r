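#' Triangle mesh container
#'
#' A triangulated surface in world millimetre coordinates, the unit of shape
#' exchange throughout the package (read and written as STL). Faces index
#' vertices 1-based and are oriented counter-clockwise seen from outside.
#'
#' @param vertices numeric N x 3 matrix of vertex coordinates (mm).
#' @param faces integer M x 3 matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh` with elements `vertices` and
#'   `faces`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an N x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an M x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("  bbox (mm): x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Named landmark set
#'
#' An ordered set of named 3D points (mm) tied to one shape or space. The
#' surgical-planning protocol in this package uses 11 landmarks, but the
#' container itself does not enforce a count.
#'
#' @param names character vector of unique landmark names.
#' @param points numeric n x 3 matrix of coordinates (mm).
#' @param frame optional identifier of the shape/space the points live in.
#' @return Object of class `landmark_set`.
#' @export
landmark_set <- function(names, points, frame = "unknown") {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  names <- as.character(names)
  if (length(names) != nrow(points)) stop("one name per point required")
  if (anyDuplicated(names)) stop("duplicate landmark names")
  if (ncol(points) != 3L) stop("points must be n x 3")
  if (!all(is.finite(points))) stop("non-finite landmark coordinates")
  rownames(points) <- names
  structure(list(names = names, points = points, frame = frame),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d landmarks (frame: %s)\n",
              length(x$names), x$frame))
  print(round(x$points, 3))
  invisible(x)
}

#' Scalar volume on a regular axis-aligned grid
#'
#' Values live on voxel centres: the world coordinate of voxel index
#' `(i, j, k)` (1-based in R) is `origin + spacing * (i-1, j-1, k-1)`.
#' Values are expected in `[0, 1]` (binary occupancy or averaged
#' pseudo-intensity), which is the substrate all registrations run on.
#'
#' @param values 3D numeric array.
#' @param origin length-3 world position (mm) of the first voxel centre.
#' @param spacing length-3 voxel spacing (mm), all positive.
#' @return Object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, origin, spacing) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("values must be a 3D array")
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  if (length(origin) != 3L || length(spacing) != 3L) {
    stop("origin and spacing must have length 3")
  }
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!all(is.finite(values))) stop("non-finite voxel values")
  rng <- range(values)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stop("voxel values must lie in [0, 1]")
  }
  structure(list(values = values, origin = origin, spacing = spacing,
                 dims = dim(values)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("scalar_volume: %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.2f, %.2f, %.2f) mm; value range [%.3g, %.3g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

grid_of <- function(vol) {
  list(origin = vol$origin, spacing = vol$spacing, dims = vol$dims)
}

same_grid <- function(a, b, tol = 1e-9) {
  all(a$dims == b$dims) && all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Rigid transform
#'
#' Applies as `x -> R x + t` with `R` a proper rotation.
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, det +1).
#' @param translation length-3 translation (mm).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation is not orthonormal")
  }
  if (det(rotation) < 0) stop("rotation must have det +1")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Affine transform
#'
#' Applies as `x -> L x + t`; used with the pull-back (resampling)
#' convention: registrations return the map from fixed-space coordinates to
#' moving-space coordinates.
#'
#' @param linear invertible 3 x 3 matrix.
#' @param translation length-3 translation (mm).
#' @return Object of class `affine_transform`.
#' @export
affine_transform <- function(linear = diag(3), translation = c(0, 0, 0)) {
  linear <- as.matrix(linear)
  translation <- as.numeric(translation)
  if (abs(det(linear)) <= 1e-6) stop("linear part is (near) singular")
  structure(list(linear = linear, translation = translation),
            class = "affine_transform")
}

#' Dense displacement field
#'
#' Vectors (mm) on a named reference grid; deforms points as
#' `x -> x + u(x)` with trilinear interpolation of `u`.
#'
#' @param u 4D array `[nx, ny, nz, 3]` of displacements (mm).
#' @param origin,spacing grid geometry of the reference volume.
#' @return Object of class `displacement_field`.
#' @export
displacement_field <- function(u, origin, spacing) {
  u <- as.array(u)
  if (length(dim(u)) != 4L || dim(u)[4] != 3L) {
    stop("u must be a [nx, ny, nz, 3] array")
  }
  if (!all(is.finite(u))) stop("non-finite displacement values")
  n3 <- length(u) / 3L
  mag2 <- u[seq_len(n3)]^2 + u[n3 + seq_len(n3)]^2 + u[2L * n3 + seq_len(n3)]^2
  structure(list(u = u, origin = as.numeric(origin),
                 spacing = as.numeric(spacing), dims = dim(u)[1:3],
                 max_mm = sqrt(max(mag2))),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf("displacement_field: %d x %d x %d grid, max |u| = %.3f mm\n",
              x$dims[1], x$dims[2], x$dims[3], x$max_mm))
  invisible(x)
}

zero_field <- function(grid) {
  displacement_field(array(0, c(grid$dims, 3L)), grid$origin, grid$spacing)
}

#' Per-subject transform (template space to subject space)
#'
#' The composition used to carry template-space coordinates into a subject:
#' the displacement field acts first on the template grid, then the affine
#' part, i.e. `phi(x) = L (x + u(x)) + t`. The same object serves pull-back
#' resampling of subject images onto the template grid and forward transport
#' of template landmarks into subject space.
#'
#' @param affine an [affine_transform].
#' @param field a [displacement_field] on the template grid, or `NULL` for
#'   an affine-only transform.
#' @return Object of class `subject_transform`.
#' @export
subject_transform <- function(affine = affine_transform(), field = NULL) {
  if (!inherits(affine, "affine_transform")) stop("affine part invalid")
  if (!is.null(field) && !inherits(field, "displacement_field")) {
    stop("field part invalid")
  }
  structure(list(affine = affine, field = field), class = "subject_transform")
}

#' @export
print.subject_transform <- function(x, ...) {
  cat("subject_transform (template -> subject)\n")
  cat("  affine linear:\n")
  print(round(x$affine$linear, 5))
  cat(sprintf("  translation: (%.3f, %.3f, %.3f) mm\n",
              x$affine$translation[1], x$affine$translation[2],
              x$affine$translation[3]))
  if (!is.null(x$field)) {
    cat(sprintf("  deformable part: max |u| = %.3f mm\n", x$field$max_mm))
  } else {
    cat("  deformable part: none\n")
  }
  invisible(x)
}
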