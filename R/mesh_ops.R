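# Mesh <-> volume conversion and surface comparison.

# every undirected edge must be used by exactly two faces, once per
# direction, for the parity tests below to be meaningful
is_watertight <- function(mesh) {
  F <- mesh$faces
  if (nrow(F) == 0L) return(FALSE)
  e <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key)) return(FALSE)
  und_key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(und_key) == 2L)
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin). A consistently inward-oriented mesh is detected, reported
#' with a warning, and its volume returned positive.
#'
#' @param mesh a watertight [triangle_mesh].
#' @return Enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  vol <- sum(a * cr) / 6
  if (vol < 0) {
    warning("mesh is inward-oriented; returning |volume| ",
            "(orientation auto-fixed)")
    vol <- -vol
  }
  vol
}

# flip faces so outward normals give positive signed volume
ensure_outward <- function(mesh) {
  V <- mesh$vertices
  F <- mesh$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c[, 3] - b[, 3] * c[, 2],
              b[, 3] * c[, 1] - b[, 1] * c[, 3],
              b[, 1] * c[, 2] - b[, 2] * c[, 1])
  if (sum(a * cr) < 0) mesh$faces <- F[, c(1, 3, 2)]
  mesh
}

#' Convert a watertight mesh to an occupancy or pseudo-intensity volume
#'
#' Voxel centres are classified inside/outside by a parity (ray-crossing)
#' test; the grid is the mesh bounding box padded by `padding` voxels.
#' Optional Gaussian smoothing (sigma in mm) turns the binary occupancy
#' into a smooth pseudo-intensity. With `intensity = "depth"` the interior
#' Euclidean depth (distance to the surface, clamped at `depth_tau`) is
#' blended in, so the image carries radial structure inside the bone: a
#' thin shaft then looks different from a thick one everywhere, not just at
#' the boundary, which anchors intensity-based registration against
#' sliding a thin bone inside a thicker template.
#'
#' @param mesh a watertight [triangle_mesh].
#' @param spacing voxel spacing in mm (scalar or length 3). Default 1 mm.
#' @param padding number of padding voxels on every side. Default 4.
#' @param smooth_sigma Gaussian smoothing sigma in mm (0 = no smoothing).
#' @param intensity `"occupancy"` (default; optionally smoothed) or
#'   `"depth"` (equal blend of smoothed occupancy and clamped interior
#'   depth).
#' @param depth_tau depth clamp in mm for `intensity = "depth"`
#'   (default 10).
#' @param grid optional list(origin, spacing, dims) forcing an explicit
#'   output grid (used when several subjects must share one grid).
#' @return A [scalar_volume] with values in `[0, 1]`.
#' @export
voxelize <- function(mesh, spacing = 1, padding = 4, smooth_sigma = 0,
                     intensity = c("occupancy", "depth"), depth_tau = 10,
                     grid = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  intensity <- match.arg(intensity)
  if (!is_watertight(mesh)) {
    stop("voxelize requires a watertight mesh (open or inconsistent surface)")
  }
  if (is.null(grid)) {
    spacing <- rep(as.numeric(spacing), length.out = 3)
    if (any(spacing <= 0)) stop("spacing must be positive")
    lo <- apply(mesh$vertices, 2, min) - padding * spacing
    hi <- apply(mesh$vertices, 2, max) + padding * spacing
    dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
    origin <- lo
  } else {
    origin <- grid$origin
    spacing <- grid$spacing
    dims <- grid$dims
  }
  occ <- cpp_voxelize(mesh$vertices, mesh$faces - 1L, origin, spacing,
                      as.integer(dims))
  vals <- occ
  if (smooth_sigma > 0) {
    vals <- cpp_smooth3(occ, as.integer(dims), smooth_sigma / spacing)
  }
  if (intensity == "depth") {
    depth <- cpp_interior_depth(occ, as.integer(dims), spacing)
    vals <- 0.5 * vals + 0.5 * pmin(1, depth / depth_tau)
    dim(vals) <- dims
  }
  out <- scalar_volume(vals, origin, spacing)
  # the value the true surface sits at: 0.5 for (smoothed) occupancy,
  # 0.25 for the depth blend (surface = half occupancy + zero depth)
  attr(out, "surface_iso") <- if (intensity == "depth") 0.25 else 0.5
  out
}

#' Extract an iso-surface from a scalar volume
#'
#' Marching tetrahedra at the given iso level; only the largest connected
#' component is kept. Vertices come out in world mm.
#'
#' @param volume a [scalar_volume].
#' @param iso iso level (default 0.5, the occupancy midpoint).
#' @return A [triangle_mesh].
#' @export
extract_surface <- function(volume, iso = 0.5) {
  stopifnot(inherits(volume, "scalar_volume"))
  rng <- range(volume$values)
  if (iso <= rng[1] || iso >= rng[2]) {
    stop(sprintf("iso level %.3g outside value range [%.3g, %.3g]",
                 iso, rng[1], rng[2]))
  }
  res <- cpp_marching_tets(volume$values,
                           as.integer(volume$dims), volume$origin,
                           volume$spacing, iso)
  V <- res$vertices
  F <- res$faces + 1L
  if (nrow(F) == 0L) stop("no surface found at iso level")
  lab <- cpp_face_components(F - 1L, nrow(V))
  keep_lab <- as.integer(names(which.max(table(lab))))
  F <- F[lab == keep_lab, , drop = FALSE]
  used <- sort(unique(as.vector(F)))
  remap <- integer(nrow(V))
  remap[used] <- seq_along(used)
  mesh <- triangle_mesh(V[used, , drop = FALSE],
                        matrix(remap[F], ncol = 3))
  ensure_outward(mesh)
}

#' Closest points on a mesh surface
#'
#' For each query point, the closest point on the triangulated surface, the
#' distance and the face hit.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a [triangle_mesh].
#' @return list with `dist` (mm), `point` (n x 3), `face` (1-based index).
#' @export
closest_point_on_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_closest_on_mesh(points, mesh$vertices, mesh$faces - 1L)
}

#' Are points inside a watertight mesh?
#'
#' Parity (ray-crossing) containment test.
#'
#' @param points n x 3 matrix (mm).
#' @param mesh a watertight [triangle_mesh].
#' @return Logical vector.
#' @export
points_in_mesh <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_points_in_mesh(points, mesh$vertices, mesh$faces - 1L)
}

#' Signed surface-distance model between two meshes
#'
#' Per-vertex distance from the carrier mesh to the reference surface,
#' signed negative where the carrier vertex lies inside the reference
#' (parity test), plus a histogram over the display range -6..6 mm
#' (0.5 mm bins with underflow/overflow bins) and the symmetric Hausdorff
#' distance. Both meshes must already live in a common frame (run
#' [icp_align()] first when they do not).
#'
#' @param carrier [triangle_mesh] whose vertices carry the distances.
#' @param reference [triangle_mesh] measured against.
#' @param range_mm display range for the histogram (default `c(-6, 6)`).
#' @param bin_mm histogram bin width (default 0.5 mm).
#' @return Object of class `distance_model`: `distances` (signed mm per
#'   carrier vertex), `breaks`, `counts` (with open end bins),
#'   `hausdorff_mm`, `mean_abs_mm`.
#' @export
distance_model <- function(carrier, reference, range_mm = c(-6, 6),
                           bin_mm = 0.5) {
  stopifnot(inherits(carrier, "triangle_mesh"),
            inherits(reference, "triangle_mesh"))
  if (nrow(carrier$vertices) == 0L || nrow(reference$vertices) == 0L) {
    stop("empty mesh")
  }
  cq <- closest_point_on_mesh(carrier$vertices, reference)
  d <- cq$dist
  inside <- points_in_mesh(carrier$vertices, reference)
  d[inside] <- -d[inside]
  # symmetric Hausdorff: max of the two directed maxima (vertex-sampled)
  back <- closest_point_on_mesh(reference$vertices, carrier)
  hausdorff <- max(max(cq$dist), max(back$dist))
  breaks <- c(-Inf, seq(range_mm[1], range_mm[2], by = bin_mm), Inf)
  counts <- as.integer(table(cut(d, breaks = breaks)))
  structure(list(distances = d, breaks = breaks, counts = counts,
                 hausdorff_mm = hausdorff, mean_abs_mm = mean(abs(d)),
                 range_mm = range_mm, bin_mm = bin_mm),
            class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("distance_model: %d carrier vertices\n", length(x$distances)))
  cat(sprintf("  signed distance: mean %.3f mm, mean |d| %.3f mm, range [%.3f, %.3f] mm\n",
              mean(x$distances), x$mean_abs_mm, min(x$distances),
              max(x$distances)))
  cat(sprintf("  symmetric Hausdorff: %.3f mm\n", x$hausdorff_mm))
  invisible(x)
}

#' @export
plot.distance_model <- function(x, ...) {
  mids <- seq(x$range_mm[1] + x$bin_mm / 2, x$range_mm[2] - x$bin_mm / 2,
              by = x$bin_mm)
  inner <- x$counts[2:(length(x$counts) - 1)]
  graphics::barplot(inner, names.arg = sprintf("%.1f", mids),
                    xlab = "signed distance (mm)", ylab = "vertex count",
                    las = 2, ...)
  invisible(x)
}

# mean distance from (a sample of) mesh a's vertices to surface b
directed_mean_surface_distance <- function(a, b, n_sample = 2000L) {
  V <- a$vertices
  if (nrow(V) > n_sample) {
    idx <- round(seq(1L, nrow(V), length.out = n_sample))
    V <- V[idx, , drop = FALSE]
  }
  mean(closest_point_on_mesh(V, b)$dist)
}

#' Symmetric mean surface distance between two meshes
#'
#' Average of the two directed vertex-to-surface mean distances, on a
#' deterministic vertex subsample for large meshes.
#'
#' @param a,b [triangle_mesh] objects.
#' @param n_sample maximum vertices sampled per direction.
#' @return Mean surface distance in mm.
#' @export
mean_surface_distance <- function(a, b, n_sample = 2000L) {
  (directed_mean_surface_distance(a, b, n_sample) +
     directed_mean_surface_distance(b, a, n_sample)) / 2
}


#' Common voxelization grid for a set of aligned meshes
#'
#' The padded union bounding box at one spacing. Voxelizing every subject
#' of an aligned population on the same grid removes the per-subject
#' half-voxel quantization offsets that independent grids would introduce.
#'
#' @param meshes list of [triangle_mesh] objects.
#' @param spacing voxel spacing in mm (scalar or length 3).
#' @param padding padding voxels on every side.
#' @return A grid list(origin, spacing, dims) for [voxelize()].
#' @export
common_grid <- function(meshes, spacing = 1, padding = 4) {
  spacing <- rep(as.numeric(spacing), length.out = 3)
  lo <- Reduce(pmin, lapply(meshes, function(m) apply(m$vertices, 2, min)))
  hi <- Reduce(pmax, lapply(meshes, function(m) apply(m$vertices, 2, max)))
  lo <- lo - padding * spacing
  hi <- hi + padding * spacing
  list(origin = lo, spacing = spacing,
       dims = pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L))
}
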