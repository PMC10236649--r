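# Synthetic humerus-like populations with known latent shape modes.
#
# The base shape is a solid of revolution emulating a long bone: spherical
# proximal head, cylindrical shaft, flared distal end (a frustum) with a
# flat distal cap. Ring radii are area-compensated so every polygonal
# cross-section has exactly the area of its generating circle, which makes
# the mesh volume track the analytic solid volume at any resolution.

bone_profile <- function(length_mm) {
  list(length = length_mm,
       head_radius = 0.075 * length_mm,
       shaft_radius = 0.036 * length_mm,
       distal_radius = 0.055 * length_mm,
       flare_len = 0.23 * length_mm)
}

#' Analytic volume of the base long-bone solid
#'
#' Exact volume of the generating solid of revolution (frustum + cylinder +
#' spherical head segment) used by [make_base_shape()]; the oracle for
#' voxelization and mesh-volume checks.
#'
#' @param length_mm total bone length in mm (default 300).
#' @return Volume in mm^3.
#' @export
base_shape_analytic_volume <- function(length_mm = 300) {
  p <- bone_profile(length_mm)
  zc <- p$length - p$head_radius
  zj <- zc - sqrt(p$head_radius^2 - p$shaft_radius^2)
  v_frustum <- pi * p$flare_len / 3 *
    (p$distal_radius^2 + p$distal_radius * p$shaft_radius + p$shaft_radius^2)
  v_cyl <- pi * p$shaft_radius^2 * (zj - p$flare_len)
  a <- zj - zc
  b <- p$head_radius
  v_head <- pi * (p$head_radius^2 * (b - a) - (b^3 - a^3) / 3)
  v_frustum + v_cyl + v_head
}

#' Construct the base humerus-like shape and its 11 landmarks
#'
#' Deterministic watertight surface of revolution with a spherical proximal
#' head, cylindrical shaft and flared distal end. Eleven named landmarks
#' (head apex, head equator pair, surgical-neck pair, mid-shaft pair,
#' epicondyle analog pair, trochlea/capitulum analog pair) sit exactly on
#' mesh vertices at fixed parametric locations, analogous to the clinical
#' landmark protocol on a real humerus.
#'
#' @param resolution subdivision level >= 1; level 2 gives about 6k
#'   vertices.
#' @param length_mm total bone length in mm (default 300).
#' @return List with `mesh` ([triangle_mesh]), `landmarks`
#'   ([landmark_set]) and `landmark_vertex` (vertex index of each
#'   landmark).
#' @export
make_base_shape <- function(resolution = 2, length_mm = 300) {
  if (resolution < 1) stop("resolution must be >= 1")
  p <- bone_profile(length_mm)
  n_theta <- 16L * 2L^(resolution - 1L)
  n_theta <- as.integer(4 * ceiling(n_theta / 4))  # keep quadrant vertices
  zc <- p$length - p$head_radius
  zj <- zc - sqrt(p$head_radius^2 - p$shaft_radius^2)

  # axial stations: frustum, cylinder, spherical head (by polar angle)
  nf <- 6L * resolution
  ncyl <- 20L * resolution
  nsph <- 10L * resolution
  z_frustum <- seq(0, p$flare_len, length.out = nf + 1L)
  z_cyl <- seq(p$flare_len, zj, length.out = ncyl + 1L)[-1]
  ang_j <- asin((zj - zc) / p$head_radius)  # negative
  ang <- seq(ang_j, pi / 2, length.out = nsph + 1L)[-1]
  z_sph <- zc + p$head_radius * sin(ang)
  z_sph <- z_sph[-length(z_sph)]  # apex handled as a point
  z_all <- c(z_frustum, z_cyl, z_sph)
  r_of_z <- function(z) {
    ifelse(z <= p$flare_len,
           p$distal_radius + (p$shaft_radius - p$distal_radius) *
             z / p$flare_len,
           ifelse(z <= zj, p$shaft_radius,
                  sqrt(pmax(0, p$head_radius^2 - (z - zc)^2))))
  }
  r_all <- r_of_z(z_all)
  # area compensation: polygon ring with compensated radius has the exact
  # area of the generating circle
  comp <- sqrt((2 * pi / n_theta) / sin(2 * pi / n_theta))
  theta <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  nring <- length(z_all)
  # mild surface reliefs analogous to the deltoid tuberosity and the
  # bicipital groove: a long bone is otherwise a near-surface-of-revolution
  # on which axial and rotational correspondence is unobservable; real bones
  # carry exactly such features, and they amount to well under 1% of the
  # solid volume
  ang <- function(th, th0) {
    d <- abs(th - th0)
    pmin(d, 2 * pi - d)
  }
  relief <- function(s, th) {
    0.012 * p$length * exp(-((s - 0.55) / 0.07)^2 - (ang(th, 0) / 0.5)^2) -
      0.008 * p$length * exp(-((s - 0.78) / 0.05)^2 - (ang(th, pi / 2) / 0.35)^2)
  }
  verts <- matrix(0, nrow = nring * n_theta + 2L, ncol = 3)
  for (q in seq_len(nring)) {
    rows <- (q - 1L) * n_theta + seq_len(n_theta)
    rr <- comp * r_all[q] + relief(z_all[q] / p$length, theta)
    verts[rows, 1] <- rr * cos(theta)
    verts[rows, 2] <- rr * sin(theta)
    verts[rows, 3] <- z_all[q]
  }
  i_bottom <- nring * n_theta + 1L   # distal cap centre
  i_apex <- nring * n_theta + 2L     # proximal apex
  verts[i_bottom, ] <- c(0, 0, 0)
  verts[i_apex, ] <- c(0, 0, p$length)

  faces <- list()
  ring_idx <- function(q) (q - 1L) * n_theta + seq_len(n_theta)
  nxt <- c(seq_len(n_theta)[-1], 1L)
  for (q in seq_len(nring - 1L)) {
    a <- ring_idx(q); b <- ring_idx(q + 1L)
    # outward orientation (CCW seen from outside, +z up)
    faces[[length(faces) + 1L]] <- cbind(a, a[nxt], b[nxt])
    faces[[length(faces) + 1L]] <- cbind(a, b[nxt], b)
  }
  a <- ring_idx(1L)
  faces[[length(faces) + 1L]] <- cbind(a[nxt], a, i_bottom)
  a <- ring_idx(nring)
  faces[[length(faces) + 1L]] <- cbind(a, a[nxt], i_apex)
  mesh <- triangle_mesh(verts, do.call(rbind, faces))
  mesh <- ensure_outward(mesh)

  # landmark vertices at fixed parametric stations
  q_at <- function(z) which.min(abs(z_all - z))
  v_at <- function(q, frac_theta) {
    (q - 1L) * n_theta + 1L + as.integer(round(frac_theta * n_theta)) %% n_theta
  }
  q_eq <- q_at(zc)          # head equator
  q_neck <- q_at(zj)        # surgical neck
  q_mid <- q_at(p$length / 2)
  q_dist <- 1L              # distal rim
  q_troch <- q_at(0.06 * p$length)
  lm_vertex <- c(head_apex = i_apex,
                 head_equator_ant = v_at(q_eq, 0),
                 head_equator_post = v_at(q_eq, 0.5),
                 surgical_neck_med = v_at(q_neck, 0.25),
                 surgical_neck_lat = v_at(q_neck, 0.75),
                 midshaft_ant = v_at(q_mid, 0),
                 midshaft_post = v_at(q_mid, 0.5),
                 epicondyle_med = v_at(q_dist, 0.25),
                 epicondyle_lat = v_at(q_dist, 0.75),
                 trochlea_analog = v_at(q_troch, 0),
                 capitulum_analog = v_at(q_troch, 0.5))
  landmarks <- landmark_set(names(lm_vertex), mesh$vertices[lm_vertex, ],
                            frame = "base")
  list(mesh = mesh, landmarks = landmarks, landmark_vertex = lm_vertex)
}

# Seven smooth global deformation fields on the base vertices, as 3N-vectors
# parameterised by the normalized axial coordinate s. The leading five
# fields (the default planted modes) deform the visible surface globally -
# bending, head size, length, taper - so image registration can observe
# them; torsion (tangential, nearly invisible on a surface of revolution)
# and the localized distal flare come last. Fields are orthogonalized by
# Gram-Schmidt over all vertices, then a second orthogonalization pass with
# respect to the landmark-restricted inner product so the planted modes are
# exactly orthogonal where the landmark point clouds observe them; finally
# scaled to unit RMS landmark displacement so a mode amplitude of a mm
# moves a typical landmark by about a mm. A conditioning guard rejects any
# field whose surface amplitude would be inflated far beyond its landmark
# amplitude.
deformation_basis <- function(base) {
  V <- base$mesh$vertices
  n <- nrow(V)
  L <- max(V[, 3])
  s <- V[, 3] / L
  r <- sqrt(V[, 1]^2 + V[, 2]^2)
  runit <- cbind(ifelse(r > 1e-9, V[, 1] / r, 0),
                 ifelse(r > 1e-9, V[, 2] / r, 0), 0)
  zc <- L - 0.075 * L
  fields <- list(
    bend_x = cbind(s^2, 0, 0),
    bend_y = cbind(0, s^2, 0),
    head_bulge = exp(-((s - 0.9) / 0.12)^2) *
      cbind(V[, 1], V[, 2], V[, 3] - zc) / (0.075 * L),
    length_scale = cbind(0, 0, s - 0.5),
    shaft_taper = (1 - s) * runit,
    torsion = cbind(-V[, 2], V[, 1], 0) * s / max(r),
    distal_flare = exp(-(s / 0.12)^2) * runit
  )
  B <- vapply(fields, function(f) as.numeric(f), numeric(3 * n))
  # pass 1: orthogonalize over all vertices
  for (j in seq_len(ncol(B))) {
    if (j > 1) {
      for (i in seq_len(j - 1)) {
        B[, j] <- B[, j] - sum(B[, i] * B[, j]) / sum(B[, i]^2) * B[, i]
      }
    }
    B[, j] <- B[, j] / sqrt(mean(matrix(B[, j], ncol = 3)^2) * 3)
  }
  # pass 2: orthogonalize w.r.t. the landmark restriction
  lm <- base$landmark_vertex
  restrict <- function(col) {
    m <- matrix(col, ncol = 3)
    as.numeric(m[lm, ])
  }
  for (j in seq_len(ncol(B))) {
    if (j > 1) {
      for (i in seq_len(j - 1)) {
        bi <- restrict(B[, i]); bj <- restrict(B[, j])
        B[, j] <- B[, j] - sum(bi * bj) / sum(bi^2) * B[, i]
      }
    }
    blm <- restrict(B[, j])
    rms_lm <- sqrt(mean(matrix(blm, ncol = 3)^2) * 3)
    if (rms_lm < 1e-8) stop("degenerate deformation basis at landmarks")
    B[, j] <- B[, j] / rms_lm
    # conditioning guard: a unit (1 mm) mode amplitude must not displace
    # any surface vertex by more than a few mm
    max_surf <- max(sqrt(rowSums(matrix(B[, j], ncol = 3)^2)))
    if (max_surf > 4) {
      stop(sprintf("deformation field %d ill-conditioned at the landmarks (max surface amplification %.1f)",
                   j, max_surf))
    }
  }
  colnames(B) <- names(fields)
  B
}

#' Specification of a synthetic population
#'
#' Defines the statistical structure of a generated arm: number of
#' subjects, number of latent deformation modes with their per-mode
#' standard deviations (mm of typical landmark displacement), rigid pose
#' jitter, iid vertex noise and the generation seed.
#'
#' @param n_subjects number of subjects (>= 2). Defaults mirror a 50-subject
#'   arm; a second study arm uses 43.
#' @param n_modes number of latent deformation modes k (0..7).
#' @param mode_amplitudes per-mode standard deviations in mm (length
#'   `n_modes`).
#' @param pose_rotation_sd rigid pose jitter, degrees (per axis sd).
#' @param pose_translation_sd rigid pose jitter, mm (per axis sd).
#' @param vertex_noise_sd iid Gaussian surface noise, mm.
#' @param seed integer generation seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 50L, n_modes = 5L,
                            mode_amplitudes = c(5, 4, 3, 2.5, 2),
                            pose_rotation_sd = 2, pose_translation_sd = 2,
                            vertex_noise_sd = 0.05, seed = 1L) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (n_modes < 0) stop("n_modes must be >= 0")
  if (length(mode_amplitudes) != n_modes) {
    stop("mode_amplitudes must have length n_modes")
  }
  if (any(c(mode_amplitudes, pose_rotation_sd, pose_translation_sd,
            vertex_noise_sd) < 0)) {
    stop("standard deviations must be >= 0")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_modes = as.integer(n_modes),
                 mode_amplitudes = as.numeric(mode_amplitudes),
                 pose_rotation_sd = pose_rotation_sd,
                 pose_translation_sd = pose_translation_sd,
                 vertex_noise_sd = vertex_noise_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

small_rotation <- function(angles_deg) {
  a <- angles_deg * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Generate a synthetic population of bone shapes
#'
#' Each subject's vertices are `rigid(pose) o (base + sum_j c_j basis_j)`
#' plus iid Gaussian vertex noise, with `c_j ~ N(0, amplitude_j^2)`.
#' Landmarks are carried through exactly the same deformation map (latent
#' modes and pose) but never receive vertex noise, so landmark-transfer
#' error downstream isolates pipeline error. The rigid pose rotates about
#' the deformed shape's centroid.
#'
#' @param base result of [make_base_shape()].
#' @param spec a [population_spec].
#' @return Object of class `bone_population`: list of samples (each with
#'   `mesh`, `landmarks`, `latent_coeffs`, `pose`), plus `spec`, `base` and
#'   the deformation `basis`.
#' @export
make_population <- function(base, spec) {
  stopifnot(inherits(spec, "population_spec"))
  B <- deformation_basis(base)
  if (spec$n_modes > ncol(B)) {
    stop("n_modes exceeds the ", ncol(B), " available basis fields")
  }
  V0 <- base$mesh$vertices
  n <- nrow(V0)
  lmv <- base$landmark_vertex
  samples <- local_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      coeffs <- if (spec$n_modes > 0) {
        rnorm(spec$n_modes, 0, spec$mode_amplitudes)
      } else {
        numeric(0)
      }
      disp <- if (spec$n_modes > 0) {
        matrix(B[, seq_len(spec$n_modes), drop = FALSE] %*% coeffs, ncol = 3)
      } else {
        matrix(0, n, 3)
      }
      Vd <- V0 + disp
      ctr <- colMeans(Vd)
      R <- small_rotation(rnorm(3, 0, spec$pose_rotation_sd))
      tr <- rnorm(3, 0, spec$pose_translation_sd)
      pose <- rigid_transform(R, ctr - as.numeric(R %*% ctr) + tr)
      Vp <- apply_rigid(pose, Vd)
      noise <- if (spec$vertex_noise_sd > 0) {
        matrix(rnorm(3 * n, 0, spec$vertex_noise_sd), ncol = 3)
      } else {
        matrix(0, n, 3)
      }
      mesh <- base$mesh
      mesh$vertices <- Vp + noise
      lms <- landmark_set(names(lmv), apply_rigid(pose, Vd[lmv, , drop = FALSE]),
                          frame = sprintf("subject_%03d", i))
      list(mesh = mesh, landmarks = lms, latent_coeffs = coeffs, pose = pose)
    })
  })
  structure(list(samples = samples, spec = spec, base = base, basis = B),
            class = "bone_population")
}

#' @export
print.bone_population <- function(x, ...) {
  cat(sprintf("bone_population: %d subjects, %d latent modes, seed %d\n",
              x$spec$n_subjects, x$spec$n_modes, x$spec$seed))
  if (x$spec$n_modes > 0) {
    cat("  mode amplitudes (mm):",
        paste(format(x$spec$mode_amplitudes), collapse = ", "), "\n")
  }
  cat(sprintf("  pose jitter: %.2g deg / %.2g mm; vertex noise %.3g mm\n",
              x$spec$pose_rotation_sd, x$spec$pose_translation_sd,
              x$spec$vertex_noise_sd))
  invisible(x)
}

#' Write a population to disk
#'
#' One binary STL and one landmark CSV per subject plus a JSON manifest
#' holding the spec and the per-subject latent coefficients and poses.
#'
#' @param population a [bone_population].
#' @param dir output directory (created if missing).
#' @return The manifest path, invisibly.
#' @export
write_population <- function(population, dir) {
  stopifnot(inherits(population, "bone_population"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n <- length(population$samples)
  for (i in seq_len(n)) {
    s <- population$samples[[i]]
    write_stl(s$mesh, file.path(dir, sprintf("subject_%03d.stl", i)))
    write_landmarks(s$landmarks,
                    file.path(dir, sprintf("subject_%03d_landmarks.csv", i)))
  }
  manifest <- list(
    spec = unclass(population$spec),
    subjects = lapply(seq_len(n), function(i) {
      s <- population$samples[[i]]
      list(stl = sprintf("subject_%03d.stl", i),
           landmarks = sprintf("subject_%03d_landmarks.csv", i),
           latent_coeffs = s$latent_coeffs,
           pose_rotation = as.numeric(s$pose$rotation),
           pose_translation = s$pose$translation)
    })
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
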