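# Synthetic population generator: base shape, latent modes, determinism.

test_that("base shape is watertight with on-surface landmarks and is deterministic", {
  base <- base_shape_fixture(2)
  expect_true(is_watertight(base$mesh))
  # Euler characteristic of a closed genus-0 surface
  nv <- nrow(base$mesh$vertices)
  nf <- nrow(base$mesh$faces)
  ne <- 3L * nf / 2L
  expect_equal(nv - ne + nf, 2)
  expect_equal(length(base$landmarks$names), 11L)
  d <- closest_point_on_mesh(base$landmarks$points, base$mesh)$dist
  expect_lt(max(d), 1e-6)
  again <- make_base_shape(2)
  expect_identical(again$mesh$vertices, base$mesh$vertices)
  expect_identical(again$landmarks$points, base$landmarks$points)
})

test_that("base shape volume tracks the analytic composite solid at any resolution", {
  va <- base_shape_analytic_volume(300)
  for (res in 1:3) {
    vm <- mesh_volume(make_base_shape(res)$mesh)
    expect_lt(abs(vm - va) / va, 0.02)
  }
  # length is configurable
  short <- make_base_shape(2, length_mm = 150)
  expect_equal(max(short$mesh$vertices[, 3]), 150)
  expect_lt(abs(mesh_volume(short$mesh) - base_shape_analytic_volume(150)) /
              base_shape_analytic_volume(150), 0.02)
})

test_that("zero-variation spec reproduces the base exactly for every subject", {
  base <- base_shape_fixture(2)
  spec <- population_spec(n_subjects = 3, n_modes = 0,
                          mode_amplitudes = numeric(0),
                          pose_rotation_sd = 0, pose_translation_sd = 0,
                          vertex_noise_sd = 0, seed = 5)
  pop <- make_population(base, spec)
  for (s in pop$samples) {
    expect_equal(s$mesh$vertices, base$mesh$vertices, tolerance = 1e-12)
    expect_equal(s$landmarks$points, base$landmarks$points,
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("latent coefficients have the specified spread and are reproducible", {
  base <- base_shape_fixture(2)
  spec <- population_spec(n_subjects = 200, n_modes = 1, mode_amplitudes = 5,
                          pose_rotation_sd = 0, pose_translation_sd = 0,
                          vertex_noise_sd = 0, seed = 9)
  pop <- make_population(base, spec)
  cc <- vapply(pop$samples, function(s) s$latent_coeffs[1], numeric(1))
  expect_lt(abs(sd(cc) - 5) / 5, 0.15)
  pop2 <- make_population(base, spec)
  cc2 <- vapply(pop2$samples, function(s) s$latent_coeffs[1], numeric(1))
  expect_identical(cc, cc2)
})

test_that("empirical covariance of latent coefficients converges to diag(amplitudes^2)", {
  base <- base_shape_fixture(2)
  amps <- c(5, 4, 3)
  spec <- population_spec(n_subjects = 600, n_modes = 3,
                          mode_amplitudes = amps, pose_rotation_sd = 0,
                          pose_translation_sd = 0, vertex_noise_sd = 0,
                          seed = 31)
  pop <- make_population(base, spec)
  C <- cov(t(vapply(pop$samples, `[[`, numeric(3), "latent_coeffs")))
  for (j in 1:3) {
    expect_lt(abs(C[j, j] - amps[j]^2) / amps[j]^2, 0.10)
  }
  offdiag <- abs(C[upper.tri(C)])
  expect_lt(max(offdiag), 0.1 * max(amps)^2)
})

test_that("landmarks follow the analytic deformation map exactly (no noise)", {
  base <- base_shape_fixture(2)
  spec <- population_spec(n_subjects = 4, n_modes = 2,
                          mode_amplitudes = c(5, 3), pose_rotation_sd = 3,
                          pose_translation_sd = 3, vertex_noise_sd = 0.5,
                          seed = 17)
  pop <- make_population(base, spec)
  B <- pop$basis
  lmv <- base$landmark_vertex
  for (s in pop$samples) {
    disp <- matrix(B[, 1:2] %*% s$latent_coeffs, ncol = 3)
    expected <- base$mesh$vertices[lmv, ] + disp[lmv, ]
    expected <- expected %*% t(s$pose$rotation)
    expected <- sweep(expected, 2, s$pose$translation, "+")
    expect_equal(s$landmarks$points, expected, ignore_attr = TRUE,
                 tolerance = 1e-9)
    # landmarks sit within noise + interpolation tolerance of the surface
    d <- closest_point_on_mesh(s$landmarks$points, s$mesh)$dist
    expect_lt(max(d), 3 * spec$vertex_noise_sd + 0.5)
  }
})

test_that("requesting more modes than basis fields errors", {
  base <- base_shape_fixture(2)
  spec <- population_spec(n_subjects = 2, n_modes = 8,
                          mode_amplitudes = rep(1, 8), seed = 1)
  expect_error(make_population(base, spec), "basis")
})

test_that("population export writes STL, landmark CSVs and a manifest", {
  base <- base_shape_fixture(2)
  pop <- make_population(base, population_spec(n_subjects = 2, seed = 3))
  dir <- withr::local_tempdir()
  manifest <- write_population(pop, dir)
  expect_true(file.exists(manifest))
  expect_true(file.exists(file.path(dir, "subject_001.stl")))
  expect_true(file.exists(file.path(dir, "subject_002_landmarks.csv")))
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(m$spec$n_subjects, 2)
  expect_length(m$subjects$latent_coeffs, 2)
  back <- read_stl(file.path(dir, "subject_001.stl"))
  expect_equal(nrow(back$vertices), nrow(base$mesh$vertices))
})
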