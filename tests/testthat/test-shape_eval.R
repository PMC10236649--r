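# PCA explained variance of landmark clouds, landmark transfer, template
# comparison.

make_clouds <- function(X) {
  # X: n x 33 matrix -> list of landmark sets
  nm <- sprintf("l%02d", 1:11)
  lapply(seq_len(nrow(X)), function(i) {
    landmark_set(nm, matrix(X[i, ], ncol = 3))
  })
}

test_that("explained fractions follow the eigenvalue-ratio definition", {
  # plant an exact eigenvalue spectrum (3, 1, 0, ...) via orthogonal scores
  n <- 9
  set.seed(4)
  base_pt <- rnorm(33, sd = 10)
  d1 <- rnorm(33); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- rnorm(33); d2 <- d2 - sum(d2 * d1) * d1; d2 <- d2 / sqrt(sum(d2^2))
  # scores with exact sample variances 3 and 1 and zero correlation
  s1 <- scale(seq_len(n))[, 1]
  s2 <- scale(s1^2)[, 1]
  s2 <- s2 - sum(s2 * s1) / sum(s1^2) * s1
  s1 <- s1 / sd(s1) * sqrt(3)
  s2 <- s2 / sd(s2) * 1
  X <- matrix(base_pt, n, 33, byrow = TRUE) + outer(s1, d1) + outer(s2, d2)
  pca <- pca_explained_variance(make_clouds(X))
  expect_equal(pca$explained_fraction[1:2], c(0.75, 0.25), tolerance = 1e-9)
  expect_equal(sum(pca$explained_fraction), 1, tolerance = 1e-9)
  expect_equal(pca$cumulative_fraction[length(pca$eigenvalues)], 1,
               tolerance = 1e-9)
})

test_that("single-direction variation concentrates in mode 1 and rank is n-1", {
  set.seed(11)
  d <- rnorm(33)
  X <- outer(rnorm(6), d)
  pca <- pca_explained_variance(make_clouds(X))
  expect_equal(pca$explained_fraction[1], 1, tolerance = 1e-9)
  # 10 random clouds: at most 9 non-trivial modes
  X2 <- matrix(rnorm(10 * 33), 10, 33)
  pca2 <- pca_explained_variance(make_clouds(X2))
  nz <- sum(pca2$eigenvalues > 1e-10 * pca2$eigenvalues[1])
  expect_lte(nz, 9L)
})

test_that("PCA eigenvalues are invariant under a common rigid transform", {
  set.seed(21)
  X <- matrix(rnorm(8 * 33, sd = 3), 8, 33)
  clouds <- make_clouds(X)
  R <- rotation_z(40)
  t <- c(12, -5, 7)
  moved <- lapply(clouds, function(cl) {
    landmark_set(cl$names, sweep(cl$points %*% t(R), 2, t, "+"))
  })
  p1 <- pca_explained_variance(clouds)
  p2 <- pca_explained_variance(moved)
  expect_equal(p2$eigenvalues, p1$eigenvalues, tolerance = 1e-9)
})

test_that("mismatched landmark names are rejected", {
  set.seed(2)
  X <- matrix(rnorm(4 * 33), 4, 33)
  clouds <- make_clouds(X)
  clouds[[2]] <- landmark_set(rev(clouds[[2]]$names), clouds[[2]]$points)
  expect_error(pca_explained_variance(clouds), "mismatch")
})

test_that("planted generator modes dominate the truth-cloud spectrum", {
  base <- base_shape_fixture(2)
  amps <- c(5, 4, 3)
  spec <- population_spec(n_subjects = 120, n_modes = 3,
                          mode_amplitudes = amps, pose_rotation_sd = 0,
                          pose_translation_sd = 0, vertex_noise_sd = 0.05,
                          seed = 77)
  pop <- make_population(base, spec)
  clouds <- lapply(pop$samples, `[[`, "landmarks")
  pca <- pca_explained_variance(clouds)
  # cumulative fraction at the planted rank
  expect_gte(pca$cumulative_fraction[3], 0.99)
  # eigenvalue ratios track amplitude^2 ratios
  lam <- pca$eigenvalues[1:3]
  expect_equal(lam / lam[1], amps^2 / amps[1]^2, tolerance = 0.25)
})

test_that("landmark transfer reproduces closed-form transforms", {
  base <- base_shape_fixture(2)
  lm <- base$landmarks
  g <- list(origin = c(-30, -30, -5), spacing = c(4, 4, 4),
            dims = c(16L, 16L, 80L))
  idt <- subject_transform(affine_transform(), bonatlas:::zero_field(g))
  tt <- subject_transform(affine_transform(diag(3), c(3, -2, 5)),
                          bonatlas:::zero_field(g))
  clouds <- transfer_landmarks_to_training(lm, list(idt, tt))
  expect_equal(clouds[[1]]$points, lm$points, ignore_attr = TRUE)
  expect_equal(clouds[[2]]$points, sweep(lm$points, 2, c(3, -2, 5), "+"),
               ignore_attr = TRUE)
})

test_that("compare_templates zeroes out rigid offsets between equal shapes", {
  base <- base_shape_fixture(1)
  m <- base$mesh
  moved <- m
  moved$vertices <- sweep(m$vertices %*% t(bonatlas:::small_rotation(c(8, 0, 0))),
                          2, c(4, -2, 3), "+")
  dm <- compare_templates(moved, m)
  expect_lt(mean(abs(dm$distances)), 0.3)
  expect_equal(sum(dm$counts), nrow(moved$vertices))
})

test_that("correspondence mean shape recovers the base from symmetric pairs", {
  base <- base_shape_fixture(2)
  B <- bonatlas:::deformation_basis(base)
  d <- matrix(B[, 1] * 4, ncol = 3)
  plus <- base$mesh; plus$vertices <- base$mesh$vertices + d
  minus <- base$mesh; minus$vertices <- base$mesh$vertices - d
  # shared topology: exact vertex arithmetic
  mean_t <- correspondence_mean_shape(list(plus, minus),
                                      use_known_topology = TRUE)
  expect_lt(max(abs(mean_t$vertices - base$mesh$vertices)), 0.3)
  # closest-point mode approximates the topology-mode oracle
  mean_c <- correspondence_mean_shape(list(plus, minus),
                                      use_known_topology = FALSE)
  expect_lt(mean_surface_distance(mean_c, mean_t), 0.5)
  # identical meshes reproduce themselves exactly
  mean_i <- correspondence_mean_shape(list(base$mesh, base$mesh))
  expect_equal(mean_i$vertices, base$mesh$vertices, tolerance = 1e-9)
  # topology flag with differing topologies errors
  clipped <- base$mesh
  clipped$faces <- clipped$faces[-1, , drop = FALSE]
  expect_error(correspondence_mean_shape(list(base$mesh, clipped),
                                         use_known_topology = TRUE),
               "topolog")
})

test_that("landmark projection pins points to the surface", {
  base <- base_shape_fixture(2)
  lifted <- landmark_set(base$landmarks$names,
                         base$landmarks$points + 2)
  proj <- project_landmarks_to_surface(lifted, base$mesh)
  d <- closest_point_on_mesh(proj$points, base$mesh)$dist
  expect_lt(max(d), 1e-6)
})
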