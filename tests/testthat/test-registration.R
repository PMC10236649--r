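# Registration engines: rigid ICP, affine, demons-style deformable, field
# inversion, warping, transform averaging.

test_that("icp_align is exact on identical meshes and recovers a known rigid", {
  base <- base_shape_fixture(2)
  m <- base$mesh
  res0 <- icp_align(m, m)
  expect_lt(res0$rms, 1e-6)
  expect_lt(max(abs(res0$transform$rotation - diag(3))), 1e-6)

  # known rigid about an identifiable axis (the bone is nearly a surface of
  # revolution, so rotation about its long axis is not identifiable)
  R <- bonatlas:::small_rotation(c(15, 0, 0))
  t <- c(5, -3, 2)
  moved <- m
  moved$vertices <- sweep(m$vertices %*% t(R), 2, t, "+")
  # high-precision setting: point-to-point ICP creeps tangentially on the
  # surface reliefs, so the recovery check runs it to tight convergence
  res <- icp_align(moved, m, max_iter = 400, tol = 1e-6)
  Rr <- res$transform$rotation
  ang_err <- acos(min(1, (sum(diag(Rr %*% R)) - 1) / 2))
  expect_lt(ang_err, 1e-3)
  expect_lt(sqrt(sum((Rr %*% t + res$transform$translation)^2)), 1e-2)
  # RMS residual trace is non-increasing
  expect_true(all(diff(res$rms_trace) <= 1e-8))
})

test_that("icp_align is equivariant under a common rotation of both meshes", {
  base <- base_shape_fixture(2)
  m <- base$mesh
  R0 <- bonatlas:::small_rotation(c(10, 0, 0))
  moved <- m
  moved$vertices <- sweep(m$vertices %*% t(R0), 2, c(2, 1, -3), "+")
  res1 <- icp_align(moved, m)
  Rc <- bonatlas:::small_rotation(c(0, 25, 5))
  rot <- function(mm) {
    mm$vertices <- mm$vertices %*% t(Rc)
    mm
  }
  res2 <- icp_align(rot(moved), rot(m))
  # conjugation: R2 = Rc R1 Rc^T
  expect_equal(res2$transform$rotation,
               Rc %*% res1$transform$rotation %*% t(Rc), tolerance = 1e-3)
})

test_that("icp rms trace is non-increasing over random perturbations", {
  base <- base_shape_fixture(1)
  m <- base$mesh
  set.seed(7)
  for (trial in 1:10) {
    R <- bonatlas:::small_rotation(rnorm(3, 0, 5))
    t <- rnorm(3, 0, 4)
    moved <- m
    moved$vertices <- sweep(m$vertices %*% t(R), 2, t, "+")
    res <- icp_align(moved, m, subsample = 400)
    expect_true(all(diff(res$rms_trace) <= 1e-6))
    expect_lt(res$rms, 0.5)
  }
})

test_that("affine_register is near-identity on identical volumes and recovers a known affine", {
  base <- base_shape_fixture(2)
  v <- voxelize(base$mesh, spacing = 2, smooth_sigma = 2)
  a0 <- affine_register(v, v)
  expect_lt(norm(a0$linear - diag(3), "F"), 1e-2)
  expect_lt(sqrt(sum(a0$translation^2)), 1)  # < 0.5 voxel at 2 mm
  expect_lte(attr(a0, "ssd_final"), attr(a0, "ssd_initial") + 1e-9)

  A <- diag(c(1.1, 0.95, 1.05)) %*% rotation_z(10)
  ctr <- colMeans(base$mesh$vertices)
  tt <- as.numeric(ctr - A %*% ctr) + c(3, -2, 1)
  mov <- warp_volume(v, affine_transform(A, tt), grid = bonatlas:::grid_of(v))
  aff <- affine_register(mov, v)
  expect_lte(attr(aff, "ssd_final"), attr(aff, "ssd_initial") + 1e-9)
  # composition with the true map should be identity: mean displacement of
  # foreground points below half a voxel
  Ainv <- solve(A)
  pts <- base$mesh$vertices[seq(1, nrow(base$mesh$vertices), by = 7), ]
  pred <- warp_points(pts, aff)
  tru <- sweep(pts %*% t(Ainv), 2, -as.numeric(Ainv %*% tt), "+")
  expect_lt(mean(sqrt(rowSums((pred - tru)^2))), 1)
})

test_that("affine_register rejects empty volumes", {
  arr <- array(0, c(8, 8, 8))
  empty <- scalar_volume(arr, c(0, 0, 0), c(1, 1, 1))
  base <- base_shape_fixture(2)
  v <- voxelize(base$mesh, spacing = 2)
  expect_error(affine_register(empty, v), "empty")
  expect_error(affine_register(v, empty), "empty")
})

test_that("deformable_register returns a sub-voxel field on identical volumes", {
  base <- base_shape_fixture(2)
  v <- voxelize(base$mesh, spacing = 2, smooth_sigma = 2)
  fld <- deformable_register(v, v, levels = c(4, 2))
  expect_lt(fld$max_mm, 0.5)  # < 0.25 voxel spacing at 2 mm
  expect_gte(attr(fld, "jacobian_positive_frac"), 0.99)
})

test_that("deformable_register recovers the inverse of a known smooth warp", {
  base <- base_shape_fixture(2)
  v <- voxelize(base$mesh, spacing = 2, smooth_sigma = 2)
  g <- bonatlas:::grid_of(v)
  X <- bonatlas:::grid_world_coords(g, 1)
  Z <- bonatlas:::grid_world_coords(g, 3)
  u <- array(0, c(g$dims, 3))
  u[, , , 1] <- 3 * sin(Z / 40)
  u[, , , 2] <- 3 * cos(Z / 50)
  u[, , , 3] <- 3 * sin(X / 30)
  w <- displacement_field(u, g$origin, g$spacing)
  mov <- warp_volume(v, w, grid = g)
  fld <- deformable_register(mov, v, levels = c(4, 2),
                             iters_per_level = c(50, 30))
  winv <- invert_field(w)
  fg <- which(v$values > 0.2)
  err <- sqrt((fld$u[, , , 1][fg] - winv$u[, , , 1][fg])^2 +
              (fld$u[, , , 2][fg] - winv$u[, , , 2][fg])^2 +
              (fld$u[, , , 3][fg] - winv$u[, , , 3][fg])^2)
  expect_lt(mean(err), 2)  # one voxel at 2 mm
  expect_lt(attr(fld, "ssd_final"), attr(fld, "ssd_initial"))
})

test_that("invert_field handles closed forms and smooth round trips", {
  g <- list(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(12L, 12L, 12L))
  zero <- bonatlas:::zero_field(g)
  iz <- invert_field(zero)
  expect_equal(max(abs(iz$u)), 0)
  # constant field inverts to its negation
  cfield <- displacement_field(array(rep(c(2, -1, 0.5), each = prod(g$dims)),
                                     c(g$dims, 3)), g$origin, g$spacing)
  ic <- invert_field(cfield)
  expect_equal(mean(ic$u[, , , 1]), -2, tolerance = 1e-6)
  expect_equal(mean(ic$u[, , , 2]), 1, tolerance = 1e-6)
  # smooth small random field: round-trip composition error < 0.1 mm
  set.seed(12)
  X <- bonatlas:::grid_world_coords(g, 1)
  Y <- bonatlas:::grid_world_coords(g, 2)
  u <- array(0, c(g$dims, 3))
  u[, , , 1] <- 1.5 * sin(X / 6 + 1)
  u[, , , 2] <- 1.2 * cos(Y / 5)
  u[, , , 3] <- 0.8 * sin((X + Y) / 8)
  f <- displacement_field(u, g$origin, g$spacing)
  fi <- invert_field(f)
  expect_lt(attr(fi, "roundtrip_mean_mm"), 0.1)
})

test_that("warp_points composes rigid, affine, field and subject transforms", {
  pts <- matrix(rnorm(30, sd = 5), ncol = 3)
  t <- c(3, -1, 2)
  # pure translation moves every point by t
  expect_equal(warp_points(pts, affine_transform(diag(3), t)),
               sweep(pts, 2, t, "+"))
  # identity subject transform leaves points unchanged
  g <- list(origin = c(-20, -20, -20), spacing = c(2, 2, 2),
            dims = c(21L, 21L, 21L))
  st <- subject_transform(affine_transform(), bonatlas:::zero_field(g))
  expect_equal(warp_points(pts, st), pts)
  # field-then-affine composition order
  u <- array(1.5, c(g$dims, 3))
  fld <- displacement_field(u, g$origin, g$spacing)
  A <- diag(c(2, 1, 1))
  st2 <- subject_transform(affine_transform(A, c(0, 0, 0)), fld)
  got <- warp_points(matrix(c(1, 1, 1), 1), st2)
  expect_equal(as.numeric(got), as.numeric(A %*% (c(1, 1, 1) + 1.5)))
  # points outside the field domain fall back to affine with a warning
  expect_warning(warp_points(matrix(c(100, 0, 0), 1), st2), "outside")
})

test_that("warping points forward then through the inverse returns the start", {
  g <- list(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(15L, 15L, 15L))
  X <- bonatlas:::grid_world_coords(g, 1)
  u <- array(0, c(g$dims, 3))
  u[, , , 1] <- sin(X / 5)
  u[, , , 2] <- 0.5 * cos(X / 4)
  f <- displacement_field(u, g$origin, g$spacing)
  fi <- invert_field(f)
  pts <- matrix(runif(30, 3, 11), ncol = 3)
  back <- warp_points(warp_points(pts, f), fi)
  expect_lt(max(sqrt(rowSums((back - pts)^2))), 0.15)
})

test_that("warp_volume respects identity and pure translation", {
  base <- base_shape_fixture(2)
  v <- voxelize(base$mesh, spacing = 2)
  w <- warp_volume(v, affine_transform())
  expect_equal(w$values, v$values)
  # pull-back by translation t shifts content by -t: sample at +t instead
  t <- c(4, 0, 0)
  wt <- warp_volume(v, affine_transform(diag(3), t))
  shift_vox <- t[1] / v$spacing[1]
  nx <- v$dims[1]
  expect_equal(wt$values[1:(nx - shift_vox), , ],
               v$values[(1 + shift_vox):nx, , ])
})

test_that("average_transforms obeys closed-form cases", {
  g <- list(origin = c(0, 0, 0), spacing = c(1, 1, 1), dims = c(8L, 8L, 8L))
  mk <- function(t, uval = 0) {
    subject_transform(affine_transform(diag(3), t),
                      displacement_field(array(uval, c(g$dims, 3)),
                                         g$origin, g$spacing))
  }
  # average of identical transforms is that transform
  a <- average_transforms(list(mk(c(1, 2, 3), 0.5), mk(c(1, 2, 3), 0.5)))
  expect_equal(a$affine$translation, c(1, 2, 3), tolerance = 1e-9)
  expect_equal(mean(a$field$u), 0.5, tolerance = 1e-12)
  # translations +d and -d average to identity
  b <- average_transforms(list(mk(c(5, 0, 0)), mk(c(-5, 0, 0))))
  expect_lt(max(abs(b$affine$translation)), 1e-9)
  expect_lt(norm(b$affine$linear - diag(3), "F"), 1e-9)
  # antisymmetric field pair averages to (near) zero displacement
  X <- bonatlas:::grid_world_coords(g, 1)
  u <- array(0, c(g$dims, 3))
  u[, , , 1] <- sin(X)
  fwd <- subject_transform(affine_transform(),
                           displacement_field(u, g$origin, g$spacing))
  bwd <- subject_transform(affine_transform(),
                           displacement_field(-u, g$origin, g$spacing))
  c3 <- average_transforms(list(fwd, bwd))
  expect_lt(max(abs(c3$field$u)), 1e-12)
  expect_error(average_transforms(list()), "empty")
})

test_that("log-Euclidean affine averaging of rotations splits the angle", {
  r1 <- subject_transform(affine_transform(rotation_z(30), c(0, 0, 0)))
  r0 <- subject_transform(affine_transform(diag(3), c(0, 0, 0)))
  avg <- average_transforms(list(r1, r0))
  expect_equal(avg$affine$linear, rotation_z(15), tolerance = 1e-6)
})
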