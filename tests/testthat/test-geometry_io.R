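# Mesh / landmark / volume I-O and mesh<->volume conversion.

test_that("binary STL round-trips vertices and merges duplicate corners", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, path)
  back <- read_stl(path)
  expect_equal(nrow(back$vertices), 4L)
  expect_equal(nrow(back$faces), 4L)
  # same vertex set up to float32 precision (order may differ)
  ord <- function(V) V[order(V[, 1], V[, 2], V[, 3]), ]
  expect_equal(ord(back$vertices), ord(tet$vertices), tolerance = 1e-6)
  expect_true(is_watertight(back))
})

test_that("ASCII STL parses to the same mesh as its binary twin", {
  tet <- tetra_mesh(scale = 2.5)
  bin_path <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, bin_path)
  asc_path <- withr::local_tempfile(fileext = ".stl")
  V <- tet$vertices
  lines <- c("solid ascii")
  for (t in seq_len(nrow(tet$faces))) {
    tri <- V[tet$faces[t, ], , drop = FALSE]
    lines <- c(lines, " facet normal 0 0 0", "  outer loop",
               sprintf("   vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
               "  endloop", " endfacet")
  }
  writeLines(c(lines, "endsolid"), asc_path)
  a <- read_stl(asc_path)
  b <- read_stl(bin_path)
  ord <- function(V) V[order(V[, 1], V[, 2], V[, 3]), ]
  expect_equal(ord(a$vertices), ord(b$vertices), tolerance = 1e-6)
  expect_equal(nrow(a$faces), nrow(b$faces))
})

test_that("truncated STL raises a parse error naming the byte offset", {
  tet <- tetra_mesh()
  path <- withr::local_tempfile(fileext = ".stl")
  write_stl(tet, path)
  full <- readBin(path, "raw", n = file.info(path)$size)
  writeBin(full[1:(84 + 70)], path)  # cut inside the second facet
  expect_error(read_stl(path), "byte")
})

test_that("landmark CSV round-trips and rejects bad input", {
  base <- base_shape_fixture()
  lm <- base$landmarks
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(lm, path)
  back <- read_landmarks(path)
  expect_identical(back$names, lm$names)
  expect_equal(back$points, lm$points, ignore_attr = TRUE, tolerance = 1e-12)

  # extra columns: warn and ignore
  df <- utils::read.csv(path)
  df$extra <- 1
  utils::write.csv(df, path, row.names = FALSE)
  expect_warning(read_landmarks(path), "extra")

  # duplicate names rejected at construction
  expect_error(landmark_set(c("a", "a"), rbind(c(0, 0, 0), c(1, 1, 1))),
               "duplicate")
  # non-numeric coordinates rejected
  writeLines(c("name,x,y,z", "p1,1,2,three"), path)
  expect_error(read_landmarks(path), "non-numeric|NA")
})

test_that("mesh_volume matches analytic volumes and fixes orientation", {
  expect_equal(mesh_volume(cube_mesh(1)), 1.0, tolerance = 1e-12)
  sph <- sphere_fixture(r = 10, subdiv = 4)
  expect_equal(mesh_volume(sph), 4 / 3 * pi * 1000, tolerance = 0.005)
  # inward-oriented cube: warning + positive volume
  cube_in <- cube_mesh(1)
  cube_in$faces <- cube_in$faces[, c(1, 3, 2)]
  expect_warning(v <- mesh_volume(cube_in), "orientation")
  expect_equal(v, 1.0, tolerance = 1e-12)
  # rigid invariance
  m <- tetra_mesh(3)
  R <- rotation_z(33)
  m2 <- m
  m2$vertices <- sweep(m$vertices %*% t(R), 2, c(4, -7, 2), "+")
  expect_equal(mesh_volume(m2), mesh_volume(m), tolerance = 1e-9)
  # open mesh rejected
  open_mesh <- tetra_mesh()
  open_mesh$faces <- open_mesh$faces[-1, , drop = FALSE]
  expect_error(mesh_volume(open_mesh), "watertight")
})

test_that("voxelize recovers analytic volumes and rejects open meshes", {
  cube <- cube_mesh(10)
  v <- voxelize(cube, spacing = 1, padding = 2)
  expect_s3_class(v, "scalar_volume")
  occ <- sum(v$values) * prod(v$spacing)
  expect_lt(abs(occ - 1000) / 1000, 0.05)

  sph <- sphere_fixture(r = 20, subdiv = 3)
  vs <- voxelize(sph, spacing = 1)
  occ_s <- sum(vs$values) * prod(vs$spacing)
  expect_lt(abs(occ_s - 4 / 3 * pi * 8000) / (4 / 3 * pi * 8000), 0.02)

  open_mesh <- tetra_mesh()
  open_mesh$faces <- open_mesh$faces[-1, , drop = FALSE]
  expect_error(voxelize(open_mesh), "watertight")
})

test_that("extract_surface inverts voxelize up to the voxel scale", {
  sph <- sphere_fixture(r = 20, subdiv = 3)
  v <- voxelize(sph, spacing = 1, smooth_sigma = 1)
  s <- extract_surface(v, 0.5)
  expect_true(is_watertight(s))
  # mean radial distance of extracted vertices to the r = 20 sphere
  rad <- sqrt(rowSums(s$vertices^2))
  expect_lt(mean(abs(rad - 20)), 0.6)
  # bidirectional round-trip distance below one voxel
  expect_lt(mean_surface_distance(sph, s), 1)
  # iso outside the value range
  expect_error(extract_surface(v, 2), "iso")
  expect_error(scalar_volume(array(0, c(4, 4, 4)), c(0, 0, 0), c(1, 1, 1)) |>
                 extract_surface(0.5), "iso")
})

test_that("distance_model signs distances by containment and conserves counts", {
  inner <- sphere_fixture(r = 9, subdiv = 3)
  outer <- icosphere_mesh(r = 10, subdiv = 3)
  # carrier outside reference: +1 mm
  dm <- distance_model(outer, inner)
  expect_equal(mean(dm$distances), 1, tolerance = 0.02)
  expect_true(all(dm$distances > 0))
  # carrier inside reference: -1 mm
  dm2 <- distance_model(inner, outer)
  expect_equal(mean(dm2$distances), -1, tolerance = 0.02)
  expect_true(all(dm2$distances < 0))
  # conservation + self distance
  expect_equal(sum(dm$counts), nrow(outer$vertices))
  dm0 <- distance_model(inner, inner)
  expect_equal(max(abs(dm0$distances)), 0, tolerance = 1e-9)
  expect_equal(dm0$hausdorff_mm, 0, tolerance = 1e-9)
})

test_that("point-in-mesh parity agrees with analytic containment on spheres", {
  sph <- sphere_fixture(r = 10, subdiv = 3)
  set.seed(42)
  P <- matrix(runif(300, -12, 12), ncol = 3)
  r <- sqrt(rowSums(P^2))
  keep <- abs(r - 10) > 0.5  # skip the faceting shell
  got <- points_in_mesh(P[keep, ], sph)
  expect_equal(got, r[keep] < 10)
})

test_that("NRRD round-trips volumes and displacement fields", {
  arr <- array(runif(4 * 5 * 6), c(4, 5, 6))
  v <- scalar_volume(arr, origin = c(-1, 2, 0.5), spacing = c(1, 0.5, 2))
  path <- withr::local_tempfile(fileext = ".nrrd")
  write_nrrd(v, path)
  back <- read_nrrd(path)
  expect_equal(back$values, v$values)
  expect_equal(back$origin, v$origin)
  expect_equal(back$spacing, v$spacing)

  u <- array(rnorm(4 * 5 * 6 * 3), c(4, 5, 6, 3))
  f <- displacement_field(u, origin = c(0, 0, 0), spacing = c(1, 1, 1))
  write_nrrd(f, path)
  fb <- read_nrrd(path)
  expect_s3_class(fb, "displacement_field")
  expect_equal(fb$u, f$u)
})
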