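# Train/test split, RMSE, paired t-test, percent improvement.

test_that("split_data sizes follow round-half-up of the train fraction", {
  s50 <- split_data(1:50, 0.82, seed = 3)
  expect_length(s50$train, 41L)
  expect_length(s50$test, 9L)
  s43 <- split_data(1:43, 0.82, seed = 3)
  expect_length(s43$train, 35L)
  expect_length(s43$test, 8L)
  # disjoint cover
  expect_setequal(c(s50$train, s50$test), 1:50)
  expect_length(intersect(s50$train, s50$test), 0L)
  # determinism
  expect_identical(split_data(1:50, 0.82, seed = 3)$train, s50$train)
  # different seed permutes
  expect_false(identical(split_data(1:50, 0.82, seed = 4)$train, s50$train))
  expect_error(split_data(1:10, 1.2), "fraction")
  expect_error(split_data(1:10, 0), "fraction")
})

test_that("rmse matches hand-computed values and is rigid invariant", {
  nm <- sprintf("l%02d", 1:11)
  P <- matrix(rnorm(33, sd = 10), ncol = 3, dimnames = list(nm, NULL))
  truth <- landmark_set(nm, P)
  expect_equal(rmse(truth, truth), 0)
  # one landmark off by 3 mm
  Q <- P
  Q[5, 1] <- Q[5, 1] + 3
  expect_equal(rmse(landmark_set(nm, Q), truth), sqrt(9 / 11),
               tolerance = 1e-9)
  # all off by exactly 2 mm
  Q2 <- P
  Q2[, 3] <- Q2[, 3] + 2
  expect_equal(rmse(landmark_set(nm, Q2), truth), 2, tolerance = 1e-12)
  # rigid invariance
  R <- rotation_z(77)
  t <- c(10, -4, 6)
  rig <- function(M) sweep(M %*% t(R), 2, t, "+")
  expect_equal(rmse(landmark_set(nm, rig(Q2)), landmark_set(nm, rig(P))),
               rmse(landmark_set(nm, Q2), truth), tolerance = 1e-9)
  # name mismatch
  expect_error(rmse(landmark_set(rev(nm), Q), truth), "mismatch")
})

test_that("paired_t_test matches the closed form and brute-force definition", {
  # identical arrays
  r <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # differences (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, df 2, p ~ 0.0742
  r2 <- paired_t_test(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r2$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(r2$df, 2L)
  expect_equal(r2$p, 2 * pt(-abs(r2$t), df = 2), tolerance = 1e-9)
  expect_equal(r2$p, 0.0742, tolerance = 1e-3)
  # sign flip negates t, keeps p
  r3 <- paired_t_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r3$t, -r2$t, tolerance = 1e-12)
  expect_equal(r3$p, r2$p, tolerance = 1e-12)
  # brute force from the definition on random arrays
  set.seed(99)
  for (trial in 1:100) {
    n <- sample(3:12, 1)
    a <- rnorm(n)
    b <- rnorm(n)
    d <- a - b
    tt <- mean(d) / (sd(d) / sqrt(n))
    pp <- 2 * pt(-abs(tt), df = n - 1)
    got <- paired_t_test(a, b)
    expect_equal(got$t, tt, tolerance = 1e-10)
    expect_equal(got$p, pp, tolerance = 1e-10)
  }
  # degenerate: constant nonzero difference
  r4 <- paired_t_test(c(2, 2, 2), c(1, 1, 1))
  expect_equal(r4$p, 0)
  expect_error(paired_t_test(1, 1), "equal-length")
})

test_that("improvement_pct reproduces the printed study arithmetic", {
  expect_equal(improvement_pct(2.83, 3.66), 22.6776, tolerance = 1e-4)
  expect_equal(round(improvement_pct(2.83, 3.66)), 23)
  expect_equal(improvement_pct(1, 1), 0)
  expect_equal(improvement_pct(0, 5), 100)
  expect_error(improvement_pct(1, 0), "> 0")
})

test_that("predict_landmarks is exact under identity and pure translation", {
  base <- base_shape_fixture(2)
  v <- voxelize(base$mesh, spacing = 2, smooth_sigma = 2)
  lm <- base$landmarks
  p <- predict_landmarks(v, lm, v)
  expect_lt(max(sqrt(rowSums((p$points - lm$points)^2))), 1)  # < 0.5 voxel
  t <- c(4, -6, 8)
  m2 <- base$mesh
  m2$vertices <- sweep(m2$vertices, 2, t, "+")
  v2 <- voxelize(m2, spacing = 2, smooth_sigma = 2)
  p2 <- predict_landmarks(v, lm, v2)
  expect_lt(max(sqrt(rowSums((p2$points - sweep(lm$points, 2, t, "+"))^2))), 1)
})

test_that("validate_planning produces a coherent report for two arms", {
  # synthetic RMSE-level check through the full report plumbing using a
  # trivially predictable geometry: template == subject
  base <- base_shape_fixture(2)
  v <- voxelize(base$mesh, spacing = 2, smooth_sigma = 2)
  lm <- base$landmarks
  arms <- list(template = list(template_volume = v, template_landmarks = lm),
               mean_shape = list(template_volume = v, template_landmarks = lm))
  rep <- validate_planning(arms, list(v, v), list(lm, lm))
  expect_s3_class(rep, "validation_report")
  expect_equal(dim(rep$rmse_matrix), c(2L, 2L))
  expect_true(all(rep$rmse_matrix < 1))
  expect_equal(nrow(rep$per_landmark), 2 * 2 * 11)
  expect_equal(rep$t_test$t, 0, tolerance = 1e-9)
})
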