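# Surgical-planning validation: train/test split, landmark prediction on
# held-out subjects, RMSE scoring, paired t-tests and percent improvement.

#' Random train/test split of subject ids
#'
#' Uniform random permutation under the seed; the first
#' `round(train_fraction * n)` ids (round-half-up) form the training set.
#' The default 0.82 fraction gives 41/9 at n = 50 and 35/8 at n = 43.
#'
#' @param ids vector of subject identifiers (n >= 2).
#' @param train_fraction fraction of subjects used for training, in (0,1).
#' @param seed integer seed.
#' @return Object of class `split_result` with `train`, `test`, `seed`,
#'   `train_fraction`.
#' @export
split_data <- function(ids, train_fraction = 0.82, seed = 1L) {
  if (length(ids) < 2L) stop("need at least 2 subjects")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  n <- length(ids)
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  n_train <- max(1L, min(n - 1L, n_train))
  perm <- local_seed(seed, sample.int(n))
  structure(list(train = ids[perm[seq_len(n_train)]],
                 test = ids[perm[(n_train + 1L):n]],
                 seed = as.integer(seed), train_fraction = train_fraction),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result: %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train), length(x$test), x$train_fraction, x$seed))
  invisible(x)
}

#' Predict landmarks on a held-out subject from a template
#'
#' Registers the test subject's volume (moving) to the template volume
#' (fixed) with the same affine + deformable engine used in template
#' building, then pushes the template landmarks through the resulting
#' template-to-subject map.
#'
#' @param template_volume [scalar_volume] of the average population model
#'   (either arm; the mean-shape arm is voxelized identically first).
#' @param template_landmarks [landmark_set] in the template frame.
#' @param subject_volume [scalar_volume] of the held-out subject.
#' @param reg_params registration parameters (see [build_template()]).
#' @return A [landmark_set] of predicted subject landmarks, with the
#'   [subject_transform] attached as attribute `transform`.
#' @export
predict_landmarks <- function(template_volume, template_landmarks,
                              subject_volume,
                              reg_params = default_reg_params()) {
  stopifnot(inherits(template_volume, "scalar_volume"),
            inherits(template_landmarks, "landmark_set"),
            inherits(subject_volume, "scalar_volume"))
  reg <- register_subject_to_template(subject_volume, template_volume,
                                      reg_params)
  pred <- warp_points(template_landmarks$points, reg$transform)
  out <- landmark_set(template_landmarks$names, pred, frame = "subject")
  attr(out, "transform") <- reg$transform
  out
}

#' Predict landmarks on held-out subjects (method interface)
#'
#' `predict()` on a fitted [build_template()] object: registers each
#' held-out volume to the template and transfers `landmarks` into the
#' subject's space.
#'
#' @param object a `bone_template`.
#' @param landmarks template-frame [landmark_set].
#' @param newdata a [scalar_volume] or list of them.
#' @param reg_params registration parameters.
#' @param ... unused.
#' @return A [landmark_set] or list of them.
#' @export
predict.bone_template <- function(object, landmarks, newdata,
                                  reg_params = default_reg_params(), ...) {
  one <- function(v) predict_landmarks(object$template, landmarks, v,
                                       reg_params)
  if (inherits(newdata, "scalar_volume")) return(one(newdata))
  lapply(newdata, one)
}

#' Root-mean-square landmark error
#'
#' `sqrt(mean ||p_j - q_j||^2)` over paired landmarks matched by name and
#' order.
#'
#' @param pred,truth [landmark_set] objects with identical names/order.
#' @return RMSE in mm.
#' @export
rmse <- function(pred, truth) {
  stopifnot(inherits(pred, "landmark_set"), inherits(truth, "landmark_set"))
  if (!identical(pred$names, truth$names)) {
    stop("landmark name/order mismatch")
  }
  sqrt(mean(rowSums((pred$points - truth$points)^2)))
}

#' Paired t-test on per-subject RMSE values
#'
#' Classical paired t on the differences, two-sided, df = n - 1. All-zero
#' differences give t = 0, p = 1; zero-variance nonzero differences give
#' p = 0 (reported as such with infinite t).
#'
#' @param rmse_arm_a,rmse_arm_b equal-length (>= 2) numeric vectors paired
#'   by subject.
#' @return List with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t_test <- function(rmse_arm_a, rmse_arm_b) {
  if (length(rmse_arm_a) != length(rmse_arm_b) || length(rmse_arm_a) < 2L) {
    stop("need two equal-length vectors with n >= 2")
  }
  d <- rmse_arm_a - rmse_arm_b
  n <- length(d)
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1L, mean_difference = 0))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_difference = mean(d)))
  }
  tt <- stats::t.test(rmse_arm_a, rmse_arm_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_difference = mean(d))
}

#' Percent improvement of arm A over arm B
#'
#' `(B - A) / B * 100` on mean RMSE values; positive when arm A is more
#' accurate.
#'
#' @param rmse_a_mean,rmse_b_mean mean RMSE of the two arms (B > 0).
#' @return Percent improvement.
#' @export
improvement_pct <- function(rmse_a_mean, rmse_b_mean) {
  if (rmse_b_mean <= 0) stop("reference mean RMSE must be > 0")
  (rmse_b_mean - rmse_a_mean) / rmse_b_mean * 100
}

#' Validate surgical-planning landmark prediction on held-out subjects
#'
#' For each test subject and each template arm, predicts the 11 landmarks
#' by atlas registration and scores them against ground truth by RMSE;
#' compares arms by a paired t-test and percent improvement of arm A over
#' arm B. Both arms use the same registration engine and parameters so arm
#' differences reflect the template, not optimizer settings.
#'
#' @param arms named list of arms, each a list with `template_volume` and
#'   `template_landmarks`.
#' @param test_volumes list of held-out subject [scalar_volume]s.
#' @param test_truth list of ground-truth [landmark_set]s (same order).
#' @param reg_params registration parameters.
#' @return Object of class `validation_report`: `per_subject` data.frame
#'   (subject, arm, rmse), `per_landmark` data.frame, `arm_summary`,
#'   `t_test` (first arm vs second, when two arms given), `improvement_pct`.
#' @export
validate_planning <- function(arms, test_volumes, test_truth,
                              reg_params = default_reg_params()) {
  stopifnot(length(test_volumes) == length(test_truth),
            length(test_volumes) >= 1L, length(arms) >= 1L)
  rows <- list()
  lm_rows <- list()
  rmse_mat <- matrix(NA_real_, nrow = length(test_volumes),
                     ncol = length(arms),
                     dimnames = list(NULL, names(arms)))
  for (a in seq_along(arms)) {
    arm <- arms[[a]]
    for (i in seq_along(test_volumes)) {
      pred <- predict_landmarks(arm$template_volume, arm$template_landmarks,
                                test_volumes[[i]], reg_params)
      truth <- test_truth[[i]]
      err <- sqrt(rowSums((pred$points - truth$points)^2))
      rmse_mat[i, a] <- rmse(pred, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = i, arm = names(arms)[a], rmse = rmse_mat[i, a])
      lm_rows[[length(lm_rows) + 1L]] <- data.frame(
        subject = i, arm = names(arms)[a], landmark = truth$names,
        error_mm = err)
    }
  }
  per_subject <- do.call(rbind, rows)
  arm_summary <- do.call(rbind, lapply(names(arms), function(nm) {
    v <- rmse_mat[, nm]
    data.frame(arm = nm, mean_rmse = mean(v), min_rmse = min(v),
               max_rmse = max(v))
  }))
  t_res <- NULL
  imp <- NULL
  if (length(arms) >= 2L && nrow(rmse_mat) >= 2L) {
    t_res <- paired_t_test(rmse_mat[, 1], rmse_mat[, 2])
    imp <- if (mean(rmse_mat[, 2]) > 0) {
      improvement_pct(mean(rmse_mat[, 1]), mean(rmse_mat[, 2]))
    } else {
      NA_real_
    }
  }
  structure(list(per_subject = per_subject,
                 per_landmark = do.call(rbind, lm_rows),
                 arm_summary = arm_summary, rmse_matrix = rmse_mat,
                 t_test = t_res, improvement_pct = imp),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report\n")
  print(x$arm_summary, row.names = FALSE)
  if (!is.null(x$t_test)) {
    cat(sprintf("paired t-test (%s vs %s): t = %.4f, df = %d, p = %.4g\n",
                colnames(x$rmse_matrix)[1], colnames(x$rmse_matrix)[2],
                x$t_test$t, x$t_test$df, x$t_test$p))
    cat(sprintf("improvement of %s over %s: %.2f%%\n",
                colnames(x$rmse_matrix)[1], colnames(x$rmse_matrix)[2],
                x$improvement_pct))
  }
  invisible(x)
}

#' @export
summary.validation_report <- function(object, ...) {
  print(object)
  agg <- stats::aggregate(error_mm ~ landmark + arm, object$per_landmark,
                          mean)
  cat("\nmean per-landmark error (mm):\n")
  print(agg, row.names = FALSE)
  invisible(agg)
}

#' @export
plot.validation_report <- function(x, ...) {
  m <- t(x$rmse_matrix)
  graphics::barplot(m, beside = TRUE, names.arg = seq_len(ncol(m)),
                    xlab = "test subject", ylab = "landmark RMSE (mm)",
                    legend.text = rownames(m), ...)
  invisible(x)
}
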