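# Evaluation of the average population model: landmark transfer to the
# training subjects, PCA explained variance of the transferred point
# clouds, and distance-model comparison between template arms.

#' Project landmarks onto a surface
#'
#' Replaces each landmark by its closest point on the given mesh; used to
#' pin reference landmarks onto a template surface (the synthetic stand-in
#' for expert annotation of the template).
#'
#' @param landmarks a [landmark_set].
#' @param mesh a [triangle_mesh].
#' @param frame frame identifier for the result.
#' @return A [landmark_set] on the surface.
#' @export
project_landmarks_to_surface <- function(landmarks, mesh,
                                         frame = "template") {
  cq <- closest_point_on_mesh(landmarks$points, mesh)
  landmark_set(landmarks$names, cq$point, frame = frame)
}

#' Transfer template landmarks to every training subject
#'
#' Applies each template-to-subject transform to the template landmarks,
#' producing the correspondence landmark point clouds the explained-variance
#' analysis runs on. Output order matches the subject order.
#'
#' @param template_landmarks [landmark_set] in the template frame.
#' @param transforms list of [subject_transform] (template to subject).
#' @return List of [landmark_set], one per subject.
#' @export
transfer_landmarks_to_training <- function(template_landmarks, transforms) {
  stopifnot(inherits(template_landmarks, "landmark_set"))
  lapply(seq_along(transforms), function(i) {
    p <- warp_points(template_landmarks$points, transforms[[i]])
    landmark_set(template_landmarks$names, p,
                 frame = sprintf("subject_%03d", i))
  })
}

#' PCA explained variance of landmark point clouds
#'
#' Flattens each cloud of n landmarks to a 3n-vector, subtracts the mean
#' vector and eigendecomposes the sample covariance of the raw mm
#' coordinates (no standardization, and no Procrustes re-alignment unless
#' requested). Each mode's explained fraction is its eigenvalue divided by
#' the eigenvalue sum; at most `n_subjects - 1` modes are non-trivial.
#'
#' @param clouds list (>= 2) of [landmark_set] with identical names/order.
#' @param procrustes optionally rigidly re-align the clouds to their mean
#'   before PCA (sensitivity checks only; default FALSE).
#' @return Object of class `shape_pca`: `eigenvalues`, `modes` (columns,
#'   orthonormal), `explained_fraction`, `cumulative_fraction`,
#'   `n_subjects`, `n_landmarks`.
#' @export
pca_explained_variance <- function(clouds, procrustes = FALSE) {
  if (length(clouds) < 2L) stop("need at least 2 landmark clouds")
  stopifnot(all(vapply(clouds, inherits, TRUE, "landmark_set")))
  nm <- clouds[[1]]$names
  ok <- all(vapply(clouds, function(cl) identical(cl$names, nm), TRUE))
  if (!ok) stop("mismatched landmark names/order across clouds")
  pts <- lapply(clouds, `[[`, "points")
  if (procrustes) {
    mean_p <- Reduce(`+`, pts) / length(pts)
    for (it in 1:3) {
      pts <- lapply(pts, function(P) apply_rigid(kabsch_fit(P, mean_p), P))
      mean_p <- Reduce(`+`, pts) / length(pts)
    }
  }
  X <- t(vapply(pts, as.numeric, numeric(3 * length(nm))))
  C <- cov(X)
  eig <- eigen(C, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  total <- sum(ev)
  frac <- if (total > 0) ev / total else rep(0, length(ev))
  structure(list(eigenvalues = ev, modes = eig$vectors,
                 explained_fraction = frac,
                 cumulative_fraction = cumsum(frac),
                 n_subjects = length(clouds), n_landmarks = length(nm)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat(sprintf("shape_pca: %d clouds of %d landmarks\n",
              x$n_subjects, x$n_landmarks))
  k <- min(7L, length(x$eigenvalues))
  df <- data.frame(mode = seq_len(k),
                   eigenvalue = round(x$eigenvalues[seq_len(k)], 4),
                   explained = sprintf("%.2f%%",
                                       100 * x$explained_fraction[seq_len(k)]),
                   cumulative = sprintf("%.2f%%",
                                        100 * x$cumulative_fraction[seq_len(k)]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.shape_pca <- function(object, ...) {
  nz <- sum(object$eigenvalues > 1e-10 * max(object$eigenvalues, 1e-300))
  cat(sprintf("%d non-trivial modes (at most n-1 = %d possible)\n",
              nz, object$n_subjects - 1L))
  print(object)
  invisible(object)
}

#' Scree plot of explained variance
#'
#' @param x a `shape_pca`.
#' @param n_modes number of leading modes to show.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.shape_pca <- function(x, n_modes = 10L, ...) {
  k <- min(n_modes, length(x$eigenvalues))
  f <- 100 * x$explained_fraction[seq_len(k)]
  bp <- graphics::barplot(f, names.arg = seq_len(k), xlab = "mode",
                          ylab = "explained variation (%)", ...)
  graphics::lines(bp, 100 * x$cumulative_fraction[seq_len(k)], type = "b",
                  pch = 19)
  invisible(x)
}

#' Write a shape_pca as CSV (mode, eigenvalue, fraction, cumulative)
#'
#' @param pca a `shape_pca`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pca_csv <- function(pca, path) {
  df <- data.frame(mode = seq_along(pca$eigenvalues),
                   eigenvalue = pca$eigenvalues,
                   explained_fraction = pca$explained_fraction,
                   cumulative_fraction = pca$cumulative_fraction)
  write.csv(format(df, digits = 12, scientific = FALSE, trim = TRUE), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare the two template arms by a signed distance model
#'
#' ICP-aligns the template surface onto the correspondence mean shape and
#' computes the signed distance model with the standard -6..6 mm display
#' histogram.
#'
#' @param template_surface [triangle_mesh] (iterative template arm).
#' @param mean_shape [triangle_mesh] (correspondence mean-shape arm).
#' @param ... passed to [icp_align()].
#' @return A `distance_model` (see [distance_model()]).
#' @export
compare_templates <- function(template_surface, mean_shape, ...) {
  aligned <- icp_align(template_surface, mean_shape, ...)$aligned
  distance_model(aligned, mean_shape)
}
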