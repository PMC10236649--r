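# Rigid iterative-closest-point registration on meshes.

kabsch_fit <- function(moving_pts, fixed_pts) {
  cm <- colMeans(moving_pts)
  cf <- colMeans(fixed_pts)
  H <- crossprod(sweep(moving_pts, 2, cm), sweep(fixed_pts, 2, cf))
  sv <- svd(H)
  if (min(sv$d) < 1e-12 * max(sv$d, 1e-300) && sum(sv$d > 1e-12) < 2) {
    stop("degenerate correspondence: rank-deficient cross-covariance")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cf - as.numeric(R %*% cm)
  rigid_transform(R, t)
}

apply_rigid <- function(transform, points) {
  sweep(points %*% t(transform$rotation), 2, transform$translation, "+")
}

compose_rigid <- function(b, a) {  # returns b o a
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Rigid ICP alignment of one mesh onto another
#'
#' Iterates closest-point pairing from (subsampled) moving vertices to the
#' fixed surface with a least-squares rigid fit (Kabsch/SVD) until the RMS
#' residual stops changing. Rigid only - no scaling.
#'
#' @param moving,fixed [triangle_mesh] objects.
#' @param max_iter maximum iterations (default 50).
#' @param tol stop when the RMS residual changes by less than this (mm).
#' @param subsample number of moving vertices used for pairing; vertices are
#'   taken evenly in index order unless `seed` is given, in which case a
#'   seeded uniform sample is drawn.
#' @param seed optional integer seed for the vertex subsample.
#' @return List with `transform` ([rigid_transform] mapping moving into the
#'   fixed frame), `aligned` (transformed moving mesh), `rms` (final RMS
#'   residual mm) and `rms_trace`.
#' @export
icp_align <- function(moving, fixed, max_iter = 50L, tol = 1e-4,
                      subsample = 1000L, seed = NULL) {
  stopifnot(inherits(moving, "triangle_mesh"), inherits(fixed, "triangle_mesh"))
  if (nrow(moving$vertices) == 0L || nrow(fixed$vertices) == 0L) {
    stop("empty mesh")
  }
  P0 <- moving$vertices
  if (nrow(P0) > subsample) {
    if (is.null(seed)) {
      idx <- round(seq(1L, nrow(P0), length.out = subsample))
    } else {
      idx <- local_seed(seed, sample.int(nrow(P0), subsample))
    }
    P0 <- P0[idx, , drop = FALSE]
  }
  current <- rigid_transform()
  P <- P0
  rms_prev <- Inf
  rms_trace <- numeric()
  for (it in seq_len(max_iter)) {
    cq <- closest_point_on_mesh(P, fixed)
    rms <- sqrt(mean(cq$dist^2))
    rms_trace <- c(rms_trace, rms)
    if (abs(rms_prev - rms) < tol) break
    rms_prev <- rms
    step <- kabsch_fit(P, cq$point)
    current <- compose_rigid(step, current)
    P <- apply_rigid(current, P0)
  }
  aligned <- moving
  aligned$vertices <- apply_rigid(current, moving$vertices)
  list(transform = current, aligned = aligned, rms = rms_trace[length(rms_trace)],
       rms_trace = rms_trace)
}

# evaluate expr with a temporary RNG state seeded by `seed`
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
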