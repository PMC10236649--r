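# Affine volume registration: multi-resolution gradient-based descent on
# the sum-of-squared-differences of smoothed intensities.

# resample a volume to an (approximately) target isotropic spacing,
# pre-smoothing to avoid aliasing when coarsening
resample_to_spacing <- function(vol, target_mm, presmooth = TRUE) {
  if (all(abs(vol$spacing - target_mm) < 1e-9)) return(vol)
  # a precomputed pyramid (attached by build_template for the shared fixed
  # image) short-circuits repeated smoothing + resampling
  pyr <- attr(vol, "pyramid")
  if (!is.null(pyr)) {
    hit <- pyr[[format(target_mm)]]
    if (!is.null(hit)) return(hit)
  }
  vals <- vol$values
  if (presmooth && any(target_mm > vol$spacing * 1.01)) {
    sig_vox <- pmax(0, 0.45 * target_mm / vol$spacing)
    vals <- cpp_smooth3(vals, as.integer(vol$dims), sig_vox)
  }
  extent <- (vol$dims - 1) * vol$spacing
  ndims <- pmax(2L, as.integer(ceiling(extent / target_mm)) + 1L)
  nsp <- rep(target_mm, 3)
  out <- cpp_resample(vals, as.integer(vol$dims), vol$origin,
                      vol$spacing, ndims, vol$origin, nsp)
  scalar_volume(array(pmin(1, pmax(0, out)), ndims), vol$origin, nsp)
}

resample_volume_to_grid <- function(vol, grid) {
  out <- cpp_resample(vol$values, as.integer(vol$dims),
                      vol$origin, vol$spacing, as.integer(grid$dims),
                      grid$origin, grid$spacing)
  scalar_volume(array(pmin(1, pmax(0, out)), grid$dims), grid$origin,
                grid$spacing)
}

volume_gradient_arrays <- function(vol) {
  v <- vol$values
  d <- vol$dims
  g <- vector("list", 3)
  for (ax in 1:3) {
    ip <- c(2:d[ax], d[ax])
    im <- c(1, 1:(d[ax] - 1))
    denom <- (ip - im) * vol$spacing[ax]
    if (ax == 1) {
      g[[ax]] <- (v[ip, , , drop = FALSE] - v[im, , , drop = FALSE]) /
        array(denom, d)
    } else if (ax == 2) {
      g[[ax]] <- (v[, ip, , drop = FALSE] - v[, im, , drop = FALSE]) /
        aperm(array(denom, d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      g[[ax]] <- (v[, , ip, drop = FALSE] - v[, , im, drop = FALSE]) /
        aperm(array(denom, d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  g
}

volume_com <- function(vol) {
  w <- as.numeric(vol$values)
  s <- sum(w)
  if (s <= 0) stop("empty (all-zero) volume")
  d <- vol$dims
  idx <- list(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  vapply(1:3, function(ax) {
    vol$origin[ax] + vol$spacing[ax] * sum(w * idx[[ax]]) / s
  }, numeric(1))
}

volume_second_moments <- function(vol, com) {
  w <- as.numeric(vol$values)
  s <- sum(w)
  d <- vol$dims
  out <- numeric(3)
  idx <- list(
    rep.int(seq_len(d[1]) - 1L, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  )
  for (ax in 1:3) {
    x <- vol$origin[ax] + vol$spacing[ax] * idx[[ax]]
    out[ax] <- sum(w * (x - com[ax])^2) / s
  }
  out
}

#' Affine registration of two scalar volumes
#'
#' Estimates the affine map from fixed-space coordinates to moving-space
#' coordinates (the pull-back/resampling convention). Initialised by
#' matching centres of mass and axis-wise second moments, then refined by
#' multi-resolution BFGS descent on the sum of squared intensity
#' differences with an analytic gradient.
#'
#' @param moving,fixed [scalar_volume] objects with overlapping fields of
#'   view.
#' @param levels coarse-to-fine target spacings in mm.
#' @param maxit BFGS iterations per level (recycled across levels).
#' @param init optional [affine_transform] used as the starting point
#'   instead of the moment-matching initialisation (warm start).
#' @param max_shift_mm bound on the centred translation (the displacement
#'   of the fixed image's centre of mass). Pre-aligned bones admit only a
#'   few mm; larger shifts are degenerate slide-along-the-shaft optima and
#'   are rejected.
#' @return An [affine_transform] with attributes `ssd_initial`,
#'   `ssd_final` and `converged`.
#' @export
affine_register <- function(moving, fixed, levels = c(4, 2), maxit = 60L,
                            init = NULL, max_shift_mm = 12) {
  stopifnot(inherits(moving, "scalar_volume"), inherits(fixed, "scalar_volume"))
  if (sum(moving$values) <= 0 || sum(fixed$values) <= 0) {
    stop("empty (all-zero) volume")
  }
  com_f <- volume_com(fixed)
  cen <- com_f
  # a plausible affine between pre-aligned same-species bone volumes stays
  # close to a rigid map: scales far from 1 signal a degenerate SSD optimum
  # (e.g. mapping the template onto a fraction of the subject), not anatomy
  scale_ok <- function(L) {
    sv <- svd(L)$d
    all(sv > 0.85 & sv < 1.2)
  }
  if (is.null(init)) {
    # candidate initialisations; a locally deformed subject (say an
    # enlarged head) corrupts global moment matching, so the centre-of-mass
    # and identity starts compete with it on first-level SSD
    com_m <- volume_com(moving)
    m2_f <- volume_second_moments(fixed, com_f)
    m2_m <- volume_second_moments(moving, com_m)
    scale0 <- pmin(1.2, pmax(0.85, sqrt(pmax(m2_m, 1e-12) /
                                          pmax(m2_f, 1e-12))))
    init_candidates <- list(list(Lc = diag(scale0), tc = com_m - com_f),
                            list(Lc = diag(3), tc = com_m - com_f),
                            list(Lc = diag(3), tc = c(0, 0, 0)))
    # centre-of-mass matching reflects mass distribution, not pose: a
    # tapered subject's COM sits far down the shaft, so COM candidates
    # beyond the plausible-shift bound are dropped rather than scored
    init_candidates <- Filter(function(cd) {
      sqrt(sum(cd$tc^2)) <= max_shift_mm
    }, init_candidates)
    if (length(init_candidates) == 0L) {
      init_candidates <- list(list(Lc = diag(3), tc = c(0, 0, 0)))
    }
  } else {
    stopifnot(inherits(init, "affine_transform"))
    init_candidates <- list(list(
      Lc = init$linear,
      tc = init$translation - cen + as.numeric(init$linear %*% cen)))
  }
  Lc <- init_candidates[[1]]$Lc
  tc <- init_candidates[[1]]$tc
  maxit <- rep(as.integer(maxit), length.out = length(levels))
  conv <- TRUE
  ssd0_all <- NA_real_
  ssd1_all <- NA_real_
  for (li in seq_along(levels)) {
    lev <- levels[li]
    f <- resample_to_spacing(fixed, lev)
    m <- resample_to_spacing(moving, lev)
    g <- volume_gradient_arrays(m)
    eval_fn <- function(p, want_grad) {
      Lp <- matrix(p[1:9], 3, 3, byrow = TRUE)
      tp <- p[10:12]
      L <- Lp
      tt <- as.numeric(cen + tp - Lp %*% cen)
      cpp_affine_ssd_grad(f$values, as.integer(f$dims), f$origin,
                          f$spacing, m$values,
                          g[[1]], g[[2]], g[[3]], as.integer(m$dims), m$origin,
                          m$spacing, L, tt, want_grad)
    }
    if (li == 1L && length(init_candidates) > 1L) {
      ssds <- vapply(init_candidates, function(cd) {
        eval_fn(c(as.numeric(t(cd$Lc)), cd$tc), FALSE)$ssd
      }, numeric(1))
      best <- which.min(ssds)
      Lc <- init_candidates[[best]]$Lc
      tc <- init_candidates[[best]]$tc
    }
    p0 <- c(as.numeric(t(Lc)), tc)
    r0 <- eval_fn(p0, FALSE)
    fn <- function(p) eval_fn(p, FALSE)$ssd
    gr <- function(p) {
      r <- eval_fn(p, TRUE)
      gL <- r$grad[1:9]
      gt <- r$grad[10:12]
      # chain rule to the centred parameterisation (row-major L order)
      gLc <- gL - as.numeric(t(outer(gt, cen)))
      c(gLc, gt)
    }
    opt <- stats::optim(p0, fn, gr, method = "BFGS",
                        control = list(maxit = maxit[li],
                                       parscale = c(rep(0.02, 9), rep(2, 3)),
                                       reltol = 1e-6))
    L_cand <- matrix(opt$par[1:9], 3, 3, byrow = TRUE)
    shift_ok <- sqrt(sum(opt$par[10:12]^2)) <= max_shift_mm
    if (opt$value <= r0$ssd && scale_ok(L_cand) && shift_ok) {
      Lc <- L_cand
      tc <- opt$par[10:12]
    } else if (!scale_ok(L_cand) || !shift_ok) {
      warning("affine_register: rejecting degenerate solution (",
              if (!scale_ok(L_cand)) "scale" else "shift",
              "); keeping previous estimate")
      conv <- FALSE
    }
    # report the SSD pair of the finest level (comparable voxel counts)
    ssd0_all <- r0$ssd
    ssd1_all <- min(opt$value, r0$ssd)
    if (opt$convergence != 0) conv <- FALSE
  }
  L <- Lc
  tt <- as.numeric(cen + tc - Lc %*% cen)
  out <- affine_transform(L, tt)
  attr(out, "ssd_initial") <- ssd0_all
  attr(out, "ssd_final") <- ssd1_all
  attr(out, "converged") <- conv
  if (!conv) warning("affine_register: descent did not fully converge; ",
                     "returning best-so-far")
  out
}

apply_affine <- function(transform, points) {
  sweep(points %*% t(transform$linear), 2, transform$translation, "+")
}

invert_affine <- function(transform) {
  Li <- solve(transform$linear)
  affine_transform(Li, -as.numeric(Li %*% transform$translation))
}
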