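# Rigid mutual-information co-registration and greedy symmetric diffeomorphic
# normalization with a localized cross-correlation metric.

#' Mutual information between two images
#'
#' Shannon mutual information (nats) from a joint histogram with
#' `bins` x `bins` equal-width cells spanning each image's intensity range.
#' Constant images carry no information and score 0.
#'
#' @param a,b numeric arrays of identical shape.
#' @param bins histogram bins per axis (default 32).
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(a, b, bins = 32) {
  if (!all(dim(a) == dim(b))) stop("images must share a shape")
  av <- as.numeric(a); bv <- as.numeric(b)
  if (any(!is.finite(av)) || any(!is.finite(bv))) stop("non-finite intensities")
  ra <- range(av); rb <- range(bv)
  ia <- if (diff(ra) == 0) rep(1L, length(av))
        else pmin(pmax(1L, as.integer((av - ra[1]) / diff(ra) * bins) + 1L), bins)
  ib <- if (diff(rb) == 0) rep(1L, length(bv))
        else pmin(pmax(1L, as.integer((bv - rb[1]) / diff(rb) * bins) + 1L), bins)
  p <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins) / length(av)
  pj <- matrix(p, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  max(sum(pj[nz] * log(pj[nz] / outer(pa, pb)[nz])), 0)
}

#' Rigid registration by mutual-information maximization
#'
#' 6-parameter (3 in 2-D) rigid-body alignment of `moving` to `fixed` using a
#' multiresolution pyramid and derivative-free direction-set (Nelder-Mead)
#' optimization of negative mutual information, warm-started across levels.
#'
#' @param moving,fixed numeric arrays of identical shape.
#' @param levels pyramid decimation factors, coarse to fine.
#' @param bins histogram bins for the metric.
#' @param fixed_mask optional 0/1 array in the fixed image's space; nonzero
#'   voxels (e.g. a lesion) are excluded from the metric, so intensities
#'   inside the mask cannot influence the result.
#' @return A [rigid_transform()] mapping the moving image onto the fixed
#'   grid; attributes `mi` (final metric) and `converged`.
#' @export
rigid_register <- function(moving, fixed, levels = c(4, 2, 1), bins = 32,
                           fixed_mask = NULL) {
  if (!all(dim(moving) == dim(fixed))) stop("images must share a shape")
  d <- length(dim(fixed))
  na <- if (d == 2) 1 else 3
  par <- rep(0, na + d)
  mi0 <- NA_real_
  sel1 <- TRUE
  for (lv in levels) {
    mv <- downsample_image(moving, lv)
    fx <- downsample_image(fixed, lv)
    sel <- if (is.null(fixed_mask)) TRUE
           else !(downsample_image(array(as.numeric(fixed_mask > 0),
                                         dim(fixed)), lv) > 0)
    if (lv == 1) sel1 <- sel
    geom <- volume_geometry(dim(fx))
    obj <- function(p) {
      rt <- rigid_transform(p[seq_len(na)], p[na + seq_len(d)])
      w <- warp_image(mv, rt, geometry = geom)
      -mutual_information(w[sel], fx[sel], bins)
    }
    # translations live in level voxels
    par[na + seq_len(d)] <- par[na + seq_len(d)] * ifelse(lv == levels[1], 1, 2)
    fit <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-9,
                                       parscale = c(rep(2, na), rep(1, d))))
    par <- fit$par
    mi0 <- -fit$value
  }
  # pyramid uses seq(1, n, by = f) so level origins coincide at voxel 1;
  # translations recovered at the final (full-resolution) level need no rescale
  out <- rigid_transform(par[seq_len(na)], par[na + seq_len(d)])
  base <- mutual_information(moving[sel1], fixed[sel1], bins)
  attr(out, "mi") <- mi0
  attr(out, "converged") <- is.finite(mi0) && mi0 >= base - 1e-9
  if (!attr(out, "converged"))
    warning("rigid registration failed to improve mutual information")
  out
}

# ---- localized cross-correlation metric -------------------------------------

# Shared statistics for the CC metric over truncated (2r+1)^d windows.
# valid marks voxels allowed to contribute (FALSE inside cost-function masks).
cc_stats <- function(S, T, r, valid) {
  V <- valid * 1
  N <- box_sum(V, r)
  bs <- function(x) box_sum(x * V, r)
  sS <- bs(S); sT <- bs(T)
  Np <- pmax(N, 1)
  muS <- sS / Np; muT <- sT / Np
  A <- bs(S * T) - N * muS * muT
  B <- bs(S * S) - N * muS^2
  C <- bs(T * T) - N * muT^2
  eps <- 1e-10
  ok <- valid & (B > eps) & (C > eps) & (N >= 2)
  rho <- array(0, dim(S))
  rho[ok] <- (A[ok]^2) / (B[ok] * C[ok])
  list(A = A, B = B, C = C, muS = muS, muT = muT, rho = rho, ok = ok,
       n_valid = sum(valid))
}

# exact gradient of mean(rho over valid centers) wrt the intensities of one
# image (img = S side when other = T); window sums make it O(image).
cc_intensity_grad <- function(stats_, img, other, r, valid) {
  q1 <- array(0, dim(img)); q2 <- array(0, dim(img))
  ok <- stats_$ok
  q1[ok] <- 2 * stats_$A[ok] / (stats_$B[ok] * stats_$C[ok])
  q2[ok] <- 2 * stats_$A[ok]^2 / (stats_$B[ok]^2 * stats_$C[ok])
  g <- other * box_sum(q1, r) - box_sum(q1 * stats_$muT, r) -
       img * box_sum(q2, r) + box_sum(q2 * stats_$muS, r)
  g * (valid * 1) / max(stats_$n_valid, 1)
}

#' Localized squared cross-correlation and its gradient
#'
#' Computes the per-voxel localized (squared) cross-correlation
#' `rho = <Sb,Tb>^2 / (<Sb,Sb> <Tb,Tb>)` over a `(2r+1)^d` window with local
#' means subtracted, its mean over valid voxels (the registration score), and
#' the analytic gradient of the score with respect to a deformation of `S`.
#' Masked voxels are excluded from the windows and from the score; the
#' gradient is forced to zero inside the mask.
#'
#' @param S,T numeric arrays of identical shape.
#' @param radius window radius in voxels (default 4).
#' @param mask optional 0/1 array; nonzero voxels are excluded.
#' @return List: `score`, `rho` (array), `grad` (list of d arrays — the
#'   vector force on S), `grad_scalar` (d(score)/d(S intensity)).
#' @export
local_cc <- function(S, T, radius = 4, mask = NULL) {
  if (!all(dim(S) == dim(T))) stop("images must share a shape")
  if (any(2 * radius + 1 > dim(S))) stop("window larger than the image")
  valid <- if (is.null(mask)) array(TRUE, dim(S)) else !(array(mask, dim(S)) > 0)
  st <- cc_stats(S, T, radius, valid)
  gs <- cc_intensity_grad(st, S, T, radius, valid)
  gI <- gradient_arrays(S)
  list(score = if (st$n_valid) sum(st$rho[valid]) / st$n_valid else 0,
       rho = st$rho,
       grad = lapply(gI, function(G) gs * G),
       grad_scalar = gs)
}

#' Constrained cost-function masking of an update field
#'
#' Treats the lesion as missing data: update vectors inside the mask are
#' discarded and re-estimated by diffusion inpainting (iterative neighbor
#' averaging with the exterior held fixed), producing a smooth extension of
#' the exterior velocity into the lesion.
#'
#' @param update a [deformation_field()].
#' @param mask 0/1 array in the update's space; nonzero marks the lesion.
#' @param sweeps Jacobi sweeps (default 50).
#' @return The constrained [deformation_field()].
#' @export
apply_cost_mask <- function(update, mask, sweeps = 50) {
  msk <- array(mask, update$geometry$shape) > 0
  if (!any(msk)) return(update)
  if (all(msk)) stop("mask covers the whole image")
  d <- length(update$geometry$shape)
  ones <- array(1, dim(msk))
  nb_n <- box_sum(ones, 1) - 1
  disp <- update$disp
  for (k in seq_len(d)) {
    v <- field_component(update, k)
    v[msk] <- 0
    for (s in seq_len(sweeps)) {
      av <- (box_sum(v, 1) - v) / nb_n
      v[msk] <- av[msk]
    }
    idx <- c(rep(list(quote(expr = )), d), list(k))
    disp <- do.call(`[<-`, c(list(disp), idx, list(v)))
  }
  deformation_field(disp, update$geometry)
}

# ---- greedy symmetric diffeomorphic registration ----------------------------

scale_force <- function(force, max_step) {
  mag <- sqrt(Reduce(`+`, lapply(force, function(x) x^2)))
  m <- max(mag)
  if (m < 1e-12) return(NULL)
  lapply(force, function(x) x * (max_step / m))
}

force_to_field <- function(force, geometry) {
  d <- length(geometry$shape)
  disp <- array(0, c(geometry$shape, d))
  for (k in seq_len(d)) {
    idx <- c(rep(list(quote(expr = )), d), list(k))
    disp <- do.call(`[<-`, c(list(disp), idx, list(force[[k]])))
  }
  deformation_field(disp, geometry)
}

#' Greedy symmetric diffeomorphic registration
#'
#' Estimates a diffeomorphic map between `S` and `T` as two half-warps that
#' meet at a mid-point, so the result is independent of the input order.  Per
#' iteration, both images are warped to the mid-space, localized
#' cross-correlation forces are computed for each side, fluid-smoothed,
#' step-limited, composed into the half-warps, and the total fields are
#' elastically smoothed; the similarity score must not decrease (failed steps
#' are halved).  A resolution pyramid (decimation factors `levels`) runs
#' coarse to fine.  When a lesion `mask` (in `S`'s space) is given, masked
#' voxels are excluded from the metric and the update inside the lesion is
#' inpainted from the exterior (constrained cost-function masking), making
#' the output independent of the intensities inside the lesion.
#'
#' @param S,T numeric arrays of identical shape (source and target).
#' @param levels pyramid decimation factors, coarse to fine.
#' @param max_iter iteration cap per level (default 250).
#' @param radius correlation-window radius in voxels.
#' @param mask optional 0/1 lesion mask in `S`'s space.
#' @param sigma_fluid Gaussian sigma (voxels) smoothing each update.
#' @param sigma_elastic Gaussian sigma (voxels) smoothing the total fields.
#' @param max_step largest update per iteration (voxels).
#' @param tol,patience stop a level early when the score has improved by less
#'   than `tol` over `patience` iterations.
#' @param verbose print per-level progress.
#' @return Object of class `diffeo_pair`: `forward` / `inverse`
#'   [deformation_field()]s (pull-back maps resampling `S` onto `T`'s grid
#'   and vice versa), the half-warps `phi1`, `phi2`, and `trace` (accepted
#'   similarity scores per level).
#' @export
syn_register <- function(S, T, levels = c(8, 4, 2, 1), max_iter = 250,
                         radius = 4, mask = NULL,
                         sigma_fluid = 3.0, sigma_elastic = 0.5,
                         max_step = 0.25, tol = 1e-6, patience = 10,
                         verbose = FALSE) {
  if (!all(dim(S) == dim(T))) stop("images must share a shape")
  shape <- dim(S)
  d <- length(shape)
  u1 <- NULL; u2 <- NULL
  trace <- list()
  for (lv in levels) {
    S_l <- downsample_image(S, lv)
    T_l <- downsample_image(T, lv)
    mask_l <- if (is.null(mask)) NULL
              else (downsample_image(array(as.numeric(mask > 0), shape), lv) > 0) * 1
    geom <- volume_geometry(dim(S_l))
    if (is.null(u1)) {
      u1 <- zero_field(geom); u2 <- zero_field(geom)
    } else {
      fac <- dim(S_l)[1] / u1$geometry$shape[1]
      u1 <- upsample_field(u1, dim(S_l), fac)
      u2 <- upsample_field(u2, dim(S_l), fac)
    }
    co <- grid_coords(dim(S_l))
    warp_by <- function(img, u, interp = "linear") {
      pts <- lapply(seq_len(d), function(k) co[[k]] + field_component(u, k))
      array(interp_linear(img, pts, fill = 0), dim(S_l))
    }
    step_scale <- 1
    best_score <- -Inf
    prev_score <- -Inf
    best <- list(u1 = u1, u2 = u2)
    lvl_trace <- numeric(0)
    best_hist <- numeric(0)
    it <- 0
    while (it < max_iter) {
      it <- it + 1
      Sw <- warp_by(S_l, u1)
      Tw <- warp_by(T_l, u2)
      validS <- if (is.null(mask_l)) array(TRUE, dim(S_l))
                else !(warp_by(mask_l, u1) > 0)
      # any voxel whose interpolation stencil touched the lesion is invalid;
      # zeroing them keeps image gradients free of lesion intensities
      if (!is.null(mask_l)) Sw <- Sw * validS
      st <- cc_stats(Sw, Tw, radius, validS)
      score <- if (st$n_valid) sum(st$rho[validS]) / st$n_valid else 0
      if (score >= best_score) {
        # accepted iterate: the recorded trace is non-decreasing
        best_score <- score
        best <- list(u1 = u1, u2 = u2)
        lvl_trace <- c(lvl_trace, score)
      }
      best_hist <- c(best_hist, best_score)
      # simple trust-region on the step length; worse scores are kept (the
      # best iterate is remembered) so a transient dip cannot stall the level
      step_scale <- if (score < prev_score) max(step_scale / 2, 0.05)
                    else min(step_scale * 1.1, 1)
      prev_score <- score
      # stop when the score has improved by < tol over the last `patience`
      # iterations
      if (it > patience &&
          best_hist[it] - best_hist[it - patience] < tol) break
      gS <- cc_intensity_grad(st, Sw, Tw, radius, validS)
      # T side: swap the roles of the two images in the same statistics
      stT <- list(A = st$A, B = st$C, C = st$B, muS = st$muT, muT = st$muS,
                  ok = st$ok, n_valid = st$n_valid)
      gT <- cc_intensity_grad(stT, Tw, Sw, radius, validS)
      gradSw <- gradient_arrays(Sw)
      gradTw <- gradient_arrays(Tw)
      f1 <- lapply(seq_len(d), function(k) smooth_gaussian(gS * gradSw[[k]], sigma_fluid))
      f2 <- lapply(seq_len(d), function(k) smooth_gaussian(gT * gradTw[[k]], sigma_fluid))
      d1 <- scale_force(f1, max_step * step_scale)
      d2 <- scale_force(f2, max_step * step_scale)
      if (is.null(d1) && is.null(d2)) break
      # missing-data region in mid-space: the lesion carried along S's half-warp
      mmid <- if (is.null(mask_l)) NULL else (!validS) * 1
      upd <- function(u, dd) {
        if (is.null(dd)) return(u)
        df <- force_to_field(dd, geom)
        if (!is.null(mmid) && any(mmid > 0) && !all(mmid > 0))
          df <- apply_cost_mask(df, mmid)
        smooth_field(compose_disp(u, df), sigma_elastic)
      }
      u1n <- upd(u1, d1)
      u2n <- upd(u2, d2)
      jac_ok <- function(u) min(jacobian_determinant(u)) > 0
      tries <- 0
      while ((!jac_ok(u1n) || !jac_ok(u2n)) && tries < 5) {
        tries <- tries + 1
        d1 <- if (is.null(d1)) NULL else lapply(d1, `/`, 2)
        d2 <- if (is.null(d2)) NULL else lapply(d2, `/`, 2)
        u1n <- upd(u1, d1)
        u2n <- upd(u2, d2)
      }
      if (tries == 5 && (!jac_ok(u1n) || !jac_ok(u2n)))
        stop("could not maintain a positive Jacobian")
      u1 <- u1n; u2 <- u2n
    }
    u1 <- best$u1; u2 <- best$u2
    trace[[paste0("level_", lv)]] <- lvl_trace
    if (verbose)
      message(sprintf("level %d: %d iters, score %.6f", lv, it, best_score))
  }
  u1i <- invert_field(u1, max_iter = 50, tol = 0.002)
  u2i <- invert_field(u2, max_iter = 50, tol = 0.002)
  structure(list(forward = compose_disp(u1, u2i),
                 inverse = compose_disp(u2, u1i),
                 phi1 = u1, phi2 = u2,
                 trace = trace, score = max(unlist(trace), -Inf)),
            class = "diffeo_pair")
}

#' @export
print.diffeo_pair <- function(x, ...) {
  cat("diffeo_pair: final similarity", signif(x$score, 5), "\n")
  cat("  forward: "); print(x$forward)
  cat("  inverse: "); print(x$inverse)
  invisible(x)
}
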