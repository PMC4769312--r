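#' Simplified reference tissue model parameters
#'
#' `R_I` is the relative delivery (target/reference perfusion ratio), `k2`
#' (1/min) the efflux rate from the target region, `BP` the binding
#' potential.  The basis rate is `theta = k2 / (1 + BP)`, which must be
#' positive and finite, hence `BP > -1`.
#'
#' @param R_I relative delivery (unitless).
#' @param k2 efflux rate (1/min), non-negative.
#' @param BP binding potential, `> -1`.
#' @return Object of class `srtm_params`.
#' @export
srtm_params <- function(R_I, k2, BP) {
  if (!is.finite(R_I)) stop("R_I must be finite")
  if (k2 < 0) stop("k2 must be >= 0")
  if (BP <= -1) stop("BP must be > -1")
  structure(list(R_I = R_I, k2 = k2, BP = BP), class = "srtm_params")
}

#' @export
print.srtm_params <- function(x, ...) {
  cat(sprintf("srtm_params: R_I = %.4g, k2 = %.4g /min, BP = %.4g\n",
              x$R_I, x$k2, x$BP))
  invisible(x)
}

#' Logarithmic theta grid for the basis function method
#'
#' `theta_j = lo * (hi/lo)^((j-1)/(n-1))`: 100 values distributed
#' logarithmically between 0.00636 and 1 per minute by default.
#'
#' @param n number of basis rates (>= 2).
#' @param lo,hi grid bounds (1/min), `0 < lo < hi`.
#' @return Numeric vector of length `n`, strictly increasing.
#' @export
theta_grid <- function(n = 100, lo = 0.00636, hi = 1.0) {
  if (!(lo > 0 && hi > lo)) stop("need 0 < lo < hi")
  if (n < 2) stop("need n >= 2")
  lo * (hi / lo)^((seq_len(n) - 1) / (n - 1))
}

#' Simulate an SRTM tissue curve
#'
#' Evaluates
#' `C_T(t) = R_I C_R(t) + (k2 - R_I k2/(1+BP)) (C_R (x) e^{-k2/(1+BP) t})(t)`
#' by convolution on the fine kinetic grid.
#'
#' @param p an [srtm_params()].
#' @param ref reference-region curve: anything with `time_min` and `value`
#'   (a [tissue_curve()] or [blood_curve()]); linearly interpolated, zero
#'   before its first sample.
#' @param times_min evaluation times (min) within the reference span.
#' @return Numeric vector of target-tissue values.
#' @export
srtm_tac <- function(p, ref, times_min) {
  if (any(times_min < 0) || any(times_min > max(ref$time_min) + 1e-9))
    stop("requested times outside the reference curve's span")
  theta <- p$k2 / (1 + p$BP)
  grid <- fine_grid(max(ref$time_min))
  cr <- interp_to_grid(ref$time_min, ref$value, grid)
  ct <- p$R_I * cr + (p$k2 - p$R_I * theta) * exp_conv(cr, theta, grid[2] - grid[1])
  stats::approx(grid, ct, xout = times_min, rule = 2)$y
}

#' Build the SRTM basis set
#'
#' Each basis curve `B_i = (C_R (x) e^{-theta_i t})` is evaluated on the fine
#' grid and frame-averaged onto the acquisition schedule; the reference curve
#' is frame-averaged alongside so that data and design live in the same
#' (frame) domain.
#'
#' @param ref reference-region curve (`time_min`, `value`).
#' @param schedule a [frame_schedule()] the basis is fitted on.
#' @param thetas strictly increasing basis rates (1/min).
#' @return Object of class `srtm_basis`: `thetas`, `B` (frames x n matrix),
#'   `cr` (reference at frames), `weight`, `time_min`.
#' @export
build_basis <- function(ref, schedule, thetas = theta_grid()) {
  if (!length(thetas)) stop("empty theta grid")
  if (any(diff(thetas) <= 0)) stop("thetas must be strictly increasing")
  t_end <- max(schedule$start_s + schedule$duration_s) / 60
  # a frame-domain reference reaches only the last mid-time; the tail to the
  # frame end is held at the last sample
  if (max(ref$time_min) < max(frame_mid_times(schedule)) - 1e-9)
    stop("reference curve does not cover the schedule")
  grid <- fine_grid(t_end)
  dt <- grid[2] - grid[1]
  cr_grid <- interp_to_grid(ref$time_min, ref$value, grid)
  cr_f <- frame_average(cr_grid, grid, schedule)
  B <- vapply(thetas,
              function(th) frame_average(exp_conv(cr_grid, th, dt), grid, schedule)$value,
              numeric(length(schedule)))
  structure(list(thetas = thetas, B = B, cr = cr_f$value,
                 weight = cr_f$weight, time_min = cr_f$time_min,
                 cr_grid = cr_grid, grid = grid),
            class = "srtm_basis")
}

#' @export
print.srtm_basis <- function(x, ...) {
  cat("srtm_basis:", length(x$thetas), "rates in [",
      signif(min(x$thetas), 4), ",", signif(max(x$thetas), 4), "] /min,",
      length(x$time_min), "frames\n")
  invisible(x)
}

# weighted 2-column LS sufficient statistics shared by voxel and map fits
basis_gram <- function(basis) {
  w <- basis$weight
  list(w = w,
       Scc = sum(w * basis$cr^2),
       Scb = colSums(w * basis$cr * basis$B),
       Sbb = colSums(w * basis$B * basis$B))
}

#' Fit SRTM to one tissue curve by the basis function method
#'
#' For every basis rate `theta_i`, solves the weighted linear problem
#' `C_T = alpha1 C_R + alpha2 B_i` and keeps the rate with the lowest
#' weighted residual sum of squares (ties broken toward the smaller rate).
#' Parameters are recovered as `R_I = alpha1`, `k2 = alpha2 + alpha1 theta`,
#' `BP = k2/theta - 1`.
#'
#' @param tac a [tissue_curve()] aligned with the basis frames.
#' @param basis an [srtm_basis()][build_basis].
#' @return List: `params` ([srtm_params()]), `theta_index`, `theta`, `alpha`,
#'   `wrss` (vector over all rates at `$wrss_all`), `flagged` (degenerate
#'   design).
#' @export
fit_srtm_voxel <- function(tac, basis) {
  if (length(tac$value) != length(basis$cr))
    stop("tissue curve is not aligned with the basis frames")
  g <- basis_gram(basis)
  w <- g$w
  y <- tac$value
  Scy <- sum(w * basis$cr * y)
  Sby <- colSums(w * basis$B * y)
  Syy <- sum(w * y^2)
  det <- g$Scc * g$Sbb - g$Scb^2
  flagged <- det < 1e-10 * pmax(g$Scc * g$Sbb, 1e-300)
  det_safe <- ifelse(flagged, NA_real_, det)
  a1 <- (g$Sbb * Scy - g$Scb * Sby) / det_safe
  a2 <- (g$Scc * Sby - g$Scb * Scy) / det_safe
  wrss_all <- Syy - (a1 * Scy + a2 * Sby)
  wrss_all <- pmax(wrss_all, 0)
  if (all(is.na(wrss_all))) stop("all basis designs degenerate")
  i <- which.min(wrss_all)  # ties resolve to the smaller theta
  theta <- basis$thetas[i]
  R_I <- a1[i]
  k2 <- a2[i] + a1[i] * theta
  BP <- if (abs(k2) < 1e-12 && abs(a2[i]) < 1e-12) 0 else k2 / theta - 1
  if (all(y == 0)) { R_I <- 0; k2 <- 0; BP <- 0 }
  list(params = srtm_params(R_I, max(k2, 0), max(BP, -1 + 1e-9)),
       theta_index = i, theta = theta,
       alpha = c(a1[i], a2[i]),
       wrss = wrss_all[i], wrss_all = wrss_all,
       flagged = any(flagged))
}

#' Voxel-wise SRTM parametric maps by the basis function method
#'
#' Builds the basis once from the reference curve and fits every masked voxel,
#' fully vectorized over voxels.
#'
#' @param img a [dynamic_image()].
#' @param ref_tac reference-region curve (e.g. cerebellar gray matter from
#'   [region_tac()]).
#' @param mask logical/0-1 array of voxels to fit.
#' @param thetas basis rates, default [theta_grid()].
#' @return List of [parametric_map()]s `R_I`, `k2`, `BP`, `theta`, `wrss`,
#'   plus `flagged` (logical array of degenerate voxels).
#' @export
srtm_parametric_map <- function(img, ref_tac, mask = NULL, thetas = theta_grid()) {
  geom <- img$geometry
  if (is.null(mask)) mask <- array(TRUE, geom$shape)
  mask <- array(as.logical(mask), geom$shape)
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  basis <- build_basis(ref_tac, img$schedule, thetas)
  g <- basis_gram(basis)
  w <- g$w
  Fn <- n_frames(img)
  Y <- t(matrix(img$data, ncol = Fn)[idx, , drop = FALSE])  # F x nvox
  Scy <- colSums(w * basis$cr * Y)                          # nvox
  SbY <- crossprod(basis$B, w * Y)                          # ntheta x nvox
  Syy <- colSums(w * Y * Y)
  det <- g$Scc * g$Sbb - g$Scb^2
  bad <- det < 1e-10 * pmax(g$Scc * g$Sbb, 1e-300)
  nv <- length(idx)
  best <- list(wrss = rep(Inf, nv), i = rep(NA_integer_, nv),
               a1 = rep(NA_real_, nv), a2 = rep(NA_real_, nv))
  for (i in seq_along(basis$thetas)) {
    if (bad[i]) next
    a1 <- (g$Sbb[i] * Scy - g$Scb[i] * SbY[i, ]) / det[i]
    a2 <- (g$Scc * SbY[i, ] - g$Scb[i] * Scy) / det[i]
    wr <- pmax(Syy - (a1 * Scy + a2 * SbY[i, ]), 0)
    upd <- wr < best$wrss - 1e-15 * pmax(Syy, 1)  # strict: ties keep smaller theta
    best$wrss[upd] <- wr[upd]; best$i[upd] <- i
    best$a1[upd] <- a1[upd]; best$a2[upd] <- a2[upd]
  }
  theta <- basis$thetas[best$i]
  R_I <- best$a1
  k2 <- pmax(best$a2 + best$a1 * theta, 0)
  BP <- k2 / theta - 1
  zero <- Syy == 0
  R_I[zero] <- 0; k2[zero] <- 0; BP[zero] <- 0
  mk <- function(v, nm, un) {
    arr <- array(NA_real_, geom$shape); arr[idx] <- v
    parametric_map(nm, arr, un, geom)
  }
  flag_arr <- array(FALSE, geom$shape)
  list(R_I = mk(R_I, "R_I", "ratio"), k2 = mk(k2, "k2", "1/min"),
       BP = mk(BP, "BP", "unitless"), theta = mk(theta, "theta", "1/min"),
       wrss = mk(best$wrss, "wrss", "kBq^2/mL^2"), flagged = flag_arr)
}

#' Early-summed normalized uptake ratio map
#'
#' Integrates the dynamic image over an early window (0-6 min by default) and
#' divides by the mean of the summed image inside a reference mask, yielding
#' the relative-perfusion ratio map.
#'
#' @param img a [dynamic_image()].
#' @param window integration window in minutes, default `c(0, 6)`.
#' @param reference_mask logical/0-1 array defining the reference region.
#' @return A [parametric_map()] named `"R_P"`.
#' @export
early_sum_ratio <- function(img, window = c(0, 6), reference_mask) {
  s <- integrate_frames(img, window[1], window[2])
  m <- mean(s[as.logical(reference_mask)])
  if (!is.finite(m) || m <= 0) stop("reference mean must be positive")
  parametric_map("R_P", s / m, "ratio", img$geometry)
}
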