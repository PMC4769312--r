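#' One-tissue model parameters
#'
#' `K1` (1/min) is the delivery rate constant — the CBF surrogate for
#' O-15 water — `k2` (1/min) the tissue clearance rate, and `Vb` the
#' fractional vascular volume contributing intravascular signal.
#'
#' @param K1,k2 rate constants (1/min), non-negative.
#' @param Vb vascular volume fraction in `[0, 1]`.
#' @return Object of class `one_tissue_params`.
#' @export
one_tissue_params <- function(K1, k2, Vb) {
  if (K1 < 0 || k2 < 0) stop("K1 and k2 must be >= 0")
  if (Vb < 0 || Vb > 1) stop("Vb must lie in [0, 1]")
  structure(list(K1 = K1, k2 = k2, Vb = Vb), class = "one_tissue_params")
}

#' @export
print.one_tissue_params <- function(x, ...) {
  cat(sprintf("one_tissue_params: K1 = %.4g /min, k2 = %.4g /min, Vb = %.4g\n",
              x$K1, x$k2, x$Vb))
  invisible(x)
}

#' Simulate a one-tissue tissue curve
#'
#' Evaluates the measured total concentration
#' `C(t) = K1 (Cb (x) e^{-k2 t})(t) + Vb Cb(t)` for an arterial input `Cb`,
#' where `(x)` is convolution, on the fine kinetic grid (step 0.01 min, linear
#' interpolation of the blood samples, zero before the first sample).
#'
#' @param p a [one_tissue_params()].
#' @param input a [blood_curve()].
#' @param times_min evaluation times (min), within `[0, max(input time)]`.
#' @return Numeric vector of tissue activity values at `times_min`.
#' @export
one_tissue_tac <- function(p, input, times_min) {
  if (any(times_min < 0) || any(times_min > max(input$time_min) + 1e-9))
    stop("requested times outside the input curve's span")
  grid <- fine_grid(max(input$time_min))
  cb <- blood_on_grid(input, grid)
  ct <- one_tissue_on_grid(p, cb, grid[2] - grid[1])
  stats::approx(grid, ct, xout = times_min, rule = 2)$y
}

# model curve on an already-interpolated fine-grid input
one_tissue_on_grid <- function(p, cb, dt) {
  p$K1 * exp_conv(cb, p$k2, dt) + p$Vb * cb
}

# model prediction in the frame domain: frame-averaged when a schedule is
# given, otherwise evaluated at the supplied mid-times
one_tissue_predict <- function(p, cb, grid, schedule = NULL, times_min = NULL) {
  ct <- one_tissue_on_grid(p, cb, grid[2] - grid[1])
  if (!is.null(schedule)) frame_average(ct, grid, schedule)$value
  else stats::approx(grid, ct, xout = times_min, rule = 2)$y
}

#' Fit the one-tissue model to a tissue curve
#'
#' Bounded weighted nonlinear least squares (three starting points to avoid
#' local minima).  When `schedule` is supplied the model is frame-averaged
#' before comparison, matching how frames measure time-averaged activity.
#'
#' @param tac a [tissue_curve()] (>= 4 frames).
#' @param input a [blood_curve()] (already delay/dispersion corrected).
#' @param schedule optional [frame_schedule()] for frame averaging.
#' @return List with `params` ([one_tissue_params()]), `wrss`, and
#'   `convergence` (0 = ok).
#' @export
fit_one_tissue <- function(tac, input, schedule = NULL) {
  if (length(tac$value) < 4) stop("need at least 4 frames")
  if (any(!is.finite(tac$value))) stop("non-finite values in tissue curve")
  if (all(tac$value == 0))
    return(list(params = one_tissue_params(0, 0, 0), wrss = 0, convergence = 0L))
  t_end <- if (is.null(schedule)) max(tac$time_min)
           else max(schedule$start_s + schedule$duration_s) / 60
  grid <- fine_grid(max(t_end, max(input$time_min)))
  cb <- blood_on_grid(input, grid)
  w <- tac$weight
  obj <- function(th) {
    p <- list(K1 = th[1], k2 = th[2], Vb = th[3])
    pred <- one_tissue_predict(p, cb, grid, schedule, tac$time_min)
    sum(w * (tac$value - pred)^2)
  }
  starts <- list(c(0.3, 0.3, 0.05), c(0.8, 1.0, 0.10), c(0.1, 0.05, 0.02))
  best <- NULL
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "L-BFGS-B",
                        lower = c(0, 0, 0), upper = c(10, 10, 1),
                        control = list(factr = 1e4, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$convergence != 0 && best$convergence != 52)
    warning("one-tissue optimizer did not converge: code ", best$convergence)
  list(params = one_tissue_params(best$par[1], best$par[2], best$par[3]),
       wrss = best$value, convergence = best$convergence)
}

# ---- linearized operational-equation estimator -------------------------------
# C(t) = P1 int Cb - P2 int C + P3 Cb with P1 = K1 + k2 Vb, P2 = k2, P3 = Vb.
# Returns the weighted LS solution; exact for noiseless data, and the
# work-horse behind the ridge parametric fit and the delay/dispersion search.

# cumulative integral of frame-domain data up to each frame mid-time
frame_cum_integral <- function(y, schedule = NULL, time_min = NULL) {
  if (!is.null(schedule)) {
    dur <- schedule$duration_s / 60
    if (is.matrix(y)) {
      inc <- y * dur
      apply(inc, 2, cumsum) - inc / 2
    } else cumsum(y * dur) - y * dur / 2
  } else {
    tm <- time_min
    tt <- c(0, tm)
    if (is.matrix(y)) {
      yy <- rbind(0, y)
      inc <- (yy[-1, , drop = FALSE] + yy[-nrow(yy), , drop = FALSE]) / 2 * diff(tt)
      apply(inc, 2, cumsum)
    } else {
      yy <- c(0, y)
      cumsum((yy[-1] + yy[-length(yy)]) / 2 * diff(tt))
    }
  }
}

one_tissue_linfit <- function(y, w, a, cvec, b) {
  X <- cbind(a, -b, cvec)
  A <- crossprod(X, X * w)
  r <- crossprod(X, w * y)
  th <- tryCatch(solve(A, r), error = function(e) matrix(0, 3, 1))
  pred <- X %*% th
  list(P = as.numeric(th), wrss = sum(w * (y - pred)^2))
}

lin_to_params <- function(P) {
  k2 <- max(P[2], 0)
  Vb <- min(max(P[3], 0), 1)
  K1 <- max(P[1] - k2 * Vb, 0)
  one_tissue_params(K1, k2, Vb)
}

#' Delay and dispersion correction of a measured arterial input
#'
#' The measured arterial curve lags (delay) and is smeared (dispersion,
#' monoexponential kernel `(1/tau) e^{-t/tau}`) relative to the input the
#' brain sees.  Both are estimated by a grid search — delay -10..20 s in
#' 0.25 s steps, dispersion 0..20 s in 0.5 s steps — minimizing the residual
#' sum of squares of a one-tissue fit to the whole-brain time-activity curve.
#' Numerical deconvolution is avoided: the monoexponential kernel has the
#' exact analytic inverse `true = m + tau dm/dt`, so each candidate input is
#' obtained by shifting the measured curve by `-dt` and sharpening it on the
#' fine grid; the candidate input then drives the tissue model against the
#' unmodified whole-brain curve, keeping the residual comparable across the
#' whole grid.
#'
#' @param measured a [blood_curve()] as sampled at the wrist.
#' @param whole_brain a [tissue_curve()] averaged over a brain mask.
#' @param schedule optional [frame_schedule()] for frame-averaged comparison.
#' @param delta_range_s,delta_step_s,tau_max_s,tau_step_s search grid (s).
#' @return List with `corrected` ([blood_curve()] estimate of the true input),
#'   `dd` (list `delta_t_s`, `tau_s`), `params` (whole-brain
#'   [one_tissue_params()] from a final nonlinear polish) and `wrss`.
#' @export
correct_delay_dispersion <- function(measured, whole_brain, schedule = NULL,
                                     delta_range_s = c(-10, 20),
                                     delta_step_s = 0.25,
                                     tau_max_s = 20, tau_step_s = 0.5) {
  if (stats::sd(whole_brain$value) < 1e-12)
    stop("whole-brain TAC is flat; cannot estimate delay/dispersion")
  dts <- seq(delta_range_s[1], delta_range_s[2], by = delta_step_s)
  taus <- seq(0, tau_max_s, by = tau_step_s)
  if (!length(dts) || !length(taus)) stop("empty search grid")

  t_end <- max(whole_brain$time_min)
  if (!is.null(schedule))
    t_end <- max(t_end, max(schedule$start_s + schedule$duration_s) / 60)
  grid <- fine_grid(t_end)
  dt <- grid[2] - grid[1]
  y <- whole_brain$value
  w <- whole_brain$weight
  b <- frame_cum_integral(y, schedule, whole_brain$time_min)

  deriv <- function(v) {
    n <- length(v)
    c(v[2] - v[1], (v[-(1:2)] - v[-((n - 1):n)]) / 2, v[n] - v[n - 1]) / dt
  }
  frame_of <- function(vals)
    if (!is.null(schedule)) frame_average(vals, grid, schedule)$value
    else stats::approx(grid, vals, xout = whole_brain$time_min, rule = 2)$y

  # candidate input: shift by -dt, sharpen analytically by tau.  Sharpening
  # is linear in tau, so design columns split into shift-only and
  # derivative parts computed once per delay.
  designs <- lapply(dts, function(d) {
    v <- interp_to_grid(measured$time_min - d / 60, measured$value, grid)
    dv <- deriv(v)
    list(v = v, dv = dv,
         Av = frame_of(cum_trapz(v, dt)), Ad = frame_of(cum_trapz(dv, dt)),
         Cv = frame_of(v), Cd = frame_of(dv))
  })

  wrss <- matrix(Inf, length(dts), length(taus))
  for (i in seq_along(dts)) for (j in seq_along(taus)) {
    de <- designs[[i]]
    tm <- taus[j] / 60
    wrss[i, j] <- one_tissue_linfit(y, w, de$Av + tm * de$Ad,
                                    de$Cv + tm * de$Cd, b)$wrss
  }
  # the linear objective carries a small frame-discretization floor that can
  # blur the (dt, tau) minimum; refine the best candidates with the exact
  # frame-averaged nonlinear model, which has no such floor
  n_refine <- min(60L, length(wrss))
  cand <- arrayInd(order(wrss)[seq_len(n_refine)], dim(wrss))
  best <- NULL
  for (r in seq_len(n_refine)) {
    i <- cand[r, 1]; j <- cand[r, 2]
    de <- designs[[i]]
    tm <- taus[j] / 60
    chat <- pmax(de$v + tm * de$dv, 0)
    lin <- one_tissue_linfit(y, w, de$Av + tm * de$Ad, de$Cv + tm * de$Cd, b)
    p0 <- lin_to_params(lin$P)
    obj <- function(th)
      sum(w * (y - one_tissue_predict(list(K1 = th[1], k2 = th[2], Vb = th[3]),
                                      chat, grid, schedule,
                                      whole_brain$time_min))^2)
    fit <- stats::optim(c(p0$K1, p0$k2, p0$Vb), obj, method = "L-BFGS-B",
                        lower = c(0, 0, 0), upper = c(10, 10, 1),
                        control = list(factr = 1e5, maxit = 200))
    if (is.null(best) || fit$value < best$value)
      best <- list(value = fit$value, par = fit$par, i = i, j = j, chat = chat)
  }
  best_dt <- dts[best$i]; best_tau <- taus[best$j]
  input_best <- blood_curve(grid, best$chat)

  list(corrected = input_best,
       dd = list(delta_t_s = best_dt, tau_s = best_tau),
       params = one_tissue_params(best$par[1], best$par[2], best$par[3]),
       wrss = best$value)
}

#' Voxel-wise linearized (ridge) parametric fit of the one-tissue model
#'
#' Solves the operational equation
#' `C(t) = P1 int Cb - P2 int C + P3 Cb` (with `P1 = K1 + k2 Vb`, `P2 = k2`,
#' `P3 = Vb`) by weighted linear least squares in every masked voxel.  A
#' second pass adds a per-voxel ridge penalty `h ||P - P_s||^2` pulling each
#' voxel toward the Gaussian-smoothed first-pass maps `P_s` (FWHM 2 voxels),
#' with `h = wrss_voxel / (local variance of the first-pass P + eps)` per
#' component — a spatially constrained regularization that suppresses noise
#' without biasing smooth regions, and that reduces to plain least squares as
#' `h -> 0`.
#'
#' @param img a [dynamic_image()].
#' @param input corrected arterial [blood_curve()].
#' @param mask logical/0-1 array of voxels to fit.
#' @param h `"auto"` (default) for the data-driven per-voxel penalty, or a
#'   single number (0 disables the second pass).
#' @param fwhm_voxels smoothing FWHM of the spatial prior, in voxels.
#' @return List of [parametric_map()]s `K1`, `k2`, `Vb`, plus `wrss` map.
#' @export
ridge_parametric_fit <- function(img, input, mask = NULL, h = "auto",
                                 fwhm_voxels = 2) {
  geom <- img$geometry
  if (is.null(mask)) mask <- array(TRUE, geom$shape)
  mask <- array(as.logical(mask), geom$shape)
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  Fn <- n_frames(img)
  if (Fn < 4) stop("need at least 4 frames")
  Y <- matrix(img$data, ncol = Fn)[idx, , drop = FALSE]  # nvox x F
  Y <- t(Y)                                              # F x nvox
  sched <- img$schedule
  tm <- frame_mid_times(sched)
  w <- sched$duration_s / 60
  grid <- fine_grid(max(max(tm), max(input$time_min)))
  cb <- blood_on_grid(input, grid)
  a <- stats::approx(grid, cum_trapz(cb, grid[2] - grid[1]), xout = tm, rule = 2)$y
  cv <- stats::approx(grid, cb, xout = tm, rule = 2)$y
  B <- frame_cum_integral(Y, sched)                      # F x nvox

  # per-voxel weighted normal equations (design: [a, -b_v, c])
  Saa <- sum(w * a * a); Sac <- sum(w * a * cv); Scc <- sum(w * cv * cv)
  Sab <- colSums(w * a * B); Sbc <- colSums(w * cv * B); Sbb <- colSums(w * B * B)
  r1 <- colSums(w * a * Y); r2 <- -colSums(w * B * Y); r3 <- colSums(w * cv * Y)
  Syy <- colSums(w * Y * Y)

  solve3 <- function(m11, m12, m13, m22, m23, m33, b1, b2, b3) {
    det <- m11 * (m22 * m33 - m23^2) - m12 * (m12 * m33 - m23 * m13) +
      m13 * (m12 * m23 - m22 * m13)
    det[abs(det) < 1e-300] <- NA
    p1 <- (b1 * (m22 * m33 - m23^2) - m12 * (b2 * m33 - m23 * b3) +
             m13 * (b2 * m23 - m22 * b3)) / det
    p2 <- (m11 * (b2 * m33 - b3 * m23) - b1 * (m12 * m33 - m23 * m13) +
             m13 * (m12 * b3 - b2 * m13)) / det
    p3 <- (m11 * (m22 * b3 - m23 * b2) - m12 * (m12 * b3 - b2 * m13) +
             b1 * (m12 * m23 - m22 * m13)) / det
    list(p1 = p1, p2 = p2, p3 = p3)
  }
  wrss_of <- function(p) {
    pmax(Syy - 2 * (p$p1 * r1 + p$p2 * r2 + p$p3 * r3) +
      (p$p1^2 * Saa + p$p2^2 * Sbb + p$p3^2 * Scc
       - 2 * p$p1 * p$p2 * Sab + 2 * p$p1 * p$p3 * Sac - 2 * p$p2 * p$p3 * Sbc), 0)
  }

  first <- solve3(Saa, -Sab, Sac, Sbb, -Sbc, Scc, r1, r2, r3)
  # flat (all-zero) voxels are exactly determined: no signal, no parameters
  flat <- Syy == 0
  for (nm in names(first)) first[[nm]][flat] <- 0
  wrss1 <- wrss_of(first)
  wrss1[flat] <- 0
  fin <- is.finite(first$p1) & is.finite(first$p2) & is.finite(first$p3)

  use_ridge <- !(is.numeric(h) && h == 0)
  if (use_ridge) {
    sigma <- fwhm_voxels / (2 * sqrt(2 * log(2)))
    # smoothing weights cover only voxels with a finite first pass, so a
    # rare singular voxel cannot poison the spatial prior
    smooth_masked <- function(v) {
      full <- array(0, geom$shape); full[idx[fin]] <- v[fin]
      msk <- array(0, geom$shape); msk[idx[fin]] <- 1
      num <- smooth_gaussian(full, sigma)
      den <- smooth_gaussian(msk, sigma)
      (num / pmax(den, 1e-12))[idx]
    }
    Ps <- lapply(first, smooth_masked)
    locvar <- lapply(names(first), function(nm) {
      m2 <- smooth_masked(first[[nm]]^2)
      pmax(m2 - Ps[[nm]]^2, 0)
    })
    names(locvar) <- names(first)
    eps <- 1e-6
    hh <- if (is.numeric(h)) lapply(first, function(z) rep(h, length(z)))
          else lapply(locvar, function(v) wrss1 / (v + eps))
    second <- solve3(Saa + hh$p1, -Sab, Sac, Sbb + hh$p2, -Sbc, Scc + hh$p3,
                     r1 + hh$p1 * Ps$p1, r2 + hh$p2 * Ps$p2, r3 + hh$p3 * Ps$p3)
    est <- second
    wrss <- wrss_of(second)
    for (nm in names(est)) est[[nm]][flat] <- 0
    wrss[flat] <- 0
  } else {
    est <- first
    wrss <- wrss1
  }

  k2 <- pmin(pmax(est$p2, 0), 10)
  Vb <- pmin(pmax(est$p3, 0), 1)
  K1 <- pmin(pmax(est$p1 - k2 * Vb, 0), 10)
  mk <- function(v, nm, un) {
    arr <- array(NA_real_, geom$shape); arr[idx] <- v
    parametric_map(nm, arr, un, geom)
  }
  list(K1 = mk(K1, "K1", "1/min"), k2 = mk(k2, "k2", "1/min"),
       Vb = mk(Vb, "Vb", "fraction"), wrss = mk(wrss, "wrss", "kBq^2/mL^2"))
}

#' Convert a K1 map into cerebral blood flow
#'
#' `CBF = K1 / E * 100` (mL/100 g/min, tissue density 1 g/mL), with the
#' first-pass extraction fraction of water `E` fixed at 0.85 by default.
#' `E = 1` reports K1 itself in per-100-g units.
#'
#' @param K1_map a [parametric_map()] of K1 (1/min).
#' @param extraction_fraction `E`, in `(0, 1]`.
#' @return A [parametric_map()] named `"CBF"`.
#' @export
flow_map <- function(K1_map, extraction_fraction = 0.85) {
  if (extraction_fraction <= 0) stop("extraction fraction must be positive")
  parametric_map("CBF", K1_map$data / extraction_fraction * 100,
                 "mL/100g/min", K1_map$geometry)
}

#' Normalize a parametric map by a reference-region mean
#'
#' @param map a [parametric_map()].
#' @param reference_mean positive scalar (e.g. cerebellar gray matter mean).
#' @return A [parametric_map()] with `_norm` appended to the name.
#' @export
normalize_map <- function(map, reference_mean) {
  if (!is.finite(reference_mean) || reference_mean <= 0)
    stop("reference mean must be positive")
  parametric_map(paste0(map$name, "_norm"), map$data / reference_mean,
                 "ratio", map$geometry)
}
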