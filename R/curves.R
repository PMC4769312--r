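#' Arterial blood curve
#'
#' Sampled arterial activity concentration.  Times are stored in minutes on
#' the kinetic time axis; values in kBq/mL.  Inputs are assumed
#' decay-corrected to injection time (the flag is carried, no correction is
#' applied).
#'
#' @param time_min strictly increasing sample times (min), first >= 0.
#' @param value activity concentration (kBq/mL), finite and non-negative.
#' @param decay_corrected logical flag recorded with the curve.
#' @return Object of class `blood_curve`.
#' @export
blood_curve <- function(time_min, value, decay_corrected = TRUE) {
  time_min <- as.numeric(time_min)
  value <- as.numeric(value)
  if (length(time_min) != length(value)) stop("time and value lengths differ")
  if (length(time_min) < 3) stop("a blood curve needs at least 3 samples")
  if (any(!is.finite(time_min)) || any(!is.finite(value)))
    stop("blood curve values must be finite")
  if (any(value < 0)) stop("negative activity concentration")
  if (time_min[1] < 0) stop("times must start at >= 0")
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing")
  structure(list(time_min = time_min, value = value,
                 decay_corrected = isTRUE(decay_corrected)),
            class = "blood_curve")
}

#' @export
print.blood_curve <- function(x, ...) {
  cat("blood_curve:", length(x$time_min), "samples,",
      signif(x$time_min[1], 4), "-", signif(max(x$time_min), 4), "min, peak",
      signif(max(x$value), 4), "kBq/mL\n")
  invisible(x)
}

#' Tissue time-activity curve
#'
#' Frame-domain tissue curve: values at frame mid-times with per-frame fit
#' weights (default proportional to frame duration).
#'
#' @param time_min frame mid-times (min).
#' @param value activity concentration (kBq/mL).
#' @param weight non-negative fit weights, not all zero.  Default 1.
#' @return Object of class `tissue_curve`.
#' @export
tissue_curve <- function(time_min, value, weight = NULL) {
  time_min <- as.numeric(time_min)
  value <- as.numeric(value)
  if (is.null(weight)) weight <- rep(1, length(time_min))
  weight <- as.numeric(weight)
  if (length(time_min) != length(value) || length(value) != length(weight))
    stop("time, value and weight must have equal length")
  if (any(weight < 0) || all(weight == 0))
    stop("weights must be >= 0 and not all zero")
  structure(list(time_min = time_min, value = value, weight = weight),
            class = "tissue_curve")
}

#' @export
print.tissue_curve <- function(x, ...) {
  cat("tissue_curve:", length(x$time_min), "frames,",
      signif(x$time_min[1], 4), "-", signif(max(x$time_min), 4), "min\n")
  invisible(x)
}

# kinetic fine grid step (min); all convolutions are evaluated on this grid
FINE_DT <- 0.01

fine_grid <- function(t_max_min, dt = FINE_DT) seq(0, t_max_min + dt / 2, by = dt)

# linear interpolation onto the fine grid; zero before the first sample,
# last value held beyond the last sample (callers validate coverage).
interp_to_grid <- function(time_min, value, grid) {
  stats::approx(time_min, value, xout = grid, method = "linear",
                yleft = 0, rule = 2)$y
}

#' @keywords internal
blood_on_grid <- function(input, grid) interp_to_grid(input$time_min, input$value, grid)

# Convolution with a decaying exponential, y(t) = int_0^t f(s) e^{-k (t-s)} ds,
# exact for piecewise-linear f on a uniform grid (exponential integrator).
exp_conv <- function(f, k, dt) {
  n <- length(f)
  if (n == 0) return(numeric(0))
  if (k < 0) stop("rate constant must be >= 0")
  if (k * dt < 1e-12) {
    # plain cumulative trapezoid
    y <- c(0, cumsum((f[-n] + f[-1]) / 2 * dt))
    return(y)
  }
  E <- exp(-k * dt)
  A <- (1 - (1 + k * dt) * E) / (k^2 * dt)  # weight of f[i]
  B <- (1 - E) / k - A                      # weight of f[i+1]
  z <- A * f[-n] + B * f[-1]
  c(0, as.numeric(stats::filter(z, E, method = "recursive")))
}

# cumulative trapezoid integral of f on a uniform grid
cum_trapz <- function(f, dt) {
  n <- length(f)
  c(0, cumsum((f[-n] + f[-1]) / 2 * dt))
}

#' Average a continuous curve over acquisition frames
#'
#' Converts a model curve evaluated on the fine kinetic grid into the
#' frame-domain signal a scanner measures: each frame value is the mean of the
#' continuous curve over `[start, start + duration]`.  Fit weights are set
#' proportional to frame duration.
#'
#' @param values curve values on `grid`.
#' @param grid uniform fine time grid (min) covering the schedule.
#' @param schedule a [frame_schedule()].
#' @return A [tissue_curve()] at frame mid-times.
#' @export
frame_average <- function(values, grid, schedule) {
  stopifnot(length(values) == length(grid))
  t0 <- schedule$start_s / 60
  t1 <- (schedule$start_s + schedule$duration_s) / 60
  if (max(t1) > max(grid) + 1e-9) stop("fine grid does not cover the schedule")
  dt <- grid[2] - grid[1]
  ci <- cum_trapz(values, dt)
  at <- function(t) stats::approx(grid, ci, xout = t, rule = 2)$y
  v <- (at(t1) - at(t0)) / (t1 - t0)
  tissue_curve(frame_mid_times(schedule), v, weight = schedule$duration_s / 60)
}
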