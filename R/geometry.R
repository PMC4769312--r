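#' Volume geometry
#'
#' Bundles the voxel grid shape, the physical voxel size and the voxel-to-world
#' affine of an image volume.  All internal field arithmetic in the package is
#' carried out in voxel units of the fixed image; the affine is only used when
#' reading and writing NIfTI files.
#'
#' @param shape integer vector of voxels per axis (length 2 or 3).
#' @param voxel_size physical size of a voxel per axis in mm; recycled to the
#'   length of `shape`.
#' @param affine voxel-to-world map, a `(d+1) x (d+1)` homogeneous matrix.
#'   Defaults to a scaling by `voxel_size`.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(shape, voxel_size = 1, affine = NULL) {
  shape <- as.integer(shape)
  d <- length(shape)
  if (!d %in% c(2L, 3L)) stop("shape must have length 2 or 3")
  if (any(shape <= 0L)) stop("shape must be positive integers")
  voxel_size <- rep_len(as.numeric(voxel_size), d)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be strictly positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == d + 1) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be an invertible (d+1) x (d+1) matrix")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat("volume_geometry:", paste(x$shape, collapse = " x "),
      "voxels,", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
format.volume_geometry <- function(x, ...)
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(signif(x$voxel_size, 3), collapse = "x"), "mm")

same_geometry <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$affine - b$affine)) < tol
}

stopifnot_same_geometry <- function(a, b) {
  if (!same_geometry(a, b)) stop("volume geometries do not match")
  invisible(TRUE)
}

#' PET frame schedule
#'
#' Frame start times and durations of a dynamic acquisition, stored in
#' seconds.  Frames must be non-overlapping with non-decreasing starts.
#'
#' @param start_s numeric vector of frame start times (s).
#' @param duration_s numeric vector of frame durations (s), all positive.
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(start_s, duration_s) {
  start_s <- as.numeric(start_s)
  duration_s <- as.numeric(duration_s)
  if (length(start_s) != length(duration_s))
    stop("start_s and duration_s must have equal length")
  if (any(!is.finite(start_s)) || any(!is.finite(duration_s)))
    stop("frame times must be finite")
  if (any(duration_s <= 0)) stop("frame durations must be positive")
  if (is.unsorted(start_s)) stop("frame starts must be non-decreasing")
  ends <- start_s + duration_s
  if (length(start_s) > 1 &&
      any(start_s[-1] < ends[-length(ends)] - 1e-9))
    stop("frames overlap")
  structure(list(start_s = start_s, duration_s = duration_s),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$start_s)

#' @export
print.frame_schedule <- function(x, ...) {
  cat("frame_schedule:", length(x), "frames spanning",
      signif(x$start_s[1], 4), "-",
      signif(max(x$start_s + x$duration_s), 4), "s\n")
  invisible(x)
}

#' Frame mid-times
#'
#' @param x a `frame_schedule`.
#' @param unit `"min"` (default, the kinetic time axis) or `"s"`.
#' @return Numeric vector of frame mid-times `start + duration/2`.
#' @export
frame_mid_times <- function(x, unit = c("min", "s")) {
  unit <- match.arg(unit)
  mid <- x$start_s + x$duration_s / 2
  if (unit == "min") mid / 60 else mid
}

#' Canned acquisition protocols
#'
#' Frame schedules for the 10-min water protocol
#' (6 x 5 s, 9 x 10 s, 6 x 30 s, 5 x 60 s; 26 frames) and the 65-min FDDNP
#' protocol (6 x 30 s, 4 x 180 s, 10 x 300 s; 20 frames), plus the 15-point
#' arterial sampling times (0, 5 x 12, 3 x 20, 2 x 30, 2 x 60, 2 x 150 s).
#'
#' @param protocol one of `"water"`, `"fddnp"`.
#' @return A `frame_schedule`.
#' @export
standard_schedule <- function(protocol = c("water", "fddnp")) {
  protocol <- match.arg(protocol)
  dur <- switch(protocol,
    water = c(rep(5, 6), rep(10, 9), rep(30, 6), rep(60, 5)),
    fddnp = c(rep(30, 6), rep(180, 4), rep(300, 10)))
  frame_schedule(cumsum(c(0, dur[-length(dur)])), dur)
}

#' @rdname standard_schedule
#' @export
arterial_sample_times_s <- function() {
  cumsum(c(0, rep(12, 5), rep(20, 3), rep(30, 2), rep(60, 2), rep(150, 2)))
}
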