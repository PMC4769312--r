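#' Dynamic PET image
#'
#' A frame-indexed stack of activity-concentration volumes (kBq/mL) together
#' with its grid geometry and frame schedule.  The last array dimension is the
#' frame index.
#'
#' @param data numeric array; last dimension indexes frames.
#' @param geometry a [volume_geometry()] for a single frame.
#' @param schedule a [frame_schedule()] with one row per frame.
#' @return Object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, geometry, schedule) {
  data <- as.array(data)
  nd <- length(dim(data))
  if (nd != length(geometry$shape) + 1)
    stop("data must have one more dimension than the geometry")
  if (!all(dim(data)[-nd] == geometry$shape))
    stop("frame shape does not match geometry")
  if (dim(data)[nd] != length(schedule))
    stop("number of frames differs from the schedule length")
  structure(list(data = data, geometry = geometry, schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat("dynamic_image:", format(x$geometry), ",", length(x$schedule), "frames\n")
  invisible(x)
}

n_frames <- function(img) length(img$schedule)

frame_data <- function(img, f) {
  d <- dim(img$data)
  nd <- length(d)
  idx <- c(rep(list(quote(expr = )), nd - 1), list(f))
  array(do.call(`[`, c(list(img$data), idx)), d[-nd])
}

#' Parametric map
#'
#' Per-voxel estimates of one named kinetic parameter.  Voxels outside the fit
#' mask carry `NA`.
#'
#' @param name parameter identifier, e.g. `"K1"`, `"CBF"`, `"R_I"`.
#' @param data numeric array matching `geometry$shape`.
#' @param units unit string, e.g. `"1/min"`, `"mL/100g/min"`.
#' @param geometry a [volume_geometry()].
#' @return Object of class `parametric_map`.
#' @export
parametric_map <- function(name, data, units, geometry) {
  data <- as.array(data)
  if (!all(dim(data) == geometry$shape))
    stop("map shape does not match geometry")
  structure(list(name = name, data = data, units = units, geometry = geometry),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  v <- x$data[is.finite(x$data)]
  cat("parametric_map", x$name, "[", x$units, "]:", format(x$geometry), "\n")
  if (length(v))
    cat("  fitted voxels:", length(v), " median:", signif(stats::median(v), 4), "\n")
  invisible(x)
}

geometry_from_nifti <- function(img) {
  d <- dim(img)
  nd <- min(length(d), 3L)
  shape <- d[seq_len(nd)]
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- rep(1, nd)
  aff <- tryCatch(structure(RNifti::xform(img), dimnames = NULL),
                  error = function(e) NULL)
  if (is.null(aff) || nrow(aff) != 4) aff <- diag(4)
  if (nd == 2L) aff <- aff[c(1, 2, 4), c(1, 2, 4)]
  volume_geometry(shape, rep_len(pix, nd), aff)
}

nifti_with_geometry <- function(data, geometry) {
  d <- length(geometry$shape)
  aff <- geometry$affine
  if (d == 2L) {  # embed the 2-D affine in a 4x4 map for NIfTI
    a4 <- diag(4)
    a4[c(1, 2), c(1, 2)] <- aff[1:2, 1:2]
    a4[c(1, 2), 4] <- aff[1:2, 3]
    aff <- a4
  }
  img <- RNifti::asNifti(data)
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Save a volume as NIfTI-1
#'
#' Integer-valued arrays (label volumes) survive a save/load roundtrip
#' bit-exactly; floating point data within 1e-6.
#'
#' @param data array matching `geometry$shape` (one extra trailing dimension
#'   allowed for multi-frame / multi-component data).
#' @param geometry a [volume_geometry()].
#' @param path output file (`.nii` / `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(data, geometry, path) {
  data <- as.array(data)
  nd <- length(dim(data))
  d <- length(geometry$shape)
  if (!(nd == d || nd == d + 1) || !all(dim(data)[seq_len(d)] == geometry$shape))
    stop("data shape does not match geometry")
  RNifti::writeNifti(nifti_with_geometry(data, geometry), path)
  invisible(path)
}

#' Load a 3-D (or 2-D) volume from NIfTI
#'
#' @param path NIfTI file.
#' @return list with `data` (array) and `geometry`.
#' @export
load_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = array(as.numeric(img), dim(img)), geometry = geometry_from_nifti(img))
}

#' Load a dynamic PET series with its frame-timing sidecar
#'
#' The image is a 4-D (or 3-D for planar data) NIfTI; the sidecar is a TSV
#' with columns `frame_start_s` and `frame_duration_s`, one row per frame.
#'
#' @param image_path NIfTI file with frames in the last dimension.
#' @param timing_path TSV sidecar.
#' @return A [dynamic_image()].
#' @export
load_dynamic_image <- function(image_path, timing_path) {
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  tab <- utils::read.delim(timing_path, sep = "\t")
  if (!all(c("frame_start_s", "frame_duration_s") %in% names(tab)))
    stop("timing table needs columns frame_start_s, frame_duration_s")
  sched <- frame_schedule(tab$frame_start_s, tab$frame_duration_s)
  if (d[length(d)] != length(sched))
    stop(sprintf("image has %d frames but timing table has %d rows",
                 d[length(d)], length(sched)))
  geom <- geometry_from_nifti(img)
  # geometry covers the spatial dims only
  if (length(d) - 1 == 2 && length(geom$shape) == 3)
    geom <- volume_geometry(d[1:2], geom$voxel_size[1:2])
  dynamic_image(array(as.numeric(img), d), geom, sched)
}

#' Save a dynamic image plus timing sidecar
#'
#' @param img a [dynamic_image()].
#' @param image_path,timing_path output paths.
#' @return `image_path`, invisibly.
#' @export
save_dynamic_image <- function(img, image_path, timing_path) {
  save_volume(img$data, img$geometry, image_path)
  utils::write.table(
    data.frame(frame_start_s = img$schedule$start_s,
               frame_duration_s = img$schedule$duration_s),
    timing_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(image_path)
}

#' Load an arterial blood curve from TSV
#'
#' Expects columns `time` and `activity_kBq_mL`; the time unit is declared by
#' naming the column `time_s` or `time_min`.  Times are converted to minutes
#' and sorted; duplicate times are rejected.
#'
#' @param path TSV file.
#' @param decay_corrected recorded flag, default `TRUE`.
#' @return A [blood_curve()].
#' @export
load_blood_curve <- function(path, decay_corrected = TRUE) {
  tab <- utils::read.delim(path, sep = "\t")
  tcol <- intersect(c("time_s", "time_min"), names(tab))
  if (length(tcol) != 1 || !"activity_kBq_mL" %in% names(tab))
    stop("blood TSV needs columns time_s or time_min, and activity_kBq_mL")
  tm <- tab[[tcol]]
  if (tcol == "time_s") tm <- tm / 60
  o <- order(tm)
  tm <- tm[o]
  if (anyDuplicated(tm)) stop("duplicate sample times")
  blood_curve(tm, tab$activity_kBq_mL[o], decay_corrected)
}

#' Save a blood curve as TSV (times in seconds)
#'
#' @param curve a [blood_curve()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
save_blood_curve <- function(curve, path) {
  utils::write.table(
    data.frame(time_s = curve$time_min * 60, activity_kBq_mL = curve$value),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Integrate a dynamic image over a time window
#'
#' Duration-weighted sum (a time integral, units kBq.min/mL) over the frames
#' whose mid-time lies in `[window_start_min, window_end_min)`.  Used to build
#' the early-summed images that drive rigid co-registration and the
#' relative-perfusion ratio map.
#'
#' @param img a [dynamic_image()].
#' @param window_start_min,window_end_min window bounds in minutes.
#' @return A numeric array of the spatial shape.
#' @export
integrate_frames <- function(img, window_start_min, window_end_min) {
  if (window_end_min <= window_start_min) stop("empty integration window")
  mid <- frame_mid_times(img$schedule)
  sel <- which(mid >= window_start_min & mid < window_end_min)
  if (!length(sel)) stop("integration window contains no frame mid-times")
  d <- dim(img$data)
  nd <- length(d)
  out <- array(0, d[-nd])
  for (f in sel)
    out <- out + frame_data(img, f) * (img$schedule$duration_s[f] / 60)
  out
}
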