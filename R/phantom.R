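# Deterministic digital brain phantom: labelled geometry, arterial input,
# frame-averaged noisy dynamic PET for both tracers, smooth invertible
# deformations and focal lesions.  The forward curves reuse the same model
# evaluators the estimators invert (one_tissue / SRTM), so recovery tests
# close the loop without duplicating model code.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

ellipse_mask <- function(shape, center, radii) {
  co <- grid_coords(shape)
  acc <- 0
  for (k in seq_along(shape))
    acc <- acc + ((co[[k]] - center[k]) / radii[k])^2
  acc <= 1
}

sector_of <- function(shape, center) {
  co <- grid_coords(shape)
  atan2(co[[2]] - center[2], co[[1]] - center[1])
}

#' Default phantom specification
#'
#' A 2-D 128 x 128 brain-like slice: an elliptical cerebrum with a cortical
#' gray shell split into four lobar sectors (FRT, PAR, TEMP, OCC), a white
#' matter core (SWM, the centrum-semiovale stand-in), eight subcortical gray
#' blobs (AMY, HIPP, PHIP, CAU, PUT, PALL, THAL, INS), a central ventricle,
#' and a separate cerebellar patch (CGM, the reference region).  Kinetic
#' parameters per region: water one-tissue (K1 from CBF 33 mL/100g/min in all
#' 13 gray regions and 20 in white, extraction fraction 0.85) and FDDNP SRTM
#' (relative delivery tracking the flow ratio to CGM, low binding in the
#' reference).
#'
#' @param shape grid shape, default `c(128, 128)`.
#' @param noise_percent proportional noise level of the dynamic data.
#' @param seed integer seed fixing all phantom randomness.
#' @param gray_cbf,white_cbf generating flows (mL/100 g/min).
#' @param extraction_fraction water first-pass extraction used to map flow to
#'   K1.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128), noise_percent = 0, seed = 1,
                         gray_cbf = 33, white_cbf = 20,
                         extraction_fraction = 0.85) {
  k1_of <- function(cbf) extraction_fraction * cbf / 100
  gray_water <- list(K1 = k1_of(gray_cbf), k2 = k1_of(gray_cbf) / 0.9, Vb = 0.04)
  white_water <- list(K1 = k1_of(white_cbf), k2 = k1_of(white_cbf) / 0.9, Vb = 0.02)
  r_i_white <- white_cbf / gray_cbf
  gray_fddnp <- list(R_I = 1.0, k2 = 0.40, BP = 0.20)
  white_fddnp <- list(R_I = r_i_white, k2 = 0.35, BP = 0.30)
  ctr <- shape / 2 + c(0, 14)
  blob_angles <- seq(0, 2 * pi, length.out = 9)[-9]
  blob_names <- c("AMY", "HIPP", "PHIP", "CAU", "PUT", "PALL", "THAL", "INS")
  regions <- list()
  sector_names <- c("FRT", "PAR", "TEMP", "OCC")
  for (i in seq_along(sector_names))
    regions[[sector_names[i]]] <- list(
      type = "shell_sector", sector = i, intensity = 80,
      water = gray_water, fddnp = gray_fddnp)
  for (i in seq_along(blob_names)) {
    cen <- ctr + 20 * c(cos(blob_angles[i]), sin(blob_angles[i])) * c(1, 0.9)
    regions[[blob_names[i]]] <- list(
      type = "ellipse", center = cen, radii = c(4.5, 4.5), intensity = 85,
      water = gray_water, fddnp = gray_fddnp)
  }
  regions$CGM <- list(type = "cerebellum", intensity = 80,
                      water = modifyList(gray_water, list()),
                      fddnp = list(R_I = 1, k2 = 0.40, BP = 0),
                      fddnp_ref = list(K1 = 0.30, k2 = 0.12, Vb = 0.04))
  regions$SWM <- list(type = "core", intensity = 110,
                      water = white_water, fddnp = white_fddnp)
  regions$VENT <- list(type = "ellipse", center = ctr, radii = c(9, 7),
                       intensity = 30, reporting = FALSE,
                       water = list(K1 = 0.02, k2 = 0.05, Vb = 0.01),
                       fddnp = list(R_I = 0.1, k2 = 0.3, BP = 0))
  structure(list(shape = as.integer(shape), noise_percent = noise_percent,
                 seed = seed, regions = regions,
                 center = ctr,
                 cerebrum = list(center = ctr, radii = c(46, 42)),
                 core = list(center = ctr, radii = c(36, 32)),
                 cerebellum = list(center = c(shape[1] / 2, 17),
                                   radii = c(26, 11)),
                 extraction_fraction = extraction_fraction),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("phantom_spec:", paste(x$shape, collapse = "x"), ",",
      length(x$regions), "regions, noise", x$noise_percent, "%, seed", x$seed, "\n")
  invisible(x)
}

region_ids <- function(spec) {
  nm <- names(spec$regions)
  stats::setNames(seq_along(nm), nm)
}

#' The phantom's reporting region set
#'
#' The 14 reporting regions (13 gray including the cerebellar reference, plus
#' white matter); the ventricle is excluded from reporting.
#'
#' @param spec a [phantom_spec()].
#' @return A [region_set()].
#' @export
phantom_region_set <- function(spec = phantom_spec()) {
  ids <- region_ids(spec)
  rep_names <- names(ids)[names(ids) != "VENT"]
  region_set(as.list(ids[rep_names]),
             gray_regions = setdiff(rep_names, "SWM"))
}

#' Build the phantom label volume and structural image
#'
#' Paints the labelled geometry of `spec` and a structural image made of
#' per-region constant intensities, a smooth multiplicative bias field, and
#' seeded Gaussian noise at `spec$noise_percent`.
#'
#' @param spec a [phantom_spec()].
#' @return List: `labels` ([label_volume()]), `structural` (array),
#'   `geometry`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  shape <- spec$shape
  geom <- volume_geometry(shape, c(1.5, 1.5))
  ids <- region_ids(spec)
  lab <- array(0L, shape)
  cer <- ellipse_mask(shape, spec$cerebrum$center, spec$cerebrum$radii)
  core <- ellipse_mask(shape, spec$core$center, spec$core$radii)
  shell <- cer & !core
  ang <- sector_of(shape, spec$cerebrum$center)
  sector_idx <- findInterval(ang, c(-pi, -pi / 2, 0, pi / 2, pi),
                             rightmost.closed = TRUE)
  cereb <- ellipse_mask(shape, spec$cerebellum$center, spec$cerebellum$radii)
  # pairwise overlap check for declared ellipse primitives
  blobs <- Filter(function(r) r$type == "ellipse" && is.null(r$reporting),
                  spec$regions)
  if (length(blobs) > 1) {
    cs <- t(vapply(blobs, function(b) b$center, numeric(2)))
    rs <- t(vapply(blobs, function(b) b$radii, numeric(2)))
    for (i in seq_len(nrow(cs) - 1)) for (j in (i + 1):nrow(cs)) {
      if (sqrt(sum((cs[i, ] - cs[j, ])^2)) < max(rs[i, ]) + max(rs[j, ]))
        stop("overlapping phantom primitives: ",
             names(blobs)[i], " and ", names(blobs)[j])
    }
  }
  # painting order: shell, core, cerebellum, then focal blobs on top
  prio <- c(shell_sector = 1, core = 2, cerebellum = 3, ellipse = 4)
  paint_order <- names(spec$regions)[order(prio[vapply(spec$regions,
                                                       `[[`, "", "type")])]
  for (nm in paint_order) {
    r <- spec$regions[[nm]]
    m <- switch(r$type,
      shell_sector = shell & (sector_idx == r$sector),
      ellipse = ellipse_mask(shape, r$center, r$radii),
      cerebellum = cereb,
      core = core,
      stop("unknown primitive type"))
    lab[m] <- ids[[nm]]
  }
  if (any(vapply(names(ids), function(nm) sum(lab == ids[[nm]]) == 0, TRUE)))
    stop("a declared region received no voxels")
  structural <- array(8, shape)  # air background
  for (nm in names(spec$regions))
    structural[lab == ids[[nm]]] <- spec$regions[[nm]]$intensity
  co <- grid_coords(shape)
  # scalp/skull layer: the head is imaged whole (no skull-stripping), and the
  # textured extracranial tissue anchors registration outside the brain
  head <- ellipse_mask(shape, spec$cerebrum$center,
                       spec$cerebrum$radii + c(6, 8)) |
    ellipse_mask(shape, c(shape[1] / 2, shape[2] * 0.23),
                 c(shape[1] * 0.375, shape[2] * 0.2))
  scalp <- head & lab == 0L
  structural[scalp] <- 55 * (1 + 0.3 * sin(2 * pi * co[[1]] / 16) *
                               sin(2 * pi * co[[2]] / 16))[scalp]
  bias <- 1 + 0.08 * sin(2 * pi * co[[1]] / shape[1]) *
               cos(2 * pi * co[[2]] / shape[2])
  structural <- structural * bias
  if (spec$noise_percent > 0) {
    structural <- structural + with_seed(spec$seed + 7,
      array(stats::rnorm(prod(shape)), shape)) *
      (spec$noise_percent / 100) * structural
  }
  lbl_tab <- data.frame(id = unname(ids), name = names(ids))
  list(labels = label_volume(lab, geom, lbl_tab),
       structural = structural, geometry = geom)
}

#' Gamma-variate arterial input
#'
#' `A (t - t0)^alpha exp(-(t - t0)/beta)` for `t > t0` (zero before), plus an
#' optional recirculation tail; peak at `t0 + alpha beta`.  Sampled on the
#' 15-point arterial schedule or on a fine grid.
#'
#' @param A amplitude scale (kBq/mL per min^alpha).
#' @param alpha shape exponent (> 0).
#' @param beta_min time constant (min).
#' @param t0_min appearance time (min).
#' @param recirc_fraction recirculation plateau as a fraction of the peak.
#' @param times_min sample times; default the 15-point arterial schedule.
#' @param fine if `TRUE`, sample on the 0.01-min grid to 10 min instead.
#' @return A [blood_curve()].
#' @export
synth_input <- function(A = 300, alpha = 2, beta_min = 0.2, t0_min = 0.25,
                        recirc_fraction = 0.05, times_min = NULL,
                        fine = FALSE) {
  if (A <= 0 || alpha <= 0 || beta_min <= 0 || t0_min < 0 ||
      recirc_fraction < 0)
    stop("invalid input-shape parameters")
  if (is.null(times_min))
    times_min <- if (fine) fine_grid(10) else arterial_sample_times_s() / 60
  tt <- pmax(times_min - t0_min, 0)
  v <- A * tt^alpha * exp(-tt / beta_min)
  peak <- A * (alpha * beta_min)^alpha * exp(-alpha)
  v <- v + recirc_fraction * peak * (1 - exp(-tt / (2 * beta_min))) *
    exp(-tt / 30)
  v[times_min <= t0_min] <- 0
  blood_curve(times_min, v)
}

#' Degrade an arterial input with delay, dispersion and noise
#'
#' Emulates the measurement chain of arterial sampling: convolve with the
#' monoexponential dispersion kernel `(1/tau) exp(-t/tau)`, delay by
#' `delta_t`, and add seeded proportional Gaussian noise.
#'
#' @param true a [blood_curve()] (the input the brain sees).
#' @param delta_t_s delay (s) added to the measured curve.
#' @param tau_s dispersion time constant (s), >= 0.
#' @param noise_percent proportional noise SD in percent.
#' @param seed RNG seed for the noise.
#' @return A [blood_curve()] sampled at the same times as `true`.
#' @export
degrade_input <- function(true, delta_t_s = 0, tau_s = 0, noise_percent = 0,
                          seed = 1) {
  if (tau_s < 0) stop("tau must be >= 0")
  grid <- fine_grid(max(true$time_min) + abs(delta_t_s) / 60)
  dt <- grid[2] - grid[1]
  v <- interp_to_grid(true$time_min, true$value, grid)
  if (tau_s > 0) v <- exp_conv(v, 60 / tau_s, dt) * 60 / tau_s
  out <- stats::approx(grid, v, xout = true$time_min - delta_t_s / 60,
                       yleft = 0, rule = 2)$y
  if (noise_percent > 0)
    out <- pmax(out + with_seed(seed, stats::rnorm(length(out))) *
                  (noise_percent / 100) * out, 0)
  blood_curve(true$time_min, out)
}

#' Simulate a dynamic PET acquisition over a labelled phantom
#'
#' Evaluates each region's forward model — the one-tissue model against the
#' arterial input for water; the simplified reference tissue model against
#' the reference-region curve for FDDNP, the reference region itself being
#' generated from its own one-tissue parameters — frame-averages the curves
#' onto `schedule`, broadcasts them to the region's voxels, and adds seeded
#' Gaussian noise with per-frame SD
#' `noise_percent/100 * value * sqrt(max duration / frame duration)`,
#' emulating count statistics.
#'
#' @param labels a [label_volume()] (possibly deformed/lesioned).
#' @param spec the generating [phantom_spec()].
#' @param tracer `"water"` or `"fddnp"`.
#' @param input the arterial [blood_curve()] (water) or the pseudo-plasma
#'   curve driving the reference region (fddnp).
#' @param schedule a [frame_schedule()]; defaults to the tracer's protocol.
#' @param noise_percent,seed noise level and seed; default from `spec`.
#' @return A [dynamic_image()]; attribute `region_curves` holds the noiseless
#'   frame-domain curve per region.
#' @export
simulate_dynamic <- function(labels, spec, tracer = c("water", "fddnp"),
                             input, schedule = NULL,
                             noise_percent = spec$noise_percent,
                             seed = spec$seed) {
  tracer <- match.arg(tracer)
  if (is.null(schedule)) schedule <- standard_schedule(tracer)
  ids <- region_ids(spec)
  t_end <- max(schedule$start_s + schedule$duration_s) / 60
  grid <- fine_grid(max(t_end, max(input$time_min)))
  dt <- grid[2] - grid[1]
  cb <- blood_on_grid(input, grid)
  ref_grid <- NULL
  if (tracer == "fddnp") {
    pr <- spec$regions$CGM$fddnp_ref
    ref_grid <- one_tissue_on_grid(pr, cb, dt)
  }
  curves <- list()
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    cont <- if (tracer == "water") {
      one_tissue_on_grid(r$water, cb, dt)
    } else if (nm == "CGM") {
      ref_grid
    } else {
      p <- r$fddnp
      th <- p$k2 / (1 + p$BP)
      p$R_I * ref_grid + (p$k2 - p$R_I * th) * exp_conv(ref_grid, th, dt)
    }
    curves[[nm]] <- frame_average(cont, grid, schedule)$value
  }
  shape <- labels$geometry$shape
  Fn <- length(schedule)
  data <- array(0, c(shape, Fn))
  flat <- matrix(data, ncol = Fn)
  lab <- as.integer(labels$data)
  for (nm in names(curves)) {
    sel <- lab == ids[[nm]]
    if (any(sel)) flat[sel, ] <- rep(curves[[nm]], each = sum(sel))
  }
  if (noise_percent > 0) {
    scale <- sqrt(max(schedule$duration_s) / schedule$duration_s)
    z <- with_seed(seed, matrix(stats::rnorm(length(flat)), nrow(flat)))
    flat <- flat + z * (noise_percent / 100) * flat *
      rep(scale, each = nrow(flat))
  }
  img <- dynamic_image(array(flat, c(shape, Fn)),
                       labels$geometry, schedule)
  attr(img, "region_curves") <- curves
  img
}

# smooth taper to zero at the domain boundary (keeps warps inside the grid)
edge_window <- function(shape, margin = 10) {
  co <- grid_coords(shape)
  w <- 1
  for (k in seq_along(shape)) {
    dist <- pmin(co[[k]] - 1, shape[k] - co[[k]]) / margin
    w <- w * pmin(pmax(dist, 0), 1)^2 * (3 - 2 * pmin(pmax(dist, 0), 1))
  }
  w
}

#' Generate a known smooth invertible deformation
#'
#' Seeded random vectors, Gaussian-smoothed to `smoothness_voxels`, tapered
#' to zero at the boundary and scaled so the largest displacement equals
#' `amplitude_voxels`; the amplitude is reduced (error if by more than 5%) if
#' needed to keep the Jacobian strictly positive.  Returns 25 landmark pairs
#' on an interior 5 x 5 grid for recovery scoring.
#'
#' @param geometry a [volume_geometry()].
#' @param amplitude_voxels requested maximum displacement.
#' @param smoothness_voxels Gaussian sigma of the field.
#' @param seed RNG seed.
#' @return A [deformation_field()]; attribute `landmarks` is a data.frame of
#'   matched point pairs (`x_def`, `y_def` on the deformed grid; `x_src`,
#'   `y_src` in the source image).
#' @export
make_deformation <- function(geometry, amplitude_voxels = 8,
                             smoothness_voxels = 12, seed = 1) {
  shape <- geometry$shape
  d <- length(shape)
  if (amplitude_voxels == 0) {
    f <- zero_field(geometry)
  } else {
    win <- edge_window(shape)
    comps <- with_seed(seed, lapply(seq_len(d), function(k)
      array(stats::rnorm(prod(shape)), shape)))
    comps <- lapply(comps, function(a)
      smooth_gaussian(a, smoothness_voxels) * win)
    mag <- sqrt(Reduce(`+`, lapply(comps, function(a) a^2)))
    comps <- lapply(comps, function(a) a * (amplitude_voxels / max(mag)))
    amp <- amplitude_voxels
    repeat {
      disp <- array(0, c(shape, d))
      for (k in seq_len(d)) {
        idx <- c(rep(list(quote(expr = )), d), list(k))
        disp <- do.call(`[<-`, c(list(disp), idx, list(comps[[k]])))
      }
      f <- deformation_field(disp, geometry)
      if (min(jacobian_determinant(f)) > 0.05) break
      comps <- lapply(comps, `*`, 0.95)
      amp <- amp * 0.95
      if (amp < 0.5 * amplitude_voxels)
        stop("cannot reach a positive Jacobian at this amplitude; ",
             "max feasible about ", signif(amp, 3), " voxels")
    }
  }
  lm <- as.matrix(expand.grid(lapply(shape, function(n)
    round(seq(0.2, 0.8, length.out = 5) * n))))
  pts <- lapply(seq_len(d), function(k) lm[, k])
  uv <- sample_field(f, pts)
  lmk <- data.frame(lm, do.call(cbind, lapply(seq_len(d),
                                              function(k) lm[, k] + uv[[k]])))
  names(lmk) <- c(paste0(c("x", "y", "z")[seq_len(d)], "_def"),
                  paste0(c("x", "y", "z")[seq_len(d)], "_src"))
  attr(f, "landmarks") <- lmk
  f
}

#' Insert an ellipsoidal focal lesion
#'
#' Sets an ellipsoidal region to a (typically atypically high or low)
#' intensity and returns the binary lesion mask.
#'
#' @param volume numeric array.
#' @param center,radii lesion ellipsoid in voxel coordinates; must lie inside
#'   the volume.
#' @param intensity value painted inside the lesion.
#' @return List: `volume` (modified array), `mask` (0/1 array).
#' @export
insert_lesion <- function(volume, center, radii, intensity) {
  shape <- dim(volume)
  if (any(center - radii < 1) || any(center + radii > shape))
    stop("lesion extends outside the volume")
  m <- ellipse_mask(shape, center, radii)
  volume[m] <- intensity
  list(volume = volume, mask = array(as.numeric(m), shape))
}
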