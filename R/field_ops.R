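# Dense displacement fields and the array utilities behind registration.
# All coordinates are R array indices (first voxel at 1); displacements are in
# voxel units of the fixed image grid.

#' Dense deformation field
#'
#' Per-voxel displacement vectors in voxel units.  A field `u` acts on an
#' image `I` by pull-back resampling: `(I o phi)(x) = I(x + u(x))`.
#'
#' @param disp numeric array of shape `c(shape, d)` (last dimension = vector
#'   component).
#' @param geometry a [volume_geometry()].
#' @return Object of class `deformation_field`.
#' @export
deformation_field <- function(disp, geometry) {
  disp <- as.array(disp)
  d <- length(geometry$shape)
  if (length(dim(disp)) != d + 1 || !all(dim(disp)[seq_len(d)] == geometry$shape) ||
      dim(disp)[d + 1] != d)
    stop("displacement array must have shape c(shape, d)")
  if (any(!is.finite(disp))) stop("displacements must be finite")
  structure(list(disp = disp, geometry = geometry), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$disp, ncol = dim(x$disp)[length(dim(x$disp))])^2))
  cat("deformation_field:", format(x$geometry),
      ", mean |u| =", signif(mean(mag), 4),
      ", max |u| =", signif(max(mag), 4), "voxels\n")
  invisible(x)
}

zero_field <- function(geometry)
  deformation_field(array(0, c(geometry$shape, length(geometry$shape))), geometry)

field_component <- function(f, k) {
  d <- dim(f$disp)
  nd <- length(d)
  idx <- c(rep(list(quote(expr = )), nd - 1), list(k))
  array(do.call(`[`, c(list(f$disp), idx)), d[-nd])
}

field_magnitude <- function(f) {
  d <- length(f$geometry$shape)
  m2 <- 0
  for (k in seq_len(d)) m2 <- m2 + field_component(f, k)^2
  sqrt(m2)
}

grid_coords <- function(shape) {
  d <- length(shape)
  if (d == 2) {
    list(matrix(rep(seq_len(shape[1]), shape[2]), shape[1]),
         matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1]))
  } else {
    n <- prod(shape)
    i <- array(seq_len(shape[1]), shape)
    j <- array(rep(seq_len(shape[2]), each = shape[1]), shape)
    k <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
    list(i, j, k)
  }
}

# ---- n-linear interpolation --------------------------------------------------

# vectorized bilinear / trilinear sampling of `arr` at fractional coordinates.
# clamp = TRUE extends the array by its edge values (used for fields);
# otherwise points outside the domain evaluate to `fill`.
interp_linear <- function(arr, coords, fill = 0, clamp = FALSE) {
  dm <- dim(arr)
  d <- length(dm)
  n <- length(coords[[1]])
  if (clamp) {
    for (k in seq_len(d)) coords[[k]] <- pmin(pmax(coords[[k]], 1), dm[k])
    inside <- TRUE
  } else {
    inside <- rep(TRUE, n)
    for (k in seq_len(d))
      inside <- inside & coords[[k]] >= 1 & coords[[k]] <= dm[k]
    for (k in seq_len(d)) coords[[k]] <- pmin(pmax(coords[[k]], 1), dm[k])
  }
  lo <- list(); fr <- list()
  for (k in seq_len(d)) {
    l <- pmin(floor(coords[[k]]), dm[k] - 1)
    l <- pmax(l, 1)
    lo[[k]] <- l
    fr[[k]] <- coords[[k]] - l
  }
  if (d == 2) {
    i0 <- lo[[1]]; j0 <- lo[[2]]; fx <- fr[[1]]; fy <- fr[[2]]
    n1 <- dm[1]
    b <- (j0 - 1) * n1
    v00 <- arr[i0 + b];      v10 <- arr[i0 + 1 + b]
    v01 <- arr[i0 + b + n1]; v11 <- arr[i0 + 1 + b + n1]
    out <- (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
           (1 - fx) * fy * v01 + fx * fy * v11
  } else {
    i0 <- lo[[1]]; j0 <- lo[[2]]; k0 <- lo[[3]]
    fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
    n1 <- dm[1]; n12 <- dm[1] * dm[2]
    b <- (j0 - 1) * n1 + (k0 - 1) * n12
    g <- function(di, dj, dk) arr[i0 + di + b + dj * n1 + dk * n12]
    out <- (1 - fx) * (1 - fy) * (1 - fz) * g(0, 0, 0) +
           fx * (1 - fy) * (1 - fz) * g(1, 0, 0) +
           (1 - fx) * fy * (1 - fz) * g(0, 1, 0) +
           fx * fy * (1 - fz) * g(1, 1, 0) +
           (1 - fx) * (1 - fy) * fz * g(0, 0, 1) +
           fx * (1 - fy) * fz * g(1, 0, 1) +
           (1 - fx) * fy * fz * g(0, 1, 1) +
           fx * fy * fz * g(1, 1, 1)
  }
  if (!clamp) out[!inside] <- fill
  out
}

interp_nearest <- function(arr, coords, fill = 0) {
  dm <- dim(arr)
  d <- length(dm)
  n <- length(coords[[1]])
  inside <- rep(TRUE, n)
  idx <- 0
  mult <- 1
  for (k in seq_len(d)) {
    r <- round(coords[[k]])
    inside <- inside & r >= 1 & r <= dm[k]
    r <- pmin(pmax(r, 1), dm[k])
    idx <- idx + (r - 1) * mult
    mult <- mult * dm[k]
  }
  out <- arr[idx + 1]
  out[!inside] <- fill
  out
}

# sample a displacement field at fractional points; edge-clamped
sample_field <- function(f, coords) {
  d <- length(f$geometry$shape)
  lapply(seq_len(d), function(k)
    interp_linear(field_component(f, k), coords, clamp = TRUE))
}

# ---- separable filters -------------------------------------------------------

# apply an n x n banded operator along dimension `along` of an array
apply_along <- function(arr, op, along) {
  dm <- dim(arr)
  d <- length(dm)
  perm <- c(along, setdiff(seq_len(d), along))
  a <- aperm(arr, perm)
  m <- op(matrix(a, dm[along]))
  a <- array(m, dm[perm])
  aperm(a, order(perm))
}

gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(NULL)
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  kv <- exp(-off^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1 & j <= n
    K[i, j[ok]] <- kv[ok] / sum(kv[ok])  # renormalized at the edges
  }
  K
}

#' Gaussian smoothing of an array (separable, edge-renormalized)
#'
#' @param arr 2-D or 3-D numeric array.
#' @param sigma standard deviation in voxels; `0` returns the input.
#' @return Smoothed array of the same shape.
#' @export
smooth_gaussian <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  dm <- dim(arr)
  Ks <- lapply(dm, gauss_kernel_matrix, sigma = sigma)
  for (k in seq_along(dm))
    arr <- apply_along(arr, function(m) Ks[[k]] %*% m, k)
  arr
}

smooth_field <- function(f, sigma) {
  if (sigma <= 0) return(f)
  d <- length(f$geometry$shape)
  disp <- f$disp
  for (k in seq_len(d)) {
    comp <- smooth_gaussian(field_component(f, k), sigma)
    idx <- c(rep(list(quote(expr = )), d), list(k))
    disp <- do.call(`[<-`, c(list(disp), idx, list(comp)))
  }
  deformation_field(disp, f$geometry)
}

# moving-window (box) sum with truncated windows at the edges, via cumsums
box_sum <- function(arr, r) {
  box1 <- function(m) {
    n <- nrow(m)
    cs <- rbind(0, apply(m, 2, cumsum))
    hi <- pmin(seq_len(n) + r, n) + 1
    lo <- pmax(seq_len(n) - r, 1)
    cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  for (k in seq_along(dim(arr))) arr <- apply_along(arr, box1, k)
  arr
}

# central-difference spatial gradient (one-sided at the edges)
gradient_arrays <- function(arr) {
  diff1 <- function(m) {
    n <- nrow(m)
    if (n == 1) return(m * 0)
    g <- m
    g[2:(n - 1), ] <- (m[3:n, , drop = FALSE] - m[1:(n - 2), , drop = FALSE]) / 2
    g[1, ] <- m[2, ] - m[1, ]
    g[n, ] <- m[n, ] - m[n - 1, ]
    g
  }
  lapply(seq_along(dim(arr)), function(k) apply_along(arr, diff1, k))
}

# ---- rigid transforms --------------------------------------------------------

rotation_matrix <- function(angles_deg, d) {
  th <- angles_deg * pi / 180
  if (d == 2) {
    matrix(c(cos(th[1]), sin(th[1]), -sin(th[1]), cos(th[1])), 2, 2)
  } else {
    cx <- cos(th[1]); sx <- sin(th[1])
    cy <- cos(th[2]); sy <- sin(th[2])
    cz <- cos(th[3]); sz <- sin(th[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
}

#' Rigid-body transform
#'
#' Rotation about the grid center followed by a translation, in voxel units of
#' the fixed image.  Acting on a moving image it resamples
#' `moving(R (x - c) + c + t)` onto the fixed grid, so the stored translation
#' equals the content shift of the moving image relative to the fixed one.
#'
#' @param angles_deg rotation angles in degrees (1 value in 2-D, 3 in 3-D:
#'   about x, y, z).
#' @param translation_voxels translation per axis (voxels).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(angles_deg, translation_voxels) {
  d <- length(translation_voxels)
  if (!d %in% 2:3) stop("translation must have length 2 or 3")
  na <- if (d == 2) 1 else 3
  if (length(angles_deg) != na) stop("wrong number of rotation angles")
  structure(list(angles_deg = as.numeric(angles_deg),
                 translation = as.numeric(translation_voxels),
                 R = rotation_matrix(angles_deg, d)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform: angles", paste(signif(x$angles_deg, 4), collapse = ", "),
      "deg; translation", paste(signif(x$translation, 4), collapse = ", "),
      "voxels\n")
  invisible(x)
}

rigid_map_points <- function(rt, coords, shape) {
  d <- length(shape)
  ctr <- (shape + 1) / 2
  out <- vector("list", d)
  for (k in seq_len(d)) {
    acc <- 0
    for (m in seq_len(d)) acc <- acc + rt$R[k, m] * (coords[[m]] - ctr[m])
    out[[k]] <- acc + ctr[k] + rt$translation[k]
  }
  out
}

#' Invert a transform
#'
#' Rigid transforms invert analytically; deformation fields by fixed-point
#' iteration ([invert_field()]).
#'
#' @param x a `rigid_transform` or `deformation_field`.
#' @param ... passed on to [invert_field()] for fields.
#' @return The inverse transform, same class as the input.
#' @export
invert_transform <- function(x, ...) UseMethod("invert_transform")

#' @export
invert_transform.rigid_transform <- function(x, ...) {
  Ri <- t(x$R)
  ti <- -as.numeric(Ri %*% x$translation)
  out <- structure(list(angles_deg = -x$angles_deg, translation = ti, R = Ri),
                   class = "rigid_transform")
  out
}

#' @export
invert_transform.deformation_field <- function(x, ...) invert_field(x, ...)

rigid_to_field <- function(rt, geometry) {
  shape <- geometry$shape
  d <- length(shape)
  co <- grid_coords(shape)
  mapped <- rigid_map_points(rt, co, shape)
  disp <- array(0, c(shape, d))
  for (k in seq_len(d)) {
    idx <- c(rep(list(quote(expr = )), d), list(k))
    disp <- do.call(`[<-`, c(list(disp), idx, list(mapped[[k]] - co[[k]])))
  }
  deformation_field(disp, geometry)
}

as_field <- function(x, geometry) {
  if (inherits(x, "deformation_field")) x
  else if (inherits(x, "rigid_transform")) rigid_to_field(x, geometry)
  else stop("not a transform")
}

# ---- field algebra -----------------------------------------------------------

# f_outer o f_inner as displacements: u(x) = u_in(x) + u_out(x + u_in(x))
compose_disp <- function(outer, inner) {
  geom <- inner$geometry
  co <- grid_coords(geom$shape)
  d <- length(geom$shape)
  pts <- lapply(seq_len(d), function(k) co[[k]] + field_component(inner, k))
  uo <- sample_field(outer, pts)
  disp <- array(0, c(geom$shape, d))
  for (k in seq_len(d)) {
    idx <- c(rep(list(quote(expr = )), d), list(k))
    disp <- do.call(`[<-`, c(list(disp), idx,
                             list(field_component(inner, k) + uo[[k]])))
  }
  deformation_field(disp, geom)
}

#' Invert a deformation field
#'
#' Fixed-point iteration `g <- -f o (id + g)`, run for up to `max_iter`
#' sweeps or until the mean update falls below `tol` voxels.
#'
#' @param f a [deformation_field()] with positive Jacobian.
#' @param max_iter iteration cap (default 20).
#' @param tol mean-update stopping tolerance in voxels (default 0.01).
#' @return The inverse [deformation_field()]; attribute `residual` holds the
#'   final mean inverse-consistency error.
#' @export
invert_field <- function(f, max_iter = 20, tol = 0.01) {
  geom <- f$geometry
  d <- length(geom$shape)
  co <- grid_coords(geom$shape)
  g <- lapply(seq_len(d), function(k) array(0, geom$shape))
  for (it in seq_len(max_iter)) {
    pts <- lapply(seq_len(d), function(k) co[[k]] + g[[k]])
    fv <- sample_field(f, pts)
    upd <- 0
    for (k in seq_len(d)) {
      newg <- -fv[[k]]
      upd <- upd + (newg - g[[k]])^2
      g[[k]] <- newg
    }
    if (mean(sqrt(upd)) < tol) break
  }
  disp <- array(0, c(geom$shape, d))
  for (k in seq_len(d)) {
    idx <- c(rep(list(quote(expr = )), d), list(k))
    disp <- do.call(`[<-`, c(list(disp), idx, list(g[[k]])))
  }
  out <- deformation_field(disp, geom)
  pts <- lapply(seq_len(d), function(k) co[[k]] + g[[k]])
  fv <- sample_field(f, pts)
  res <- 0
  for (k in seq_len(d)) res <- res + (g[[k]] + fv[[k]])^2
  attr(out, "residual") <- mean(sqrt(res))
  out
}

#' Concatenate a chain of transforms into one deformation field
#'
#' The chain is applied to an image left to right; the returned field performs
#' the whole chain with a single resampling, avoiding accumulated
#' interpolation blur.
#'
#' @param chain list of `rigid_transform` / `deformation_field` objects.
#' @param geometry output-grid [volume_geometry()]; defaults to the geometry
#'   of the first field in the chain.
#' @return A [deformation_field()].
#' @export
compose_chain <- function(chain, geometry = NULL) {
  if (!length(chain)) stop("empty transform chain")
  if (is.null(geometry)) {
    for (el in chain)
      if (inherits(el, "deformation_field")) { geometry <- el$geometry; break }
    if (is.null(geometry)) stop("geometry needed for a rigid-only chain")
  }
  fields <- lapply(chain, as_field, geometry = geometry)
  comp <- fields[[1]]
  for (k in seq_along(fields)[-1]) comp <- compose_disp(comp, fields[[k]])
  comp
}

#' Warp an image through a transform
#'
#' Pull-back resampling: linear interpolation for intensity images, nearest
#' neighbor for label volumes.  Out-of-domain voxels receive 0.
#'
#' @param img numeric array (2-D or 3-D).
#' @param transform a `deformation_field`, `rigid_transform`, or list chain.
#' @param interp `"linear"` or `"nearest"`.
#' @param geometry output geometry, needed when `transform` is rigid only.
#' @return Warped array on the output grid.
#' @export
warp_image <- function(img, transform, interp = c("linear", "nearest"),
                       geometry = NULL) {
  interp <- match.arg(interp)
  if (!inherits(transform, c("deformation_field", "rigid_transform"))) {
    if (!is.list(transform) ||
        !all(vapply(transform, inherits, TRUE,
                    what = c("deformation_field", "rigid_transform"))))
      stop("not a transform")
    transform <- compose_chain(transform, geometry)
  }
  if (inherits(transform, "rigid_transform")) {
    if (is.null(geometry)) geometry <- volume_geometry(dim(img))
    transform <- rigid_to_field(transform, geometry)
  }
  geom <- transform$geometry
  d <- length(geom$shape)
  co <- grid_coords(geom$shape)
  pts <- lapply(seq_len(d), function(k) co[[k]] + field_component(transform, k))
  out <- if (interp == "linear") interp_linear(img, pts, fill = 0)
         else interp_nearest(img, pts, fill = 0)
  array(out, geom$shape)
}

#' Jacobian determinant of a deformation
#'
#' Determinant of the spatial gradient of `id + u` by central differences — a
#' diagnostic that the map is locally one-to-one (positive everywhere for a
#' diffeomorphism).
#'
#' @param f a [deformation_field()].
#' @return Numeric array of determinants.
#' @export
jacobian_determinant <- function(f) {
  d <- length(f$geometry$shape)
  J <- vector("list", d)
  for (k in seq_len(d)) {
    gk <- gradient_arrays(field_component(f, k))
    J[[k]] <- lapply(seq_len(d), function(m)
      gk[[m]] + as.numeric(k == m))
  }
  if (d == 2) {
    J[[1]][[1]] * J[[2]][[2]] - J[[1]][[2]] * J[[2]][[1]]
  } else {
    J[[1]][[1]] * (J[[2]][[2]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[2]]) -
    J[[1]][[2]] * (J[[2]][[1]] * J[[3]][[3]] - J[[2]][[3]] * J[[3]][[1]]) +
    J[[1]][[3]] * (J[[2]][[1]] * J[[3]][[2]] - J[[2]][[2]] * J[[3]][[1]])
  }
}

# ---- pyramid helpers ---------------------------------------------------------

downsample_image <- function(arr, factor) {
  if (factor == 1) return(arr)
  sm <- smooth_gaussian(arr, factor / 2)
  dm <- dim(arr)
  idx <- lapply(dm, function(n) seq(1, n, by = factor))
  do.call(`[`, c(list(sm), idx, list(drop = FALSE)))
}

# upsample a coarse displacement field (coarse voxel units) onto a fine grid
upsample_field <- function(f, fine_shape, factor) {
  d <- length(fine_shape)
  co <- grid_coords(fine_shape)
  pts <- lapply(seq_len(d), function(k) (co[[k]] - 1) / factor + 1)
  uv <- sample_field(f, pts)
  disp <- array(0, c(fine_shape, d))
  for (k in seq_len(d)) {
    idx <- c(rep(list(quote(expr = )), d), list(k))
    disp <- do.call(`[<-`, c(list(disp), idx, list(uv[[k]] * factor)))
  }
  deformation_field(disp, volume_geometry(fine_shape))
}
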