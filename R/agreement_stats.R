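#' Bland-Altman agreement analysis
#'
#' Differences are `a - b` (first argument minus second).  The bias is the
#' mean difference; the limits of agreement are `bias +/- 1.96 sd` with the
#' sample (n-1) standard deviation.
#'
#' @param a,b paired numeric vectors of equal length (>= 2).
#' @return Object of class `bland_altman`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, plus `mean_pair` and `diff` for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d), mean_pair = (a + b) / 2, diff = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("bland_altman (n = %d): bias %.4f, SD %.4f, LoA [%.4f, %.4f]\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "pair mean", ylab = "difference", ...) {
  graphics::plot(x$mean_pair, x$diff, xlab = xlab, ylab = ylab,
                 ylim = range(c(x$diff, x$loa_low, x$loa_high)), ...)
  graphics::abline(h = x$bias, lty = 3)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Coefficient of variation per region
#'
#' `CV% = 100 * SD / mean` of subject-level regional means, one row per
#' region.
#'
#' @param values matrix or data.frame, subjects in rows, regions in columns.
#' @return data.frame with columns `region`, `n`, `mean`, `sd`, `cv_percent`.
#' @export
cv_by_region <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 subjects per region")
  m <- colMeans(values)
  if (any(m == 0)) stop("zero regional mean; CV undefined")
  s <- apply(values, 2, stats::sd)
  data.frame(region = colnames(values) %||% paste0("R", seq_along(m)),
             n = nrow(values), mean = m, sd = s,
             cv_percent = 100 * s / m, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gray-to-white flow ratio
#'
#' @param wbgm_mean whole-brain gray matter mean.
#' @param swm_mean subcortical white matter mean (> 0).
#' @return Scalar ratio.
#' @export
gray_white_ratio <- function(wbgm_mean, swm_mean) {
  if (!is.finite(swm_mean) || swm_mean <= 0)
    stop("white-matter mean must be positive")
  wbgm_mean / swm_mean
}
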