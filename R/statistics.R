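#' Heterogeneity summary of repeated measurements
#'
#' Mean, SEM and coefficient of variation of a set of region or image
#' measurements. The CV — sample standard deviation (n - 1 denominator)
#' divided by the mean, as a percent — is the heterogeneity index used
#' throughout the pipeline.
#'
#' @param values Numeric vector, n >= 2.
#' @return List of class `heterogeneity`: `n`, `mean`, `sd`, `sem`,
#'   `cv_pct` (NA when the mean is 0).
#' @examples
#' heterogeneity(c(1, 2, 3))$cv_pct # 50
#' @export
heterogeneity <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  m <- mean(values); s <- sd(values)
  structure(list(n = n, mean = m, sd = s, sem = s / sqrt(n),
                 cv_pct = if (m != 0) 100 * s / m else NA_real_),
            class = "heterogeneity")
}

#' @export
print.heterogeneity <- function(x, ...) {
  cat(sprintf("<heterogeneity> n=%d mean=%.4g sem=%.4g CV=%.1f%%\n",
              x$n, x$mean, x$sem, x$cv_pct))
  invisible(x)
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x` with R² and the two-sided p-value
#' for slope != 0 (t distribution, n - 2 df). Used for all paired-dataset
#' correlations in the pipeline (marker vs particle densities, leakage
#' strata, band profiles). Delegates to [stats::lm()].
#'
#' @param x,y Numeric vectors of equal length, n >= 3; `x` must not be
#'   constant.
#' @return List of class `ols_fit`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
ols_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired values")
  if (sd(x) == 0) stop("x is constant")
  fit <- lm(y ~ x)
  # summary.lm warns on residual-free fits; exact lines are valid input here
  sm <- suppressWarnings(summary(fit))
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(x)),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> slope=%.4g intercept=%.4g R2=%.3f p=%.3g n=%d\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D statistic (maximum absolute difference of the two empirical CDFs) with
#' the asymptotic two-sided p-value, via [stats::ks.test()]. D is 0 for
#' identical samples and 1 for samples with disjoint supports.
#'
#' @param a,b Numeric vectors, each with n >= 1.
#' @return List of class `ks_result`: `D`, `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  structure(list(D = unname(kt$statistic), p_value = kt$p.value,
                 n_a = length(a), n_b = length(b)),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D=%.3f p=%.3g (n=%d, %d)\n",
              x$D, x$p_value, x$n_a, x$n_b))
  invisible(x)
}

#' Area-density profile along sequential bands of a panorama
#'
#' Tiles a long panorama (e.g. the unrolled circumference of a vessel) into
#' sequential, non-overlapping bands along the flow/circumference axis and
#' reports the thresholded area density of each requested channel per band.
#' Any remainder shorter than one band is dropped; the band count is
#' `floor(panorama length / band_length)`.
#'
#' @param stack A [channel_stack()] whose columns run along the
#'   circumference.
#' @param channels Character vector of channel names to profile.
#' @param thresholds Intensity thresholds, recycled across channels
#'   (default 60).
#' @param band_length Band extent along the circumference axis in pixels
#'   (default 1500).
#' @param band_width Band extent across the panorama in pixels; `NULL`
#'   (default) uses the full height. Wider requests are clipped.
#' @return A `band_profile`: long data frame with columns `band`, `channel`,
#'   `area_density_pct`; attribute `band_px` gives pixels per band.
#' @export
band_profile <- function(stack, channels, thresholds = 60,
                         band_length = 1500, band_width = NULL) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack)
  if (band_length > d[2]) stop("band_length exceeds panorama length")
  n_bands <- floor(d[2] / band_length)
  rows <- seq_len(min(if (is.null(band_width)) d[1] else band_width, d[1]))
  thresholds <- rep_len(thresholds, length(channels))
  out <- do.call(rbind, lapply(seq_along(channels), function(i) {
    ch <- get_channel(stack, channels[i])
    dens <- vapply(seq_len(n_bands), function(b) {
      cols <- ((b - 1) * band_length + 1):(b * band_length)
      block <- ch[rows, cols, drop = FALSE]
      100 * sum(block > thresholds[i]) / length(block)
    }, numeric(1))
    data.frame(band = seq_len(n_bands), channel = channels[i],
               area_density_pct = dens)
  }))
  attr(out, "band_px") <- length(rows) * band_length
  class(out) <- c("band_profile", "data.frame")
  out
}

#' Normalize a profile to its mean
#'
#' Divides each value by the vector mean, so the normalized vector has mean
#' exactly 1. Standard preprocessing before comparing plot profiles of two
#' channels on a common scale.
#'
#' @param values Numeric vector with positive mean.
#' @return Numeric vector of the same length with mean 1.
#' @export
normalize_to_mean <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be positive")
  values / m
}
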