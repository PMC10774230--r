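#' Binary colocalization fractions between two masks
#'
#' Exact set-overlap ratios: the percentage of A-pixels that are also
#' B-pixels, and the reverse. The two directions are asymmetric in general
#' (e.g. most of a junction-restricted marker colocalizes with the junction
#' reference, while only a small share of the reference colocalizes back).
#'
#' @param mask_a,mask_b Binary 0/1 matrices of equal shape.
#' @return List of class `coloc_fraction` with `pct_a_in_b`, `pct_b_in_a`
#'   (NA when the respective mask is empty) and the pixel counts
#'   `n_a`, `n_b`, `n_overlap`.
#' @export
coloc_fraction <- function(mask_a, mask_b) {
  mask_a <- as_mask_matrix(mask_a)
  mask_b <- as_mask_matrix(mask_b)
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask dimensions differ")
  n_a <- sum(mask_a); n_b <- sum(mask_b)
  ov <- sum(mask_a * mask_b)
  structure(list(
    pct_a_in_b = if (n_a > 0) 100 * ov / n_a else NA_real_,
    pct_b_in_a = if (n_b > 0) 100 * ov / n_b else NA_real_,
    n_a = n_a, n_b = n_b, n_overlap = ov
  ), class = "coloc_fraction")
}

#' @export
print.coloc_fraction <- function(x, ...) {
  cat(sprintf("<coloc_fraction> A in B: %.1f%%  B in A: %.1f%% (|A|=%d |B|=%d)\n",
              x$pct_a_in_b, x$pct_b_in_a, x$n_a, x$n_b))
  invisible(x)
}

#' Junctional fraction of a marker
#'
#' Percentage of a marker's thresholded staining that falls within the
#' junction mask (the junction reference used as a binary sampling mask).
#'
#' @param marker_mask Binary marker mask.
#' @param junction_mask Binary junction mask of the same shape.
#' @return Percentage (NA if the marker mask is empty).
#' @export
junctional_fraction <- function(marker_mask, junction_mask) {
  coloc_fraction(marker_mask, junction_mask)$pct_a_in_b
}

#' van Steensel cross-correlation curve along the flow axis
#'
#' Computes the Pearson correlation of two intensity channels as one is
#' shifted column-by-column along the flow axis: for each integer shift
#' `d` in `[-max_shift, +max_shift]` the value is
#' `cor(A[, j], B[, j + d])` over the overlapping columns only (no zero
#' padding, so edge columns never dilute the correlation). A positive peak
#' shift means the structure in `b` lies downstream of the structure in `a`
#' — equivalently, non-colocalized `a` signal sits upstream of the
#' colocalized signal. The peak is the argmax of the curve; ties are broken
#' toward shift 0.
#'
#' @param a,b Intensity matrices of equal shape (channel of interest and
#'   reference channel).
#' @param max_shift Maximum shift S in pixels; the curve has 2S + 1 values
#'   (default 20, i.e. shifts -20..+20).
#' @param calibration Optional [calibration()]; converts the peak shift to µm.
#' @param roi Optional binary ROI mask; correlations are restricted to ROI
#'   pixels (evaluated at the unshifted position).
#' @return A `ccf_curve`: data frame with columns `shift_px` and `ccf`
#'   (NA where an overlap window has zero variance), and attributes
#'   `peak_px`, `peak_um` (NA without calibration) and `peak_value`.
#' @examples
#' set.seed(1)
#' a <- matrix(runif(900, 0, 255), 30)
#' cc <- van_steensel_ccf(a, a, max_shift = 5)
#' attr(cc, "peak_px") # 0
#' @export
van_steensel_ccf <- function(a, b, max_shift = 20, calibration = NULL,
                             roi = NULL) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (!identical(dim(a), dim(b))) stop("channel dimensions differ")
  nc <- ncol(a)
  if (max_shift < 1 || max_shift >= nc) stop("max_shift must be in [1, ncol - 1]")
  if (!is.null(roi)) roi <- as_mask_matrix(roi)
  shifts <- -max_shift:max_shift
  vals <- vapply(shifts, function(d) {
    ja <- if (d >= 0) seq_len(nc - d) else seq(1 - d, nc)
    jb <- ja + d
    x <- a[, ja]; y <- b[, jb]
    if (!is.null(roi)) {
      keep <- roi[, ja] == 1L
      x <- x[keep]; y <- y[keep]
    }
    if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
    cor(as.vector(x), as.vector(y))
  }, numeric(1))
  ok <- which(!is.na(vals))
  if (length(ok) == 0L) stop("every shift window has zero variance")
  best <- ok[vals[ok] == max(vals[ok])]
  peak <- best[order(abs(shifts[best]), shifts[best])][1]
  out <- data.frame(shift_px = shifts, ccf = vals)
  attr(out, "peak_px") <- shifts[peak]
  attr(out, "peak_um") <- if (is.null(calibration)) NA_real_
                          else shifts[peak] * as_pixel_size(calibration)
  attr(out, "peak_value") <- vals[peak]
  class(out) <- c("ccf_curve", "data.frame")
  out
}

#' @export
print.ccf_curve <- function(x, ...) {
  cat(sprintf("<ccf_curve> %d shifts, peak %+d px (%s) ccf = %.3f\n",
              nrow(x), attr(x, "peak_px"),
              if (is.na(attr(x, "peak_um"))) "um n/a"
              else sprintf("%+.2f um", attr(x, "peak_um")),
              attr(x, "peak_value")))
  invisible(x)
}
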