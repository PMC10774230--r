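#' Extravasated-tracer area density
#'
#' Thresholded area density of an extravasated-tracer (IgG) mask within a
#' region of interest: `100 * |IgG intersect ROI| / |ROI|`.
#'
#' @param igg_mask Binary tracer mask (e.g. [binarize()] at threshold 60).
#' @param roi Optional binary ROI; defaults to the whole image. Must be
#'   non-empty.
#' @return Percentage in \[0, 100\].
#' @export
igg_density <- function(igg_mask, roi = NULL) {
  area_density(igg_mask, roi)
}

#' Tracer density stratified by marker staining
#'
#' Splits the ROI into marker-positive and marker-negative strata and
#' reports the tracer area density in each, together with the overall
#' density. The overall density is exactly the area-weighted mean of the two
#' stratum densities. An optional dilation of the marker mask (radius in
#' pixels) supports sensitivity analysis; the default of 0 uses the raw
#' mask.
#'
#' @param igg_mask Binary tracer mask.
#' @param marker_mask Binary marker mask (same shape).
#' @param roi Optional binary ROI (default: whole image).
#' @param dilate_radius Dilation radius applied to the marker mask before
#'   stratifying (default 0 = none).
#' @return List of class `leakage_result`: `overall_pct`, `with_marker_pct`,
#'   `without_marker_pct` (NA for an empty stratum), stratum pixel counts
#'   `n_with`, `n_without` and `n_roi`.
#' @export
density_by_marker <- function(igg_mask, marker_mask, roi = NULL,
                              dilate_radius = 0) {
  igg_mask <- as_mask_matrix(igg_mask)
  marker_mask <- as_mask_matrix(marker_mask)
  if (!identical(dim(igg_mask), dim(marker_mask)))
    stop("mask dimensions differ")
  if (is.null(roi)) roi <- matrix(1L, nrow(igg_mask), ncol(igg_mask))
  roi <- as_mask_matrix(roi)
  if (sum(roi) == 0) stop("ROI is empty")
  if (dilate_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_radius) + 1L, "disc")
    marker_mask <- matrix(as.integer(EBImage::dilate(marker_mask, brush) > 0),
                          nrow(marker_mask), ncol(marker_mask))
  }
  pos <- marker_mask * roi
  neg <- (1L - marker_mask) * roi
  n_pos <- sum(pos); n_neg <- sum(neg)
  d_pos <- if (n_pos > 0) 100 * sum(igg_mask * pos) / n_pos else NA_real_
  d_neg <- if (n_neg > 0) 100 * sum(igg_mask * neg) / n_neg else NA_real_
  structure(list(overall_pct = 100 * sum(igg_mask * roi) / sum(roi),
                 with_marker_pct = d_pos, without_marker_pct = d_neg,
                 n_with = n_pos, n_without = n_neg, n_roi = sum(roi)),
            class = "leakage_result")
}

#' @export
print.leakage_result <- function(x, ...) {
  cat(sprintf("<leakage_result> overall %.1f%% | +marker %.1f%% | -marker %.1f%%\n",
              x$overall_pct, x$with_marker_pct, x$without_marker_pct))
  invisible(x)
}

#' Regressions of stratified leakage across images
#'
#' Given per-image stratified leakage results, fits the three standard
#' comparisons: marker-positive density vs overall, marker-negative density
#' vs overall, and marker-positive vs marker-negative.
#'
#' @param results Either a list of `leakage_result` objects or a data frame
#'   with columns `with_marker_pct`, `without_marker_pct`, `overall_pct`
#'   (>= 3 images).
#' @return List of three [ols_fit()] results: `with_vs_total`,
#'   `without_vs_total`, `with_vs_without`.
#' @export
marker_leakage_regressions <- function(results) {
  if (is.data.frame(results)) tab <- results
  else tab <- do.call(rbind, lapply(results, function(r)
    data.frame(with_marker_pct = r$with_marker_pct,
               without_marker_pct = r$without_marker_pct,
               overall_pct = r$overall_pct)))
  if (nrow(tab) < 3) stop("need at least 3 images")
  list(with_vs_total = ols_fit(tab$overall_pct, tab$with_marker_pct),
       without_vs_total = ols_fit(tab$overall_pct, tab$without_marker_pct),
       with_vs_without = ols_fit(tab$without_marker_pct, tab$with_marker_pct))
}
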