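# Folding-reporter (FLUC-GFP type) proteostasis readout: intensity
# granularity and aggregate sizes within a dendrite ROI.

#' Granularity (coefficient of variation) of an ROI
#'
#' The proteostasis readout for a diffuse-vs-aggregated folding reporter:
#' the sample standard deviation of the ROI's pixel intensities divided by
#' their mean, computed on the maximum-intensity projection of the
#' reporter channel. Higher values indicate aggregation.
#'
#' @param intensities numeric vector or matrix of ROI pixel intensities
#'   (>= 2 pixels, all >= 0).
#' @return The coefficient of variation (SD/mean); NA with a warning when
#'   the mean is 0.
#' @export
granularity_cv <- function(intensities) {
  v <- as.numeric(intensities)
  if (length(v) < 2) stop("granularity_cv needs at least 2 pixels")
  if (any(v < 0)) stop("negative intensity")
  m <- mean(v)
  if (m == 0) {
    warning("mean intensity is 0: CV undefined")
    return(NA_real_)
  }
  stats::sd(v) / m
}

#' Maximum-intensity projection of an image stack
#'
#' @param stack 3D array (x, y, z) of intensities.
#' @return 2D matrix of per-pixel maxima.
#' @export
max_project <- function(stack) {
  if (length(dim(stack)) == 2L) return(stack)
  apply(stack, c(1, 2), max)
}

#' Aggregate sizes within an ROI
#'
#' Segments bright reporter aggregates as 8-connected components of
#' pixels above an ROI-relative threshold, mean + k x SD (default k = 2),
#' and returns their sizes in pixels, largest first. The threshold is
#' recomputed per ROI, so a uniform additive background does not change
#' the segmentation.
#'
#' @param roi 2D numeric matrix of ROI pixel intensities.
#' @param threshold_k SD multiplier above the mean (default 2).
#' @return Integer vector of component sizes in pixels, descending
#'   (empty when nothing exceeds the threshold).
#' @export
aggregate_sizes <- function(roi, threshold_k = 2) {
  roi <- as.matrix(roi)
  thr <- mean(roi) + threshold_k * stats::sd(roi)
  mask <- roi > thr
  if (!any(mask)) return(integer(0))
  lab <- .label8(mask)
  sort(as.integer(table(lab[lab > 0L])), decreasing = TRUE)
}

#' Summarize the proteostasis readout of one ROI
#'
#' @param roi 2D numeric matrix of ROI pixel intensities (max projection).
#' @param roi_id identifier for the ROI.
#' @param threshold_k SD multiplier for aggregate segmentation.
#' @return Data frame row: roi_id, area_px, cv, n_aggregates,
#'   largest_aggregate_px.
#' @export
granularity_summary <- function(roi, roi_id = "roi1", threshold_k = 2) {
  sizes <- aggregate_sizes(roi, threshold_k)
  data.frame(roi_id = roi_id, area_px = length(roi),
             cv = granularity_cv(roi),
             n_aggregates = length(sizes),
             largest_aggregate_px = if (length(sizes)) sizes[1] else 0L)
}
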