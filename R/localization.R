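#' Per-neuron localization summary
#'
#' Counts and per-pixel densities of spots by compartment, the
#' dendrite-to-soma density ratio (the localization readout: mRNA count per
#' mask pixel of dendrite divided by that of soma), and the per-bin count
#' vector of dendritic spots, indexed out to the longest analyzed distance
#' with trailing zeros kept.
#'
#' @param assignment a \code{binned_assignment}.
#' @param geometry the \code{neuron_geometry} the assignment was made on.
#' @param n_bins number of bins to report; default spans the longest branch.
#' @return An object of class \code{localization_summary}.
#' @export
summarize_localization <- function(assignment, geometry, n_bins = NULL) {
  bw <- attr(assignment, "bin_width") %||% 25000
  soma_n <- sum(assignment$compartment == "soma")
  dend <- assignment[assignment$compartment == "dendrite", , drop = FALSE]
  per_branch <- if (length(geometry$branches))
    vapply(seq_along(geometry$branches),
           function(b) sum(dend$branch == b), integer(1)) else integer(0)
  area_soma <- compartment_area(geometry, "soma")
  area_dend <- compartment_area(geometry, "dendrite")
  density_soma <- if (area_soma > 0) soma_n / area_soma else NA_real_
  density_dend <- if (area_dend > 0) nrow(dend) / area_dend else NA_real_
  ratio <- if (!is.na(density_soma) && density_soma > 0)
    density_dend / density_soma else NA_real_
  if (is.null(n_bins)) {
    max_len <- if (length(geometry$branches))
      max(vapply(geometry$branches, function(b) .polyline_length(b$skeleton),
                 numeric(1))) else 0
    n_bins <- max(1L, ceiling(max_len / bw))
  }
  bins <- tabulate(dend$bin + 1L, nbins = n_bins)
  structure(list(
    soma_count = soma_n,
    dendrite_count = nrow(dend),
    dendrite_count_per_branch = per_branch,
    outside_count = sum(assignment$compartment == "outside"),
    area_soma = area_soma, area_dendrite = area_dend,
    density_soma = density_soma, density_dendrite = density_dend,
    ratio_dendrite_to_soma = ratio,
    bin_counts = bins, bin_width = bw
  ), class = "localization_summary")
}

#' @export
print.localization_summary <- function(x, ...) {
  cat("Localization summary\n")
  cat(sprintf("  soma: %d spots / %d px (density %.4g)\n",
              x$soma_count, x$area_soma, x$density_soma))
  cat(sprintf("  dendrite: %d spots / %d px (density %.4g)\n",
              x$dendrite_count, x$area_dendrite, x$density_dendrite))
  cat(sprintf("  dendrite/soma density ratio: %.3g\n", x$ratio_dendrite_to_soma))
  cat(sprintf("  outside (QC): %d\n", x$outside_count))
  cat("  per-bin counts:", paste(x$bin_counts, collapse = " "), "\n")
  invisible(x)
}

#' @export
as_result_table.localization_summary <- function(x, ...) {
  data.frame(bin_index = seq_along(x$bin_counts) - 1L,
             stat = "bin_count",
             observed = x$bin_counts,
             soma_count = x$soma_count,
             dendrite_count = x$dendrite_count,
             density_soma = x$density_soma,
             density_dendrite = x$density_dendrite,
             ratio_dendrite_to_soma = x$ratio_dendrite_to_soma)
}

#' Nascent transcript count at a transcription site
#'
#' A transcription site's integrated intensity divided by the unit
#' single-mRNA intensity (the median integrated intensity of cytoplasmic
#' single-mRNA spots of the same channel and cell), rounded to the nearest
#' integer. A spot classified as a transcription site must exceed a single
#' mRNA, so the count is floored at 2.
#'
#' @param ts_intensity transcription-site integrated intensity (vectorized).
#' @param unit_mrna_intensity unit single-mRNA intensity, > 0.
#' @return Integer nascent transcript counts.
#' @export
ts_nascent_count <- function(ts_intensity, unit_mrna_intensity) {
  if (!isTRUE(unit_mrna_intensity > 0))
    stop("calibration error: unit mRNA intensity must be > 0")
  pmax(2L, as.integer(round(ts_intensity / unit_mrna_intensity)))
}

#' Call transcription sites in a spot table
#'
#' The unit single-mRNA intensity is the median intensity of candidate
#' single spots (robust to transcription-site contamination). Spots
#' brighter than 1.5x the unit — restricted to a nucleus polygon when one
#' is supplied — are classified as transcription sites and their nascent
#' transcript counts computed with \code{\link{ts_nascent_count}}.
#'
#' @param spots a \code{spot_table}.
#' @param nucleus optional nucleus polygon (n x 2 nm matrix, closed ring);
#'   when given, only nuclear spots can be transcription sites and the unit
#'   intensity is calibrated on cytoplasmic spots only.
#' @param ts_factor intensity multiple of the unit above which a spot is a
#'   transcription site (default 1.5).
#' @return List with \code{unit_intensity}, and a data frame \code{sites}
#'   (id, intensity, nascent_count).
#' @export
call_transcription_sites <- function(spots, nucleus = NULL, ts_factor = 1.5) {
  in_nuc <- if (is.null(nucleus)) rep(TRUE, nrow(spots))
            else .in_polygon(spots$x, spots$y, nucleus[-nrow(nucleus), , drop = FALSE])
  calib <- if (is.null(nucleus)) rep(TRUE, nrow(spots)) else !in_nuc
  if (!any(calib)) stop("calibration error: no cytoplasmic spots to estimate the unit mRNA intensity")
  unit <- stats::median(spots$intensity[calib])
  is_ts <- in_nuc & spots$intensity > ts_factor * unit
  sites <- data.frame(id = spots$id[is_ts],
                      intensity = spots$intensity[is_ts],
                      nascent_count = if (any(is_ts))
                        ts_nascent_count(spots$intensity[is_ts], unit) else integer(0))
  list(unit_intensity = unit, sites = sites)
}

#' Fold enrichment between two groups of localization summaries
#'
#' Mean per-pixel density in condition b over condition a for the chosen
#' compartment. Densities rather than raw counts, so unequal cell sizes do
#' not bias the ratio.
#'
#' @param summaries_a,summaries_b lists of \code{localization_summary}
#'   (conditions a and b).
#' @param compartment \code{"soma"} or \code{"dendrite"}.
#' @return The fold enrichment (mean density b / mean density a).
#' @export
fold_enrichment <- function(summaries_a, summaries_b,
                            compartment = c("dendrite", "soma")) {
  compartment <- match.arg(compartment)
  f <- if (compartment == "soma") function(s) s$density_soma
       else function(s) s$density_dendrite
  if (!length(summaries_a) || !length(summaries_b)) stop("empty group")
  a <- mean(vapply(summaries_a, f, numeric(1)))
  b <- mean(vapply(summaries_b, f, numeric(1)))
  if (!isTRUE(a > 0)) stop("fold enrichment undefined: zero or missing denominator")
  b / a
}

#' Welch's unequal-variance t-test between two groups
#'
#' Two-sided Welch test with Welch-Satterthwaite degrees of freedom, the
#' per-bin group comparison used throughout. Identical constant groups
#' return t = 0, p = 1 (the test statistic is defined as 0 when both
#' groups are the same constant).
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
welch_compare <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("welch_compare needs n >= 2 per group")
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    return(list(t = sign(mean(group_b) - mean(group_a)) * Inf,
                df = length(group_a) + length(group_b) - 2, p = 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
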