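#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline. Defaults follow the
#' standard widefield smFISH setup this package targets: 107.5 nm xy pixels,
#' 200 nm z-steps, 25 um dendrite bins, a 600 nm spine-proximity radius
#' (distance to the PSD95 signal center), a 700 nm two-channel coexistence
#' radius (the diameter scale of neuronal RNA granules), 100 Monte-Carlo
#' repeats, and a 200 nm base threshold for mRNA-peptide pairing.
#'
#' @param bin_width dendrite bin width, nm.
#' @param spine_radius mRNA-to-spine proximity radius, nm.
#' @param coexist_radius two-channel coexistence radius, nm.
#' @param n_simulations Monte-Carlo repeats for the null ensemble.
#' @param translation_threshold_base base mRNA-peptide pairing distance, nm.
#' @param chromatic_offset length-3 numeric, nm: mean inter-channel
#'   registration offset, subtracted from the second channel's coordinates.
#' @param chromatic_residual scalar nm: residual registration error after
#'   offset correction, added to the pairing threshold.
#' @param pixel_size_xy image pixel size, nm.
#' @param z_step axial step between z-planes, nm.
#' @param rng_seed integer root seed for all Monte-Carlo draws.
#' @param alpha significance level for observed-vs-null comparisons.
#' @return An object of class \code{analysis_config} (a named list).
#' @export
analysis_config <- function(bin_width = 25000,
                            spine_radius = 600,
                            coexist_radius = 700,
                            n_simulations = 100,
                            translation_threshold_base = 200,
                            chromatic_offset = c(0, 0, 0),
                            chromatic_residual = 0,
                            pixel_size_xy = 107.5,
                            z_step = 200,
                            rng_seed = 1L,
                            alpha = 0.05) {
  stopifnot(bin_width > 0, spine_radius > 0, coexist_radius > 0,
            n_simulations >= 1, translation_threshold_base > 0,
            length(chromatic_offset) == 3, chromatic_residual >= 0,
            pixel_size_xy > 0, z_step > 0, alpha > 0, alpha < 1)
  structure(list(
    bin_width = bin_width,
    spine_radius = spine_radius,
    coexist_radius = coexist_radius,
    n_simulations = as.integer(n_simulations),
    translation_threshold_base = translation_threshold_base,
    chromatic_offset = as.numeric(chromatic_offset),
    chromatic_residual = chromatic_residual,
    pixel_size_xy = pixel_size_xy,
    z_step = z_step,
    rng_seed = as.integer(rng_seed),
    alpha = alpha
  ), class = "analysis_config")
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat(sprintf("  bin width        %g nm\n", x$bin_width))
  cat(sprintf("  spine radius     %g nm\n", x$spine_radius))
  cat(sprintf("  coexist radius   %g nm\n", x$coexist_radius))
  cat(sprintf("  n simulations    %d\n", x$n_simulations))
  cat(sprintf("  pairing threshold %g + %g nm\n",
              x$translation_threshold_base, x$chromatic_residual))
  cat(sprintf("  pixel size xy    %g nm, z step %g nm\n",
              x$pixel_size_xy, x$z_step))
  cat(sprintf("  seed %d, alpha %g\n", x$rng_seed, x$alpha))
  invisible(x)
}

# Rebuild a config from a plain list (e.g. parsed JSON).
.config_from_list <- function(lst) {
  do.call(analysis_config, lst[intersect(names(lst), names(formals(analysis_config)))])
}
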