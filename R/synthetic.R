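# Synthetic neurons and spot tables with ground truth, emulating the data
# the analysis assumes: mask-constrained spots, distance-dependent
# dendritic density, optional spine-proximal and cross-channel enrichment,
# transcription-site intensity pile-ups, peptide intensities proportional
# to ribosome number, and a fixed chromatic offset between channels.

#' Synthetic-data configuration
#'
#' Defaults are the "paper-like" preset for cultured hippocampal/motor
#' neurons: four 150 um dendrites of 1 um half-width on a 10 um-radius
#' soma, ~100 dendritic mRNAs per dendrite for an abundant channel and ~5
#' for a rare partner channel, spine density 1/um, 107.5 nm pixels. The
#' dendritic density decays exponentially with path distance
#' (lambda(d) ~ exp(-d/tau), tau = 60 um) so proximal bins hold more
#' mRNAs, as observed distributions do; \code{decay_tau_um = Inf} gives
#' uniform placement. Enrichment dials: \code{spine_enrichment} multiplies
#' the placement density within \code{spine_radius_nm} of a spine center
#' (1 = no enrichment), \code{coexistence_enrichment} is the fraction of
#' partner spots planted within \code{coexist_radius_nm} of a reference
#' spot. Translation: each mRNA translates with probability
#' \code{p_translating}; ribosome loads are geometric (mean
#' \code{ribosome_mean}, truncated at \code{ribosome_max}); peptide spot
#' intensity is load x \code{unit_intensity} x (1 + Normal(0, cv)).
#'
#' @param n_branches,branch_length_um,half_width_um,soma_radius_um morphology.
#' @param mrna_per_branch,soma_mrna expected spot numbers (Poisson means).
#' @param decay_tau_um dendritic density decay length, um (Inf = uniform).
#' @param spine_density_per_um spine linear density along the skeleton.
#' @param spine_enrichment multiplicative mRNA density within
#'   \code{spine_radius_nm} of a spine (1 = uniform).
#' @param spine_radius_nm,coexist_radius_nm enrichment radii, nm.
#' @param partner_per_branch expected partner-channel spots per branch.
#' @param coexistence_enrichment fraction of partner spots planted near a
#'   reference spot (0..1).
#' @param p_translating probability an mRNA is translating.
#' @param ribosome_mean,ribosome_max truncated-geometric ribosome load.
#' @param unit_intensity single-molecule intensity scale, AU.
#' @param intensity_cv multiplicative intensity noise CV.
#' @param n_free_peptides expected free (mature) peptide spots.
#' @param n_ts transcription sites planted in the nucleus.
#' @param ts_nascent_max maximum nascent transcripts at a site (drawn
#'   uniformly from 2..max).
#' @param chromatic_offset fixed (x, y, z) nm offset added to the second
#'   channel's emitted coordinates.
#' @param loc_error_nm localization error SD per axis, nm.
#' @param z_range_nm sampling slab for spot z, nm.
#' @param pixel_size_xy rasterization pixel size, nm.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_branches = 4,
                             branch_length_um = 150,
                             half_width_um = 1,
                             soma_radius_um = 10,
                             mrna_per_branch = 100,
                             soma_mrna = 150,
                             decay_tau_um = 60,
                             spine_density_per_um = 1,
                             spine_enrichment = 1,
                             spine_radius_nm = 600,
                             coexist_radius_nm = 700,
                             partner_per_branch = 5,
                             coexistence_enrichment = 0,
                             p_translating = 0.3,
                             ribosome_mean = 3,
                             ribosome_max = 30,
                             unit_intensity = 100,
                             intensity_cv = 0.1,
                             n_free_peptides = 50,
                             n_ts = 2,
                             ts_nascent_max = 12,
                             chromatic_offset = c(0, 0, 0),
                             loc_error_nm = 30,
                             z_range_nm = c(0, 800),
                             pixel_size_xy = 107.5) {
  stopifnot(n_branches >= 0, branch_length_um > 0, half_width_um > 0,
            branch_length_um >= half_width_um,
            soma_radius_um > 0, mrna_per_branch >= 0, decay_tau_um > 0,
            spine_density_per_um >= 0, spine_enrichment >= 0,
            coexistence_enrichment >= 0, coexistence_enrichment <= 1,
            p_translating >= 0, p_translating <= 1,
            ribosome_mean >= 1, ribosome_max >= 1, unit_intensity > 0,
            intensity_cv >= 0, loc_error_nm >= 0,
            length(chromatic_offset) == 3, length(z_range_nm) == 2)
  structure(as.list(environment()), class = "synthetic_config")
}

.noisy_intensity <- function(n, base, cv) {
  if (n == 0L) return(numeric(0))
  pmax(base * (1 + stats::rnorm(n, 0, cv)), base * 1e-3)
}

#' Generate a synthetic neuron and its spine set
#'
#' A disc soma (64-gon), straight dendrites radiating at equal angles,
#' and spines as a Poisson process along each skeleton at the configured
#' linear density, centers offset to the mask edge. A disc nucleus of
#' half the soma radius is returned for transcription-site placement.
#'
#' @param config a \code{synthetic_config}.
#' @param seed integer seed.
#' @return List: \code{geometry} (a \code{neuron_geometry}),
#'   \code{spines} (a \code{spot_table} of spine centers, empty if spine
#'   density is 0), \code{nucleus} (closed polygon, nm).
#' @export
generate_neuron <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.derive_seed(seed, 1))
  R <- config$soma_radius_um * 1000
  th <- seq(0, 2 * pi, length.out = 65)
  soma <- cbind(R * cos(th), R * sin(th))
  hw <- config$half_width_um * 1000
  L <- config$branch_length_um * 1000
  branches <- lapply(seq_len(config$n_branches), function(b) {
    a <- 2 * pi * (b - 1) / config$n_branches
    dir <- c(cos(a), sin(a))
    list(skeleton = rbind(R * dir, (R + L) * dir), half_width = hw)
  })
  geometry <- neuron_geometry(soma, branches, pixel_size_xy = config$pixel_size_xy)
  # spines: Poisson along each skeleton, centers at the mask edge
  sx <- sy <- sz <- numeric(0)
  for (b in seq_len(config$n_branches)) {
    n_sp <- stats::rpois(1, config$spine_density_per_um * config$branch_length_um)
    if (n_sp == 0L) next
    skel <- geometry$branches[[b]]$skeleton
    dir <- (skel[2, ] - skel[1, ]) / sqrt(sum((skel[2, ] - skel[1, ])^2))
    perp <- c(-dir[2], dir[1])
    u <- stats::runif(n_sp, 0, L)
    side <- sample(c(-1, 1), n_sp, replace = TRUE)
    sx <- c(sx, skel[1, 1] + u * dir[1] + side * hw * perp[1])
    sy <- c(sy, skel[1, 2] + u * dir[2] + side * hw * perp[2])
    sz <- c(sz, stats::runif(n_sp, config$z_range_nm[1], config$z_range_nm[2]))
  }
  spines <- spot_table(sx, sy, sz, intensity = 1, channel_label = "PSD95",
                       cell_id = "synthetic")
  nr <- R / 2
  nucleus <- cbind(nr * cos(th), nr * sin(th))
  list(geometry = geometry, spines = spines, nucleus = nucleus)
}

# Sample n positions from mask pixels with the given per-pixel weights;
# returns data.frame x, y (nm, with sub-pixel jitter) and the pixel row.
.sample_mask <- function(mask, n, weights, px) {
  if (n == 0L) return(data.frame(x = numeric(0), y = numeric(0), row = integer(0)))
  idx <- sample.int(nrow(mask), n, replace = TRUE, prob = weights)
  data.frame(x = mask$x[idx] + stats::runif(n, -0.5, 0.5) * px,
             y = mask$y[idx] + stats::runif(n, -0.5, 0.5) * px,
             row = idx)
}

#' Place mRNA spots with known ground truth
#'
#' Dendritic spots are an inhomogeneous Poisson draw over each branch
#' mask: per-pixel weight exp(-path/tau), multiplied by the spine
#' enrichment factor within the spine radius of a spine center; the
#' per-branch total is Poisson with the configured mean. Somatic spots
#' are uniform over the soma mask. Transcription sites are planted in the
#' nucleus with intensity = (nascent count) x unit. Localization error is
#' added to all coordinates; z is uniform in the configured slab.
#'
#' @param neuron output of \code{\link{generate_neuron}}.
#' @param config a \code{synthetic_config}.
#' @param seed integer seed.
#' @param channel_label channel name (default "reference").
#' @return List: \code{spots} (a \code{spot_table}), \code{truth} (per
#'   spot: compartment, branch, path_nm, bin, near_spine, is_ts,
#'   ts_nascent).
#' @export
place_mrnas <- function(neuron, config, seed = 1L, channel_label = "reference") {
  set.seed(.derive_seed(seed, 2))
  g <- neuron$geometry
  px <- g$pixel_size_xy
  tau <- config$decay_tau_um * 1000
  sp2d <- cbind(neuron$spines$x, neuron$spines$y)
  rows <- list()
  for (b in seq_along(g$branches)) {
    mask <- g$branches[[b]]$mask
    w <- if (is.finite(tau)) exp(-mask$path_nm / tau) else rep(1, nrow(mask))
    if (config$spine_enrichment != 1 && nrow(sp2d) > 0) {
      near <- apply(.cross_dist(cbind(mask$x, mask$y), sp2d), 1, min) <= config$spine_radius_nm
      w[near] <- w[near] * config$spine_enrichment
    }
    n <- stats::rpois(1, config$mrna_per_branch)
    smp <- .sample_mask(mask, n, w, px)
    if (n > 0) {
      near_spine <- if (nrow(sp2d) > 0)
        apply(.cross_dist(cbind(smp$x, smp$y), sp2d), 1, min) <= config$spine_radius_nm
      else rep(FALSE, n)
      rows[[length(rows) + 1L]] <- data.frame(
        x = smp$x, y = smp$y, compartment = "dendrite", branch = b,
        path_nm = mask$path_nm[smp$row], near_spine = near_spine,
        is_ts = FALSE, ts_nascent = NA_integer_)
    }
  }
  n_soma <- stats::rpois(1, config$soma_mrna)
  if (n_soma > 0) {
    smp <- .sample_mask(g$soma_mask, n_soma, NULL, px)
    rows[[length(rows) + 1L]] <- data.frame(
      x = smp$x, y = smp$y, compartment = "soma", branch = NA_integer_,
      path_nm = 0, near_spine = FALSE, is_ts = FALSE, ts_nascent = NA_integer_)
  }
  if (config$n_ts > 0) {
    nr <- config$soma_radius_um * 1000 / 2
    r <- nr * 0.6 * sqrt(stats::runif(config$n_ts))
    a <- stats::runif(config$n_ts, 0, 2 * pi)
    rows[[length(rows) + 1L]] <- data.frame(
      x = r * cos(a), y = r * sin(a), compartment = "soma",
      branch = NA_integer_, path_nm = 0, near_spine = FALSE, is_ts = TRUE,
      ts_nascent = as.integer(sample(2:config$ts_nascent_max, config$n_ts, replace = TRUE)))
  }
  truth <- if (length(rows)) do.call(rbind, rows)
           else data.frame(x = numeric(0), y = numeric(0),
                           compartment = character(0), branch = integer(0),
                           path_nm = numeric(0), near_spine = logical(0),
                           is_ts = logical(0), ts_nascent = integer(0))
  n <- nrow(truth)
  z <- stats::runif(n, config$z_range_nm[1], config$z_range_nm[2])
  err <- config$loc_error_nm
  x <- truth$x + stats::rnorm(n, 0, err)
  y <- truth$y + stats::rnorm(n, 0, err)
  z <- z + stats::rnorm(n, 0, err)
  intensity <- .noisy_intensity(n, config$unit_intensity, config$intensity_cv)
  intensity[truth$is_ts] <- truth$ts_nascent[truth$is_ts] * config$unit_intensity *
    (1 + stats::rnorm(sum(truth$is_ts), 0, config$intensity_cv))
  truth$bin <- ifelse(truth$compartment == "dendrite",
                      floor(truth$path_nm / 25000), NA_real_)
  spots <- spot_table(x, y, z, intensity, channel_label = channel_label,
                      cell_id = "synthetic")
  truth <- cbind(id = spots$id, truth)
  list(spots = spots, truth = truth)
}

#' Place a partner channel with controlled coexistence
#'
#' A fraction \code{coexistence_enrichment} of partner spots is planted
#' uniformly within the coexistence radius (a uniform draw in the 3D
#' ball) of a randomly chosen dendritic reference spot; the rest are
#' uniform over the dendrite mask. The configured chromatic offset is
#' added to all emitted coordinates (the analysis must correct it).
#'
#' @param reference the reference-channel \code{spot_table}.
#' @param ref_truth the reference ground truth (to find dendritic spots).
#' @param neuron output of \code{\link{generate_neuron}}.
#' @param config a \code{synthetic_config}.
#' @param seed integer seed.
#' @param channel_label channel name (default "partner").
#' @return List: \code{spots}, \code{truth} (per spot: planted partner
#'   reference id or NA).
#' @export
place_partner_channel <- function(reference, ref_truth, neuron, config,
                                  seed = 1L, channel_label = "partner") {
  set.seed(.derive_seed(seed, 3))
  g <- neuron$geometry
  px <- g$pixel_size_xy
  ref_d <- reference[ref_truth$compartment == "dendrite", , drop = FALSE]
  n <- stats::rpois(1, config$partner_per_branch * max(1, length(g$branches)))
  planted <- if (n > 0 && nrow(ref_d) > 0)
    stats::runif(n) < config$coexistence_enrichment else rep(FALSE, n)
  x <- y <- z <- numeric(n)
  partner_of <- rep(NA_integer_, n)
  if (any(planted)) {
    k <- sum(planted)
    ri <- sample.int(nrow(ref_d), k, replace = TRUE)
    # uniform in the 3D ball of the coexistence radius
    u <- stats::runif(k)^(1 / 3) * config$coexist_radius_nm
    ct <- stats::runif(k, -1, 1); ph <- stats::runif(k, 0, 2 * pi)
    st <- sqrt(1 - ct^2)
    x[planted] <- ref_d$x[ri] + u * st * cos(ph)
    y[planted] <- ref_d$y[ri] + u * st * sin(ph)
    z[planted] <- ref_d$z[ri] + u * ct
    partner_of[planted] <- ref_d$id[ri]
  }
  if (any(!planted)) {
    masks <- do.call(rbind, lapply(g$branches, function(b) b$mask[, c("x", "y")]))
    k <- sum(!planted)
    idx <- sample.int(nrow(masks), k, replace = TRUE)
    x[!planted] <- masks$x[idx] + stats::runif(k, -0.5, 0.5) * px
    y[!planted] <- masks$y[idx] + stats::runif(k, -0.5, 0.5) * px
    z[!planted] <- stats::runif(k, config$z_range_nm[1], config$z_range_nm[2])
  }
  off <- config$chromatic_offset
  spots <- spot_table(x + off[1], y + off[2], z + off[3],
                      .noisy_intensity(n, config$unit_intensity, config$intensity_cv),
                      channel_label = channel_label, cell_id = "synthetic")
  list(spots = spots,
       truth = data.frame(id = spots$id, partner_of = partner_of))
}

#' Emit a nascent-peptide channel for a set of mRNAs
#'
#' Each mRNA is translating with probability \code{p_translating}; a
#' translating mRNA gets one peptide spot displaced by a 3D Normal
#' localization error, with intensity = (ribosome load) x unit x
#' (1 + Normal(0, cv)), the load drawn truncated-geometric. Free mature
#' peptides (single proteins diffused away from mRNAs) are added
#' uniformly over soma and dendrite masks at unit intensity. The
#' chromatic offset is added to all emitted peptide coordinates.
#'
#' @param mrnas the mRNA \code{spot_table}.
#' @param neuron output of \code{\link{generate_neuron}}.
#' @param config a \code{synthetic_config}.
#' @param seed integer seed.
#' @return List: \code{spots} (peptide \code{spot_table}), \code{truth}
#'   (per mRNA: translating flag, ribosome count, peptide id).
#' @export
emit_translation_channels <- function(mrnas, neuron, config, seed = 1L) {
  set.seed(.derive_seed(seed, 4))
  g <- neuron$geometry
  n <- nrow(mrnas)
  translating <- stats::runif(n) < config$p_translating
  p_geom <- 1 / config$ribosome_mean
  ribo <- pmin(stats::rgeom(n, p_geom) + 1L, config$ribosome_max)
  ribo[!translating] <- NA_integer_
  k <- sum(translating)
  err <- config$loc_error_nm
  pep <- data.frame(x = mrnas$x[translating] + stats::rnorm(k, 0, err),
                    y = mrnas$y[translating] + stats::rnorm(k, 0, err),
                    z = mrnas$z[translating] + stats::rnorm(k, 0, err),
                    intensity = pmax(ribo[translating] * config$unit_intensity *
                      (1 + stats::rnorm(k, 0, config$intensity_cv)),
                      config$unit_intensity * 1e-3),
                    of_mrna = mrnas$id[translating])
  n_free <- stats::rpois(1, config$n_free_peptides)
  if (n_free > 0) {
    masks <- rbind(g$soma_mask[, c("x", "y")],
                   do.call(rbind, lapply(g$branches, function(b) b$mask[, c("x", "y")])))
    idx <- sample.int(nrow(masks), n_free, replace = TRUE)
    pep <- rbind(pep, data.frame(
      x = masks$x[idx] + stats::runif(n_free, -0.5, 0.5) * g$pixel_size_xy,
      y = masks$y[idx] + stats::runif(n_free, -0.5, 0.5) * g$pixel_size_xy,
      z = stats::runif(n_free, config$z_range_nm[1], config$z_range_nm[2]),
      intensity = .noisy_intensity(n_free, config$unit_intensity, config$intensity_cv),
      of_mrna = NA_integer_))
  }
  off <- config$chromatic_offset
  spots <- spot_table(pep$x + off[1], pep$y + off[2], pep$z + off[3],
                      pep$intensity, channel_label = "peptide",
                      cell_id = "synthetic")
  truth_mrna <- data.frame(mrna_id = mrnas$id, translating = translating,
                           ribosomes = ribo,
                           peptide_id = spots$id[match(mrnas$id, pep$of_mrna)])
  list(spots = spots, truth = truth_mrna)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running \code{\link{generate_neuron}},
#' \code{\link{place_mrnas}}, \code{\link{place_partner_channel}} and
#' \code{\link{emit_translation_channels}} with derived seeds.
#'
#' @param config a \code{synthetic_config}.
#' @param seed integer root seed.
#' @return List with \code{neuron}, \code{mrna}, \code{partner},
#'   \code{peptide} (each with spots + truth where applicable).
#' @export
simulate_dataset <- function(config = synthetic_config(), seed = 1L) {
  neuron <- generate_neuron(config, seed)
  mrna <- place_mrnas(neuron, config, seed)
  partner <- place_partner_channel(mrna$spots, mrna$truth, neuron, config, seed)
  peptide <- emit_translation_channels(mrna$spots, neuron, config, seed)
  list(neuron = neuron, mrna = mrna, partner = partner, peptide = peptide,
       config = config, seed = seed)
}
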