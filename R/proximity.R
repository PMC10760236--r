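# Spine-proximity and two-channel coexistence statistics with the
# per-bin count-preserving Monte-Carlo null.

.xyz <- function(df) cbind(df$x, df$y, if (!is.null(df$z)) df$z else 0)

#' Observed mRNA occupancy around dendritic spines
#'
#' For each spine center (e.g. a PSD95 IF centroid) counts the mRNAs whose
#' 3D Euclidean distance is within \code{radius} (closed: a spot at exactly
#' the radius counts), then tabulates per dendrite bin the frequency of
#' spines with 0, 1 and 2-or-more mRNAs. Spines anchor the statistic: a
#' spine's bin is its own path-distance bin, and one mRNA may count toward
#' several spines. Spines not assigned to a dendrite are dropped and
#' reported.
#'
#' @param mrnas a \code{binned_assignment} of the mRNA channel.
#' @param spines a \code{binned_assignment} of the spine centers (assign
#'   the PSD95 spot table with \code{\link{assign_spots}} on the same
#'   geometry).
#' @param radius proximity radius, nm (default 600).
#' @return An object of class \code{bin_occupancy}: per-spine counts and a
#'   per-bin frequency table.
#' @export
spine_occupancy <- function(mrnas, spines, radius = 600) {
  sp <- spines[spines$compartment == "dendrite", , drop = FALSE]
  n_dropped <- nrow(spines) - nrow(sp)
  counts <- .points_within(sp, mrnas, radius)
  per_spine <- data.frame(spine_id = sp$id, bin = sp$bin, n_mrna = counts)
  structure(list(per_spine = per_spine,
                 per_bin = .occupancy_freq(per_spine),
                 radius = radius, n_spines_dropped = n_dropped),
            class = "bin_occupancy")
}

.points_within <- function(anchors, pts, radius) {
  if (nrow(anchors) == 0L) return(integer(0))
  if (nrow(pts) == 0L) return(rep(0L, nrow(anchors)))
  d <- .cross_dist(.xyz(anchors), .xyz(pts))
  as.integer(rowSums(d <= radius))
}

.occupancy_freq <- function(per_spine) {
  if (nrow(per_spine) == 0L)
    return(data.frame(bin = integer(0), n_spines = integer(0),
                      freq0 = numeric(0), freq1 = numeric(0),
                      freq2plus = numeric(0)))
  out <- do.call(rbind, lapply(split(per_spine, per_spine$bin), function(g) {
    data.frame(bin = g$bin[1], n_spines = nrow(g),
               freq0 = mean(g$n_mrna == 0),
               freq1 = mean(g$n_mrna == 1),
               freq2plus = mean(g$n_mrna >= 2))
  }))
  rownames(out) <- NULL
  out[order(out$bin), , drop = FALSE]
}

#' @export
print.bin_occupancy <- function(x, ...) {
  cat(sprintf("Spine occupancy within %g nm (%d spines, %d dropped as non-dendritic)\n",
              x$radius, nrow(x$per_spine), x$n_spines_dropped))
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' @export
as_result_table.bin_occupancy <- function(x, ...) {
  pb <- x$per_bin
  data.frame(bin_index = rep(pb$bin, 3),
             stat = rep(c("freq0", "freq1", "freq2plus"), each = nrow(pb)),
             observed = c(pb$freq0, pb$freq1, pb$freq2plus),
             n_spines = rep(pb$n_spines, 3))
}

#' Observed two-channel coexistence
#'
#' For every reference-channel mRNA, the 3D Euclidean distance to its
#' nearest partner-channel mRNA; the pair coexists when that distance is
#' within \code{radius} (closed boundary). Reported per reference bin:
#' the coexisting fraction and the mean nearest-partner distance. Both
#' channels must already be registered to a common frame (chromatic
#' aberration corrected).
#'
#' @param reference a \code{binned_assignment} of the reference channel.
#' @param partner a \code{binned_assignment} (or spot data frame) of the
#'   partner channel.
#' @param radius coexistence radius, nm (default 700).
#' @return An object of class \code{coexistence_result}.
#' @export
coexistence <- function(reference, partner, radius = 700) {
  ref <- reference[reference$compartment == "dendrite", , drop = FALSE]
  nn <- if (nrow(partner) == 0L) rep(NA_real_, nrow(ref))
        else if (nrow(ref) == 0L) numeric(0)
        else apply(.cross_dist(.xyz(ref), .xyz(partner)), 1, min)
  per_ref <- data.frame(ref_id = ref$id, bin = ref$bin, nn_dist = nn,
                        coexists = !is.na(nn) & nn <= radius)
  per_bin <- if (nrow(per_ref)) {
    out <- do.call(rbind, lapply(split(per_ref, per_ref$bin), function(g)
      data.frame(bin = g$bin[1], n_reference = nrow(g),
                 fraction = mean(g$coexists),
                 mean_nn_dist = mean(g$nn_dist))))
    rownames(out) <- NULL
    out[order(out$bin), , drop = FALSE]
  } else data.frame(bin = integer(0), n_reference = integer(0),
                    fraction = numeric(0), mean_nn_dist = numeric(0))
  structure(list(per_reference = per_ref, per_bin = per_bin, radius = radius,
                 partner_empty = nrow(partner) == 0L),
            class = "coexistence_result")
}

#' @export
print.coexistence_result <- function(x, ...) {
  cat(sprintf("Coexistence within %g nm (%d reference mRNAs)\n",
              x$radius, nrow(x$per_reference)))
  if (x$partner_empty) cat("  partner channel empty: no coexistence, distances undefined\n")
  print(x$per_bin, row.names = FALSE)
  invisible(x)
}

#' @export
as_result_table.coexistence_result <- function(x, ...) {
  pb <- x$per_bin
  data.frame(bin_index = rep(pb$bin, 2),
             stat = rep(c("fraction", "mean_nn_dist"), each = nrow(pb)),
             observed = c(pb$fraction, pb$mean_nn_dist),
             n_reference = rep(pb$n_reference, 2))
}

#' Count-preserving Monte-Carlo null ensemble
#'
#' The null model of the pipeline: for each Monte-Carlo repeat and each
#' dendrite bin, as many mask pixels are drawn (uniformly, without
#' replacement within a repeat) as real mRNAs were observed in that bin,
#' so every repeat reproduces the observed per-bin counts exactly and the
#' simulated concentration profile along the dendrite matches the real
#' one. Pixel draws happen per branch x bin. A drawn pixel becomes a
#' simulated spot at its center plus uniform sub-pixel jitter. The pixel
#' draw itself is 2D; the simulated z is by default a resample (with
#' replacement) of the observed z values in the same branch and bin, so
#' 3D observed-vs-null distances stay comparable — fixing z at the bin
#' median (\code{z_mode = "median"}) or at 0 (\code{"zero"}, pure 2D) is
#' also available. Fixed points (spines, or a fixed reference channel)
#' are never moved. A statistic is evaluated on every repeat and
#' summarized as per-bin mean and sd.
#'
#' @param observed a \code{binned_assignment} whose dendritic spots define
#'   the per-bin counts to preserve.
#' @param geometry the \code{neuron_geometry}.
#' @param statistic function taking a simulated spot data frame (columns
#'   x, y, z, branch, path_nm, bin) and returning a named numeric vector;
#'   evaluated once per repeat. When \code{NULL}, only the simulated spot
#'   sets are returned.
#' @param n_sim number of repeats (default 100).
#' @param seed integer RNG seed for the ensemble.
#' @param z_mode simulated z: \code{"resample"} (default, bootstrap of
#'   the observed z in the branch and bin), \code{"median"} (bin median),
#'   or \code{"zero"} (pure 2D).
#' @return An object of class \code{null_ensemble}: \code{values}
#'   (n_sim x n_stat matrix), \code{mean}, \code{sd}, \code{sims} (list of
#'   simulated spot sets), and the preserved \code{counts} table.
#' @export
simulate_null <- function(observed, geometry, statistic = NULL,
                          n_sim = 100, seed = 1L,
                          z_mode = c("resample", "median", "zero")) {
  stopifnot(inherits(geometry, "neuron_geometry"), n_sim >= 1)
  z_mode <- match.arg(z_mode)
  bw <- attr(observed, "bin_width") %||% 25000
  dend <- observed[observed$compartment == "dendrite", , drop = FALSE]
  key <- paste(dend$branch, dend$bin)
  cells <- unique(data.frame(branch = dend$branch, bin = dend$bin))
  cells <- cells[order(cells$branch, cells$bin), , drop = FALSE]
  px <- geometry$pixel_size_xy
  pools <- lapply(seq_len(nrow(cells)), function(i) {
    m <- bin_mask(geometry, cells$branch[i], cells$bin[i], bw)
    k <- paste(cells$branch[i], cells$bin[i])
    cnt <- sum(key == k)
    if (cnt > nrow(m))
      stop(sprintf("cannot place %d spots without replacement in branch %d bin %d (%d pixels)",
                   cnt, cells$branch[i], cells$bin[i], nrow(m)))
    list(mask = m, count = cnt, branch = cells$branch[i], bin = cells$bin[i],
         z_obs = dend$z[key == k])
  })
  set.seed(seed)
  sims <- vector("list", n_sim)
  vals <- NULL
  for (r in seq_len(n_sim)) {
    parts <- lapply(pools, function(p) {
      idx <- sample.int(nrow(p$mask), p$count)
      zsim <- switch(z_mode,
                     resample = sample(p$z_obs, p$count, replace = TRUE),
                     median = rep(stats::median(p$z_obs), p$count),
                     zero = rep(0, p$count))
      data.frame(x = p$mask$x[idx] + stats::runif(p$count, -0.5, 0.5) * px,
                 y = p$mask$y[idx] + stats::runif(p$count, -0.5, 0.5) * px,
                 z = zsim,
                 branch = rep(p$branch, p$count),
                 path_nm = p$mask$path_nm[idx],
                 bin = rep(p$bin, p$count))
    })
    sim <- if (length(parts)) do.call(rbind, parts)
           else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                           branch = integer(0), path_nm = numeric(0),
                           bin = integer(0))
    sims[[r]] <- sim
    if (!is.null(statistic)) {
      v <- statistic(sim)
      if (is.null(vals)) vals <- matrix(NA_real_, n_sim, length(v),
                                        dimnames = list(NULL, names(v)))
      vals[r, ] <- v
    }
  }
  structure(list(values = vals,
                 mean = if (!is.null(vals)) colMeans(vals),
                 sd = if (!is.null(vals)) apply(vals, 2, stats::sd),
                 sims = sims,
                 counts = stats::aggregate(list(count = key), list(key = key), length),
                 n_sim = n_sim, seed = seed, bin_width = bw),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("Monte-Carlo null ensemble: %d repeats, seed %d\n", x$n_sim, x$seed))
  if (!is.null(x$mean)) {
    cat("  statistic mean (sd) per bin:\n")
    for (i in seq_along(x$mean))
      cat(sprintf("    %s: %.4g (%.4g)\n", names(x$mean)[i], x$mean[i], x$sd[i]))
  }
  invisible(x)
}

#' Per-bin spine-occupancy statistic for the null ensemble
#'
#' Returns a closure suitable for \code{\link{simulate_null}}: the
#' frequency of spines (in each listed bin) with at least \code{min_n}
#' simulated mRNAs within \code{radius}.
#'
#' @param spines dendritic spine assignment (fixed points).
#' @param radius proximity radius, nm.
#' @param bins bin indices to report.
#' @param min_n occupancy threshold (default 1: spines with >= 1 mRNA).
#' @return Function from a simulated spot set to a named per-bin vector.
#' @export
stat_spine_frequency <- function(spines, radius, bins, min_n = 1L) {
  sp <- spines[spines$compartment == "dendrite", , drop = FALSE]
  force(radius); force(bins); force(min_n)
  function(sim) {
    counts <- .points_within(sp, sim, radius)
    v <- vapply(bins, function(b) {
      inb <- sp$bin == b
      if (!any(inb)) NA_real_ else mean(counts[inb] >= min_n)
    }, numeric(1))
    names(v) <- paste0("bin", bins)
    v
  }
}

#' Per-bin coexistence statistics for the null ensemble
#'
#' Returns a closure for \code{\link{simulate_null}} with the partner
#' channel simulated and the reference channel fixed: per reference bin,
#' either the coexisting fraction (\code{what = "fraction"}) or the mean
#' nearest-partner distance (\code{what = "nn_dist"}).
#'
#' @param reference dendritic reference assignment (fixed points).
#' @param radius coexistence radius, nm.
#' @param bins bin indices to report.
#' @param what \code{"fraction"} or \code{"nn_dist"}.
#' @return Function from a simulated spot set to a named per-bin vector.
#' @export
stat_coexistence <- function(reference, radius, bins,
                             what = c("fraction", "nn_dist")) {
  what <- match.arg(what)
  ref <- reference[reference$compartment == "dendrite", , drop = FALSE]
  force(radius); force(bins)
  function(sim) {
    nn <- if (nrow(sim) == 0L) rep(NA_real_, nrow(ref))
          else apply(.cross_dist(.xyz(ref), .xyz(sim)), 1, min)
    v <- vapply(bins, function(b) {
      inb <- ref$bin == b
      if (!any(inb)) return(NA_real_)
      if (what == "fraction") mean(!is.na(nn[inb]) & nn[inb] <= radius)
      else mean(nn[inb])
    }, numeric(1))
    names(v) <- paste0("bin", bins)
    v
  }
}

#' Null-averaged nearest-neighbor distance per bin
#'
#' The per-bin mean over Monte-Carlo repeats of the statistic stored in
#' the ensemble — for an ensemble built with
#' \code{stat_coexistence(..., what = "nn_dist")} this is the average of
#' the shortest reference-to-partner distances over the random
#' simulations.
#'
#' @param ensemble a \code{null_ensemble} with a computed statistic.
#' @return Named per-bin means.
#' @export
null_mean_nearest_distance <- function(ensemble) {
  if (is.null(ensemble$mean)) stop("ensemble has no computed statistic")
  ensemble$mean
}

#' Compare an observed statistic with its Monte-Carlo null
#'
#' Welch's unequal-variance t-test of the observed values (across neurons
#' or dendrites) against the simulated values (across repeats), as in
#' experimental-vs-simulated per-bin comparisons, plus the empirical rank
#' of the observed mean within the ensemble (rank r of N repeats means r
#' simulated values are below the observed mean).
#'
#' @param observed numeric vector of observed per-unit values (n >= 2).
#' @param null_values numeric vector of per-repeat simulated values
#'   (n >= 2), e.g. one column of \code{ensemble$values}.
#' @return List with \code{t}, \code{df}, \code{p}, \code{observed_mean},
#'   \code{null_mean}, \code{null_sd}, \code{rank}, \code{n_obs},
#'   \code{n_sim}.
#' @export
compare_to_null <- function(observed, null_values) {
  observed <- observed[!is.na(observed)]
  null_values <- null_values[!is.na(null_values)]
  if (length(observed) < 2 || length(null_values) < 2)
    stop("compare_to_null needs n >= 2 observed units and >= 2 repeats")
  w <- welch_compare(observed, null_values)
  list(t = w$t, df = w$df, p = w$p,
       observed_mean = mean(observed),
       null_mean = mean(null_values), null_sd = stats::sd(null_values),
       rank = sum(null_values < mean(observed)),
       n_obs = length(observed), n_sim = length(null_values))
}
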