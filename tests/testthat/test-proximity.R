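make_assigned <- function(g, x, y, z = 0, intensity = 100) {
  assign_spots(make_spots(x, y, z, intensity), g)
}

test_that("spine occupancy uses a closed 600 nm boundary", {
  g <- make_straight_geometry()
  att <- g$branches[[1]]$skeleton[1, 1]
  spine <- make_assigned(g, att + 10000, 900)
  near <- make_assigned(g, att + 10000 + 500, 900)
  occ <- spine_occupancy(near, spine, 600)
  expect_equal(occ$per_spine$n_mrna, 1L)
  far <- make_assigned(g, att + 10000 + 601, 900)
  expect_equal(spine_occupancy(far, spine, 600)$per_spine$n_mrna, 0L)
  at_r <- make_assigned(g, att + 10000 + 600, 900)
  expect_equal(spine_occupancy(at_r, spine, 600)$per_spine$n_mrna, 1L)
})

test_that("per-spine counts match the brute-force pairwise oracle", {
  g <- make_straight_geometry(length_um = 60)
  att <- g$branches[[1]]$skeleton[1, 1]
  set.seed(31)
  spines <- make_assigned(g, att + runif(3, 1000, 59000), runif(3, -900, 900),
                          runif(3, 0, 500))
  mrnas <- make_assigned(g, att + runif(10, 1000, 59000), runif(10, -900, 900),
                         runif(10, 0, 500))
  occ <- spine_occupancy(mrnas, spines, 600)
  expect_equal(occ$per_spine$n_mrna, as.integer(brute_counts(spines, mrnas, 600)))
  # occupancy frequencies per bin sum to 1
  pb <- occ$per_bin
  expect_equal(pb$freq0 + pb$freq1 + pb$freq2plus, rep(1, nrow(pb)))
})

test_that("the null preserves per-bin counts and mask containment in every repeat", {
  g <- make_straight_geometry(length_um = 80)
  att <- g$branches[[1]]$skeleton[1, 1]
  set.seed(9)
  # deliberately uneven observed bins: (3, 0, 2) plus two more distal
  xs <- att + c(5000, 9000, 21000, 51000, 61000, 70000, 74000)
  a <- make_assigned(g, xs, runif(7, -800, 800), runif(7, 0, 400))
  ens <- simulate_null(a, g, n_sim = 25, seed = 4)
  obs_bins <- table(a$bin[a$compartment == "dendrite"])
  hw <- g$branches[[1]]$half_width
  for (sim in ens$sims) {
    expect_identical(table(sim$bin), obs_bins)
    # containment: simulated xy within half-width of the skeleton, and in
    # the same bin as the source pixel
    pr <- dendrofish:::.project_polyline(cbind(sim$x, sim$y),
                                         g$branches[[1]]$skeleton)
    expect_true(all(pr$dist <= hw + g$pixel_size_xy))
    expect_identical(as.integer(bin_index(sim$path_nm)), as.integer(sim$bin))
  }
})

test_that("a single-pixel bin pins the simulated spot and its statistic", {
  g <- make_straight_geometry(length_um = 30, half_width_um = 1)
  att <- g$branches[[1]]$skeleton[1, 1]
  a <- make_assigned(g, att + 5000, 0, 0)
  # restrict the bin-0 mask to one pixel to force the degenerate draw
  m <- g$branches[[1]]$mask
  keep <- bin_index(m$path_nm) != 0L | (m$ix == m$ix[1] & m$iy == m$iy[1])
  first_px <- m[m$ix == m$ix[1] & m$iy == m$iy[1], ]
  g$branches[[1]]$mask <- m[keep, , drop = FALSE]
  stat <- function(sim) c(bin0 = mean(sim$x))
  ens <- simulate_null(a, g, stat, n_sim = 15, seed = 2)
  xs <- vapply(ens$sims, function(s) s$x, numeric(1))
  expect_true(all(abs(xs - first_px$x) <= g$pixel_size_xy / 2))
  # jitter varies but the pixel is fixed
  expect_true(all(vapply(ens$sims, nrow, integer(1)) == 1))
})

test_that("the null refuses to place more spots than pixels", {
  g <- make_straight_geometry(length_um = 30)
  att <- g$branches[[1]]$skeleton[1, 1]
  a <- make_assigned(g, att + c(5000, 5100, 5200), c(0, 100, 200))
  m <- g$branches[[1]]$mask
  g$branches[[1]]$mask <- m[bin_index(m$path_nm) != 0L |
                              (m$ix == m$ix[1] & m$iy == m$iy[1]), ]
  expect_error(simulate_null(a, g, n_sim = 2, seed = 1), "without replacement")
})

test_that("identical seeds reproduce the ensemble exactly", {
  g <- make_straight_geometry(length_um = 40)
  att <- g$branches[[1]]$skeleton[1, 1]
  set.seed(3)
  a <- make_assigned(g, att + runif(12, 500, 39500), runif(12, -800, 800))
  e1 <- simulate_null(a, g, n_sim = 5, seed = 77)
  e2 <- simulate_null(a, g, n_sim = 5, seed = 77)
  expect_identical(e1$sims, e2$sims)
})

test_that("coexistence flags the closed 700 nm boundary and matches enumeration", {
  g <- make_straight_geometry(length_um = 60)
  att <- g$branches[[1]]$skeleton[1, 1]
  ref1 <- make_assigned(g, att + 10000, 0, 0)
  same <- make_assigned(g, att + 10000, 0, 0)
  cx <- coexistence(ref1, same, 700)
  expect_true(cx$per_reference$coexists)
  expect_equal(cx$per_reference$nn_dist, 0)
  at700 <- make_assigned(g, att + 10700, 0, 0)
  expect_true(coexistence(ref1, at700, 700)$per_reference$coexists)
  at701 <- make_assigned(g, att + 10701, 0, 0)
  expect_false(coexistence(ref1, at701, 700)$per_reference$coexists)

  set.seed(41)
  ref <- make_assigned(g, att + runif(5, 1000, 59000), runif(5, -900, 900),
                       runif(5, 0, 300))
  par <- make_assigned(g, att + runif(5, 1000, 59000), runif(5, -900, 900),
                       runif(5, 0, 300))
  cx <- coexistence(ref, par, 700)
  nn_oracle <- vapply(seq_len(5), function(i)
    min(sqrt((par$x - ref$x[i])^2 + (par$y - ref$y[i])^2 + (par$z - ref$z[i])^2)),
    numeric(1))
  expect_equal(cx$per_reference$nn_dist, nn_oracle)
  expect_equal(cx$per_reference$coexists, nn_oracle <= 700)
})

test_that("an empty partner channel is flagged, not an error", {
  g <- make_straight_geometry()
  att <- g$branches[[1]]$skeleton[1, 1]
  ref <- make_assigned(g, att + c(5000, 15000), c(0, 0))
  empty <- make_assigned(g, numeric(0), numeric(0))
  cx <- coexistence(ref, empty, 700)
  expect_true(cx$partner_empty)
  expect_true(all(!cx$per_reference$coexists))
  expect_true(all(is.na(cx$per_reference$nn_dist)))
})

test_that("null mean nearest distance matches dense pixel quadrature", {
  # one simulated partner spot per repeat, one fixed reference: the null
  # mean distance is the mask average of distance-to-reference
  g <- make_straight_geometry(length_um = 25)
  att <- g$branches[[1]]$skeleton[1, 1]
  ref <- make_assigned(g, att + 9000, 200, 0)
  partner_obs <- make_assigned(g, att + 3000, 0, 0)
  stat <- stat_coexistence(ref, 700, bins = 0, what = "nn_dist")
  ens <- simulate_null(partner_obs, g, stat, n_sim = 400, seed = 12, z_mode = "zero")
  m <- g$branches[[1]]$mask
  quad <- mean(sqrt((m$x - ref$x)^2 + (m$y - ref$y)^2))
  se <- ens$sd[1] / sqrt(ens$n_sim)
  expect_lt(abs(null_mean_nearest_distance(ens)[["bin0"]] - quad), 3 * se + 5)
})

test_that("the SE of the null mean shrinks as 1/sqrt(n_sim)", {
  g <- make_straight_geometry(length_um = 25)
  att <- g$branches[[1]]$skeleton[1, 1]
  ref <- make_assigned(g, att + 9000, 200, 0)
  partner_obs <- make_assigned(g, att + 3000, 0, 0)
  stat <- stat_coexistence(ref, 700, bins = 0, what = "nn_dist")
  se_of <- function(n_sim, seed) {
    e <- simulate_null(partner_obs, g, stat, n_sim = n_sim, seed = seed,
                       z_mode = "zero")
    e$sd[1] / sqrt(e$n_sim)
  }
  # quadrupling the repeats halves the standard error
  ratio <- se_of(100, 5) / se_of(400, 6)
  expect_gt(ratio, 2 * 0.8)
  expect_lt(ratio, 2 * 1.2)
})

test_that("compare_to_null returns p = 1 when observed sits at the null mean", {
  null_vals <- c(0.4, 0.4, 0.4, 0.4)
  obs <- c(0.4, 0.4, 0.4)
  r <- compare_to_null(obs, null_vals)
  expect_equal(r$p, 1)
  expect_equal(r$t, 0)
  expect_error(compare_to_null(0.4, null_vals), "n >= 2")
})
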