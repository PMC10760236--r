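test_that("generated neurons honor the requested morphology", {
  cfg <- synthetic_config(n_branches = 4, branch_length_um = 40)
  n <- generate_neuron(cfg, seed = 1)
  expect_length(n$geometry$branches, 4)
  for (b in n$geometry$branches)
    expect_equal(dendrofish:::.polyline_length(b$skeleton), 40000, tolerance = 1e-6)
  expect_error(synthetic_config(branch_length_um = 0.5, half_width_um = 1))

  cfg0 <- synthetic_config(spine_density_per_um = 0)
  expect_equal(nrow(generate_neuron(cfg0, seed = 2)$spines), 0)
})

test_that("spine counts follow the Poisson process rate", {
  cfg <- synthetic_config(n_branches = 2, branch_length_um = 50,
                          spine_density_per_um = 0.8)
  counts <- vapply(1:100, function(s) nrow(generate_neuron(cfg, s)$spines),
                   numeric(1))
  lambda <- 0.8 * 100  # density x total skeleton length
  # mean of 100 Poisson draws: within 4 SE of the rate
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 100))
})

test_that("zero rates give empty spot tables", {
  cfg <- synthetic_config(mrna_per_branch = 0, soma_mrna = 0, n_ts = 0)
  n <- generate_neuron(cfg, 1)
  pm <- place_mrnas(n, cfg, 1)
  expect_equal(nrow(pm$spots), 0)
  expect_equal(nrow(pm$truth), 0)
})

test_that("synthetic generation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_branches = 2, branch_length_um = 30,
                          mrna_per_branch = 20, soma_mrna = 20)
  d1 <- simulate_dataset(cfg, seed = 5)
  d2 <- simulate_dataset(cfg, seed = 5)
  expect_identical(d1$mrna, d2$mrna)
  expect_identical(d1$partner, d2$partner)
  expect_identical(d1$peptide, d2$peptide)
  expect_identical(d1$neuron$spines, d2$neuron$spines)
  d3 <- simulate_dataset(cfg, seed = 6)
  expect_false(identical(d1$mrna$spots$x, d3$mrna$spots$x))
})

test_that("flat density places dendritic mRNAs uniformly per unit area", {
  cfg <- synthetic_config(n_branches = 1, branch_length_um = 75,
                          mrna_per_branch = 60, soma_mrna = 0, n_ts = 0,
                          decay_tau_um = Inf, spine_density_per_um = 0)
  n <- generate_neuron(cfg, 1)
  areas <- vapply(0:2, function(k) nrow(bin_mask(n$geometry, 1, k)), numeric(1))
  obs <- rep(0, 3)
  for (s in 1:30) {
    tr <- place_mrnas(n, cfg, s)$truth
    obs <- obs + tabulate(tr$bin + 1L, 3)
  }
  gof <- chisq.test(obs, p = areas / sum(areas))
  expect_gt(gof$p.value, 0.001)
})

test_that("full coexistence enrichment plants every partner near a reference", {
  cfg <- synthetic_config(n_branches = 2, branch_length_um = 50,
                          mrna_per_branch = 40, partner_per_branch = 10,
                          coexistence_enrichment = 1, loc_error_nm = 0)
  ds <- simulate_dataset(cfg, seed = 9)
  expect_true(all(!is.na(ds$partner$truth$partner_of)))
  # every emitted partner lies within the coexistence radius of its reference
  ref <- ds$mrna$spots
  idx <- match(ds$partner$truth$partner_of, ref$id)
  d <- sqrt((ds$partner$spots$x - ref$x[idx])^2 +
            (ds$partner$spots$y - ref$y[idx])^2 +
            (ds$partner$spots$z - ref$z[idx])^2)
  expect_true(all(d <= 700 + 1e-9))
})

test_that("noise-free translation channels round-trip exactly", {
  cfg <- synthetic_config(n_branches = 2, branch_length_um = 50,
                          mrna_per_branch = 40, soma_mrna = 40, n_ts = 0,
                          intensity_cv = 0, loc_error_nm = 0,
                          n_free_peptides = 0, p_translating = 0.4)
  n <- generate_neuron(cfg, 3)
  pm <- place_mrnas(n, cfg, 3)
  tc <- emit_translation_channels(pm$spots, n, cfg, 3)
  calls <- assign_peptides(pm$spots, tc$spots, 200, unit = cfg$unit_intensity)
  expect_equal(calls$mrnas$translating[order(calls$mrnas$mrna_id)],
               tc$truth$translating[order(tc$truth$mrna_id)])
  idx <- match(calls$pairs$mrna_id, tc$truth$mrna_id)
  expect_equal(calls$pairs$n_peptides, as.integer(tc$truth$ribosomes[idx]))
})

test_that("no mRNA-adjacent peptides appear when translation is off", {
  cfg <- synthetic_config(n_branches = 1, branch_length_um = 40,
                          mrna_per_branch = 30, p_translating = 0,
                          n_free_peptides = 20)
  n <- generate_neuron(cfg, 4)
  pm <- place_mrnas(n, cfg, 4)
  tc <- emit_translation_channels(pm$spots, n, cfg, 4)
  expect_true(all(is.na(tc$truth$peptide_id)))
  expect_false(any(tc$truth$translating))
})

test_that("the emitted chromatic offset is undone by the matching correction", {
  base <- synthetic_config(n_branches = 1, branch_length_um = 40,
                           mrna_per_branch = 30, n_free_peptides = 30)
  delta <- c(90, -40, 120)
  shifted <- do.call(synthetic_config, utils::modifyList(
    lapply(unclass(base), identity), list(chromatic_offset = delta)))
  n <- generate_neuron(base, 6)
  pm <- place_mrnas(n, base, 6)
  t0 <- emit_translation_channels(pm$spots, n, base, 6)
  t1 <- emit_translation_channels(pm$spots, n, shifted, 6)
  expect_equal(t1$spots$x, t0$spots$x + delta[1])
  c0 <- assign_peptides(pm$spots, t0$spots, 200, unit = 100)
  c1 <- assign_peptides(pm$spots, t1$spots, 200, chromatic_offset = delta, unit = 100)
  expect_equal(c1$pairs, c0$pairs)
})
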