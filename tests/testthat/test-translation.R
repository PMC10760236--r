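test_that("unit peptide intensity is the median of free spots", {
  mr <- make_spots(x = c(0, 1000), y = c(0, 0))
  pe <- make_spots(x = seq(5000, 5000 + 24 * 200, by = 200), y = rep(0, 25),
                   intensity = rep(100, 25))
  u <- estimate_unit_intensity(pe, mr, 200)
  expect_equal(u$value, 100)
  expect_equal(u$n_spots, 25)

  # robust to a bright aggregate among the free spots
  pe2 <- make_spots(x = seq(5000, 5000 + 23 * 200, by = 200), y = rep(0, 24),
                    intensity = c(rep(c(90, 100, 110), 7), 90, 100, 1000))
  expect_equal(estimate_unit_intensity(pe2, mr, 200)$value, 100)

  few <- make_spots(x = seq(5000, 6000, length.out = 5), y = rep(0, 5))
  expect_error(estimate_unit_intensity(few, mr, 200), "calibration error")
})

test_that("nascent peptide counts round to the nearest unit, minimum 1", {
  expect_equal(nascent_count(100, 100), 1L)
  expect_equal(nascent_count(360, 100), 4L)
  expect_equal(nascent_count(20, 100), 1L)
  expect_equal(nascent_count((1:30) * 100, 100), 1:30)
})

test_that("peptides pair with the closest mRNA within the widened threshold", {
  m <- make_spots(0, 0)
  close <- make_spots(150, 0)
  calls <- assign_peptides(m, close, 200)
  expect_true(calls$mrnas$translating)
  expect_equal(calls$pairs$distance_nm, 150)

  far <- make_spots(250, 0)
  calls <- assign_peptides(m, far, 200)
  expect_false(calls$mrnas$translating)
  expect_equal(calls$free_peptides, 1L)

  # residual aberration widens the threshold
  calls <- assign_peptides(m, far, 200, chromatic_residual = 60)
  expect_true(calls$mrnas$translating)
})

test_that("dedupe keeps the brightest candidate peptide, then the closest", {
  m <- make_spots(0, 0)
  peps <- make_spots(x = c(180, 50), y = c(0, 0), intensity = c(300, 100))
  calls <- assign_peptides(m, peps, 200)
  expect_equal(calls$pairs$peptide_id, 1L)   # the 300-AU spot at 180 nm
  expect_equal(calls$pairs$peptide_intensity, 300)

  # intensity tie: the closer peptide wins
  peps <- make_spots(x = c(180, 50), y = c(0, 0), intensity = c(100, 100))
  expect_equal(assign_peptides(m, peps, 200)$pairs$peptide_id, 2L)
})

test_that("empty mRNA tables leave every peptide free", {
  m <- make_spots(numeric(0), numeric(0))
  peps <- make_spots(c(0, 100), c(0, 0))
  calls <- assign_peptides(m, peps, 200)
  expect_equal(nrow(calls$pairs), 0)
  expect_equal(sort(calls$free_peptides), c(1L, 2L))
  expect_error(assign_peptides(make_spots(0, 0), peps, -5), "negative threshold")
})

test_that("pairing equals the exhaustive oracle on random small instances", {
  set.seed(61)
  for (rep in 1:200) {
    nm <- sample(0:8, 1); np <- sample(0:8, 1)
    m <- make_spots(runif(nm, 0, 2000), runif(nm, 0, 2000), runif(nm, 0, 400))
    p <- make_spots(runif(np, 0, 2000), runif(np, 0, 2000), runif(np, 0, 400),
                    intensity = sample(c(100, 200, 300), np, replace = TRUE))
    calls <- assign_peptides(m, p, 500)
    oracle <- brute_assign(m, p, 500)
    got <- calls$pairs[order(calls$pairs$mrna_id), c("mrna_id", "peptide_id")]
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
    # partial matching: no mRNA or peptide appears twice
    expect_false(anyDuplicated(calls$pairs$mrna_id) > 0)
    expect_false(anyDuplicated(calls$pairs$peptide_id) > 0)
  }
})

test_that("percent translating is monotone in the threshold", {
  set.seed(71)
  m <- make_spots(runif(30, 0, 10000), runif(30, 0, 10000))
  p <- make_spots(runif(30, 0, 10000), runif(30, 0, 10000))
  pct <- vapply(c(100, 300, 600, 1200, 2400), function(thr)
    percent_translating(assign_peptides(m, p, thr)), numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("chromatic offset correction is exact", {
  set.seed(81)
  m <- make_spots(runif(10, 0, 5000), runif(10, 0, 5000), runif(10, 0, 400))
  p <- make_spots(runif(10, 0, 5000), runif(10, 0, 5000), runif(10, 0, 400),
                  intensity = runif(10, 80, 300))
  base <- assign_peptides(m, p, 300)
  delta <- c(120, -80, 40)
  p_shift <- make_spots(p$x + delta[1], p$y + delta[2], p$z + delta[3],
                        intensity = p$intensity)
  shifted <- assign_peptides(m, p_shift, 300, chromatic_offset = delta)
  expect_equal(shifted$pairs, base$pairs)
  expect_equal(shifted$mrnas, base$mrnas)
})

test_that("percent translating covers cell and dendrite scopes", {
  g <- make_straight_geometry()
  att <- g$branches[[1]]$skeleton[1, 1]
  m <- make_spots(att + c(5000, 6000, 30000, 31000), rep(0, 4))
  a <- assign_spots(m, g)
  p <- make_spots(att + c(5000, 30000) + 100, c(0, 0))
  calls <- assign_peptides(m, p, 200)
  expect_equal(percent_translating(calls), 50)
  per_br <- percent_translating(calls, "dendrite", assignment = a)
  expect_equal(per_br$percent, 50)
  none <- assign_peptides(m, make_spots(numeric(0), numeric(0)), 200)
  expect_equal(percent_translating(none), 0)
  all_tr <- assign_peptides(m, make_spots(m$x + 50, m$y), 200)
  expect_equal(percent_translating(all_tr), 100)
})
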