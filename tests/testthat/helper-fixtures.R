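# Shared fixtures: small geometries and spot tables built in code.

# Square soma (side um) centered at the origin with one straight
# horizontal dendrite to the right.
make_straight_geometry <- function(length_um = 50, half_width_um = 1,
                                   soma_side_um = 10, px = 107.5,
                                   n_branches = 1) {
  h <- soma_side_um * 1000 / 2
  soma <- rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h), c(-h, -h))
  L <- length_um * 1000
  branches <- list(
    list(skeleton = rbind(c(h, 0), c(h + L, 0)), half_width = half_width_um * 1000))
  if (n_branches >= 2)
    branches[[2]] <- list(skeleton = rbind(c(-h, 0), c(-h - L, 0)),
                          half_width = half_width_um * 1000)
  neuron_geometry(soma, branches, pixel_size_xy = px)
}

make_spots <- function(x, y, z = 0, intensity = 100, channel = "test") {
  spot_table(x, y, z, intensity, channel_label = channel)
}

# Brute-force O(n*m) proximity counts: for each anchor the number of
# points within radius (3D Euclidean, closed boundary).
brute_counts <- function(anchors, pts, radius) {
  vapply(seq_len(nrow(anchors)), function(i) {
    d <- sqrt((pts$x - anchors$x[i])^2 + (pts$y - anchors$y[i])^2 +
              (pts$z - anchors$z[i])^2)
    sum(d <= radius)
  }, numeric(1))
}

# Reference implementation of the peptide-to-mRNA pairing rules by plain
# enumeration over the full distance matrix, independent of the package's
# code path.
brute_assign <- function(mrnas, peptides, thr) {
  if (nrow(mrnas) == 0 || nrow(peptides) == 0)
    return(data.frame(mrna_id = integer(0), peptide_id = integer(0)))
  kept <- list()
  prov <- list()
  for (j in seq_len(nrow(peptides))) {
    d <- sqrt((mrnas$x - peptides$x[j])^2 + (mrnas$y - peptides$y[j])^2 +
              (mrnas$z - peptides$z[j])^2)
    i <- which.min(d)
    if (d[i] <= thr)
      prov[[length(prov) + 1L]] <- data.frame(
        mrna_id = mrnas$id[i], peptide_id = peptides$id[j],
        dist = d[i], int = peptides$intensity[j])
  }
  if (!length(prov)) return(data.frame(mrna_id = integer(0), peptide_id = integer(0)))
  prov <- do.call(rbind, prov)
  for (m in sort(unique(prov$mrna_id))) {
    cand <- prov[prov$mrna_id == m, , drop = FALSE]
    cand <- cand[cand$int == max(cand$int), , drop = FALSE]
    cand <- cand[cand$dist == min(cand$dist), , drop = FALSE]
    cand <- cand[which.min(cand$peptide_id), , drop = FALSE]
    kept[[length(kept) + 1L]] <- cand[, c("mrna_id", "peptide_id")]
  }
  out <- do.call(rbind, kept)
  out[order(out$mrna_id), , drop = FALSE]
}
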