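#' Neuron geometry
#'
#' Builds the morphology model used by every spatial statistic: a closed
#' soma polygon plus dendrite branches, each branch a skeleton polyline
#' ordered from the soma outward with a half-width. Branch masks are
#' rasterized at the image pixel size; each mask pixel carries the arc
#' length (path distance, nm) from the soma attachment point to its
#' orthogonal projection onto the skeleton. All coordinates are nm.
#'
#' @param soma n x 2 matrix of soma polygon vertices (nm). The ring must be
#'   explicitly closed (first vertex repeated as the last); it is stored
#'   unduplicated.
#' @param branches list of branches, each a list with \code{skeleton}
#'   (m x 2 matrix, nm, ordered from soma outward) and \code{half_width}
#'   (scalar nm).
#' @param pixel_size_xy rasterization pixel size, nm.
#' @return An object of class \code{neuron_geometry} with rasterized
#'   \code{soma_mask} and per-branch \code{mask} data frames
#'   (columns ix, iy, x, y, path_nm).
#' @export
neuron_geometry <- function(soma, branches = list(), pixel_size_xy = 107.5) {
  soma <- as.matrix(soma)
  stopifnot(ncol(soma) == 2, nrow(soma) >= 4)
  if (!isTRUE(all.equal(soma[1, ], soma[nrow(soma), ], check.attributes = FALSE)))
    stop("geometry error: soma polygon is not closed (first vertex must be repeated last)")
  soma <- soma[-nrow(soma), , drop = FALSE]
  if (.polygon_self_intersects(soma))
    stop("geometry error: soma polygon is self-intersecting")
  if (.polygon_area(soma) <= 0)
    stop("geometry error: soma polygon has zero area")

  branches <- lapply(seq_along(branches), function(b) {
    br <- branches[[b]]
    skel <- as.matrix(br$skeleton)
    stopifnot(ncol(skel) == 2, nrow(skel) >= 2)
    hw <- br$half_width
    stopifnot(length(hw) == 1, hw > 0)
    # attachment point must lie on the soma boundary (within one pixel)
    ring <- rbind(soma, soma[1, ])
    pr <- .project_polyline(skel[1, , drop = FALSE], ring)
    if (pr$dist > pixel_size_xy) {
      att <- .nearest_ring_point(skel[1, ], ring)
      warning(sprintf("branch %d: first vertex is %.0f nm from the soma boundary; prepending nearest boundary point", b, pr$dist))
      skel <- rbind(att, skel)
    }
    if (.polyline_length(skel) <= 0) stop("geometry error: zero-length branch skeleton")
    list(skeleton = skel, half_width = hw)
  })

  g <- structure(list(soma = soma, branches = branches,
                      pixel_size_xy = pixel_size_xy),
                 class = "neuron_geometry")
  g$soma_mask <- .rasterize_soma(g)
  for (b in seq_along(g$branches))
    g$branches[[b]]$mask <- .rasterize_branch(g, b)
  g
}

.nearest_ring_point <- function(p, ring) {
  best <- NULL; bd <- Inf
  for (s in seq_len(nrow(ring) - 1L)) {
    p1 <- ring[s, ]; d <- ring[s + 1L, ] - p1
    len2 <- sum(d^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((p - p1) * d) / len2))
    q <- p1 + t * d
    dd <- sum((p - q)^2)
    if (dd < bd) { bd <- dd; best <- q }
  }
  best
}

.rasterize_soma <- function(g) {
  px <- g$pixel_size_xy
  rng_x <- range(g$soma[, 1]); rng_y <- range(g$soma[, 2])
  ix <- seq(floor(rng_x[1] / px) - 1L, ceiling(rng_x[2] / px) + 1L)
  iy <- seq(floor(rng_y[1] / px) - 1L, ceiling(rng_y[2] / px) + 1L)
  grid <- expand.grid(ix = ix, iy = iy)
  cx <- (grid$ix + 0.5) * px; cy <- (grid$iy + 0.5) * px
  keep <- .in_polygon(cx, cy, g$soma)
  data.frame(ix = grid$ix[keep], iy = grid$iy[keep],
             x = cx[keep], y = cy[keep])
}

# Candidate pixels are gathered per <=5 um skeleton chunk (tight bounding
# boxes even for oblique branches), then projected against the full skeleton.
.rasterize_branch <- function(g, b) {
  px <- g$pixel_size_xy
  br <- g$branches[[b]]
  skel <- br$skeleton; hw <- br$half_width
  pad <- hw + px
  cand <- list()
  for (s in seq_len(nrow(skel) - 1L)) {
    p1 <- skel[s, ]; p2 <- skel[s + 1L, ]
    len <- sqrt(sum((p2 - p1)^2))
    nchunk <- max(1L, ceiling(len / 5000))
    ts <- seq(0, 1, length.out = nchunk + 1L)
    for (k in seq_len(nchunk)) {
      a <- p1 + ts[k] * (p2 - p1); bb <- p1 + ts[k + 1L] * (p2 - p1)
      ix <- seq(floor((min(a[1], bb[1]) - pad) / px), ceiling((max(a[1], bb[1]) + pad) / px))
      iy <- seq(floor((min(a[2], bb[2]) - pad) / px), ceiling((max(a[2], bb[2]) + pad) / px))
      cand[[length(cand) + 1L]] <- expand.grid(ix = ix, iy = iy)
    }
  }
  cand <- unique(do.call(rbind, cand))
  cx <- (cand$ix + 0.5) * px; cy <- (cand$iy + 0.5) * px
  pr <- .project_polyline(cbind(cx, cy), skel)
  keep <- pr$dist <= hw & !.in_polygon(cx, cy, g$soma)
  data.frame(ix = cand$ix[keep], iy = cand$iy[keep],
             x = cx[keep], y = cy[keep], path_nm = pr$arc[keep])
}

#' @export
print.neuron_geometry <- function(x, ...) {
  cat("Neuron geometry\n")
  cat(sprintf("  soma: %d vertices, %d mask pixels\n",
              nrow(x$soma), nrow(x$soma_mask)))
  for (b in seq_along(x$branches)) {
    br <- x$branches[[b]]
    cat(sprintf("  branch %d: length %.1f um, half-width %.2f um, %d mask pixels\n",
                b, .polyline_length(br$skeleton) / 1000, br$half_width / 1000,
                nrow(br$mask)))
  }
  cat(sprintf("  pixel size %g nm\n", x$pixel_size_xy))
  invisible(x)
}

#' Assign spots to compartments and dendrite bins
#'
#' Each spot is classified as soma (inside the soma polygon), dendrite
#' (within half-width of a branch skeleton; the nearest branch wins, ties
#' to the lower branch index), or outside. Dendritic spots get the arc
#' length from the soma attachment to their orthogonal projection onto the
#' skeleton as path distance, and a 0-based bin index
#' \code{floor(path / bin_width)}. Soma spots have path distance 0 and no
#' bin. Outside spots take part in no statistic and are reported for QC.
#'
#' @param spots a \code{spot_table} (or data frame with x, y, z, intensity, id).
#' @param geometry a \code{neuron_geometry}.
#' @param bin_width bin width in nm (default 25000).
#' @param slack extra membership margin in nm added to the branch
#'   half-width. Use 0 (default) for mRNA channels; for spine centers,
#'   which sit at or just beyond the shaft edge (the postsynaptic density
#'   caps the spine head), pass the spine-proximity radius so edge
#'   anchors keep their branch and path distance.
#' @return A \code{binned_assignment}: the spot table plus columns
#'   \code{compartment}, \code{branch}, \code{path_nm}, \code{bin}.
#' @export
assign_spots <- function(spots, geometry, bin_width = 25000, slack = 0) {
  stopifnot(inherits(geometry, "neuron_geometry"), bin_width > 0)
  df <- as.data.frame(spots)
  n <- nrow(df)
  comp <- rep("outside", n)
  branch <- rep(NA_integer_, n)
  path <- rep(NA_real_, n)
  if (n > 0) {
    in_soma <- .in_polygon(df$x, df$y, geometry$soma)
    comp[in_soma] <- "soma"
    path[in_soma] <- 0
    rest <- which(!in_soma)
    if (length(rest)) {
      nb <- length(geometry$branches)
      dmat <- matrix(Inf, length(rest), max(nb, 1L))
      amat <- matrix(NA_real_, length(rest), max(nb, 1L))
      for (b in seq_len(nb)) {
        pr <- .project_polyline(cbind(df$x[rest], df$y[rest]),
                                geometry$branches[[b]]$skeleton)
        ok <- pr$dist <= geometry$branches[[b]]$half_width + slack
        dmat[ok, b] <- pr$dist[ok]
        amat[ok, b] <- pr$arc[ok]
      }
      hit <- which(apply(dmat, 1, min) < Inf)
      for (i in hit) {
        d <- dmat[i, ]
        # ties (within 1e-9 nm) resolve to the lowest branch index
        bsel <- which(d <= min(d) + 1e-9)[1L]
        comp[rest[i]] <- "dendrite"
        branch[rest[i]] <- bsel
        path[rest[i]] <- amat[i, bsel]
      }
    }
  }
  bin <- ifelse(comp == "dendrite", bin_index(ifelse(is.na(path), 0, path), bin_width), NA_integer_)
  bin[comp != "dendrite"] <- NA_integer_
  out <- cbind(df, data.frame(compartment = comp, branch = branch,
                              path_nm = path, bin = as.integer(bin)))
  structure(out, class = c("binned_assignment", "data.frame"),
            bin_width = bin_width,
            channel = attr(spots, "channel"), cell_id = attr(spots, "cell_id"))
}

#' Dendrite bin index from path distance
#'
#' Half-open 25 um intervals: bin k covers path distances in
#' \code{[k * bin_width, (k + 1) * bin_width)}, so bin 0 is 0-25 um from
#' the soma.
#'
#' @param path_distance path distance from the soma, nm (vectorized).
#' @param bin_width bin width, nm.
#' @return Integer 0-based bin indices.
#' @export
bin_index <- function(path_distance, bin_width = 25000) {
  if (any(path_distance < 0)) stop("domain error: negative path distance")
  stopifnot(bin_width > 0)
  as.integer(floor(path_distance / bin_width))
}

#' Per-bin pixel mask of a branch
#'
#' The subset of a branch's mask pixels whose skeleton-projection path
#' distance falls in bin \code{k}. Over k the bin masks partition the
#' branch mask.
#'
#' @param geometry a \code{neuron_geometry}.
#' @param branch branch index.
#' @param k 0-based bin index.
#' @param bin_width bin width, nm.
#' @return Data frame of mask pixels (possibly empty).
#' @export
bin_mask <- function(geometry, branch, k, bin_width = 25000) {
  m <- geometry$branches[[branch]]$mask
  m[bin_index(m$path_nm, bin_width) == k, , drop = FALSE]
}

#' Compartment area in mask pixels
#'
#' @param geometry a \code{neuron_geometry}.
#' @param compartment \code{"soma"}, \code{"dendrite"} (all branches), or a
#'   branch index.
#' @return Pixel count.
#' @export
compartment_area <- function(geometry, compartment = c("soma", "dendrite")) {
  if (is.numeric(compartment))
    return(nrow(geometry$branches[[compartment]]$mask))
  compartment <- match.arg(compartment)
  if (compartment == "soma") nrow(geometry$soma_mask)
  else sum(vapply(geometry$branches, function(b) nrow(b$mask), integer(1)))
}

#' @export
print.binned_assignment <- function(x, ...) {
  cat(sprintf("Binned spot assignment (%d spots, bin width %g um)\n",
              nrow(x), attr(x, "bin_width") / 1000))
  print(table(factor(x$compartment, levels = c("soma", "dendrite", "outside"))))
  invisible(x)
}
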