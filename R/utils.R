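# Internal geometry / numeric helpers shared across modules.

# Orthogonal projection of 2D points onto a polyline.
# pts: n x 2 matrix (nm); skel: m x 2 matrix of ordered vertices (nm).
# Returns per point the Euclidean distance to the polyline and the arc
# length (nm) from the first vertex to the projection foot. Ties between
# segments resolve to the smaller arc length.
.project_polyline <- function(pts, skel) {
  n <- nrow(pts)
  if (n == 0L) return(list(dist = numeric(0), arc = numeric(0)))
  stopifnot(nrow(skel) >= 2L)
  best_d2 <- rep(Inf, n)
  best_arc <- rep(NA_real_, n)
  cum <- c(0, cumsum(sqrt(rowSums(diff(skel)^2))))
  for (s in seq_len(nrow(skel) - 1L)) {
    p1 <- skel[s, ]; p2 <- skel[s + 1L, ]
    d <- p2 - p1
    len2 <- sum(d^2)
    if (len2 == 0) next
    t <- ((pts[, 1] - p1[1]) * d[1] + (pts[, 2] - p1[2]) * d[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (p1[1] + t * d[1])
    dy <- pts[, 2] - (p1[2] + t * d[2])
    d2 <- dx * dx + dy * dy
    arc <- cum[s] + t * sqrt(len2)
    upd <- d2 < best_d2 - 1e-9 | (abs(d2 - best_d2) <= 1e-9 & arc < best_arc)
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      best_arc[upd] <- arc[upd]
    }
  }
  list(dist = sqrt(best_d2), arc = best_arc)
}

.polyline_length <- function(skel) sum(sqrt(rowSums(diff(skel)^2)))

# Signed area by the shoelace formula; vertices as n x 2 ring (unclosed).
.polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}

.in_polygon <- function(x, y, poly) {
  as.logical(pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE))
}

# Proper-intersection test for polygon self-intersection (non-adjacent edges).
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), ])
  ccw <- function(ax, ay, bx, by, cx, cy) (by - ay) * (cx - ax) - (bx - ax) * (cy - ay)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges sharing a vertex
    for (j in js) {
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- ccw(a[1], a[2], a[3], a[4], b[1], b[2])
      d2 <- ccw(a[1], a[2], a[3], a[4], b[3], b[4])
      d3 <- ccw(b[1], b[2], b[3], b[4], a[1], a[2])
      d4 <- ccw(b[1], b[2], b[3], b[4], a[3], a[4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

# Pairwise Euclidean distance matrix between rows of a (n x k) and b (m x k).
.cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(numeric(0), nrow(a), nrow(b)))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# 8-connected component labelling of a logical matrix (iterative BFS).
# EBImage::bwlabel is 4-connected, hence this small labeller.
.label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbr <- expand.grid(di = -1:1, dj = -1:1)
  nbr <- nbr[!(nbr$di == 0 & nbr$dj == 0), ]
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[1L]; queue <- queue[-1L]
      i <- ((q - 1L) %% nr) + 1L
      j <- ((q - 1L) %/% nr) + 1L
      ii <- i + nbr$di; jj <- j + nbr$dj
      ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
      lin <- (jj[ok] - 1L) * nr + ii[ok]
      lin <- lin[mask[lin] & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- cur
        queue <- c(queue, lin)
      }
    }
  }
  lab
}

# Derived RNG streams: one root seed, per-unit offsets so unit order does
# not change results. Kept below 2^31 - 1.
.derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(counter) * 16807) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
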