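# Planar polyline helpers shared by the generator, GNSS repair and
# segmentation. All coordinates are local metric (east, north).

polyline_matrix <- function(polyline) {
  m <- as.matrix(polyline[, c("east", "north")])
  storage.mode(m) <- "double"
  m
}

polyline_cumlen <- function(poly) {
  m <- polyline_matrix(poly)
  seg <- sqrt(rowSums(diff(m)^2))
  c(0, cumsum(seg))
}

# Point at arc-length s (clamped to the polyline extent).
point_at_arclength <- function(poly, s) {
  m <- polyline_matrix(poly)
  cl <- polyline_cumlen(poly)
  s <- pmin(pmax(s, 0), cl[length(cl)])
  i <- findInterval(s, cl, rightmost.closed = TRUE)
  i <- pmin(i, nrow(m) - 1L)
  seg_len <- cl[i + 1L] - cl[i]
  frac <- ifelse(seg_len > 0, (s - cl[i]) / seg_len, 0)
  cbind(east = m[i, 1] + frac * (m[i + 1L, 1] - m[i, 1]),
        north = m[i, 2] + frac * (m[i + 1L, 2] - m[i, 2]))
}

# Orthogonal projection of points (n x 2) onto the polyline; returns the
# projected coordinates, their arc-length and the distance to the line.
project_points_polyline <- function(pts, poly) {
  m <- polyline_matrix(poly)
  cl <- polyline_cumlen(poly)
  pts <- as.matrix(pts)
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  best_pt <- matrix(0, n, 2)
  best_s <- numeric(n)
  for (k in seq_len(nrow(m) - 1L)) {
    a <- m[k, ]
    b <- m[k + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) next
    tt <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    tt <- pmin(pmax(tt, 0), 1)
    px <- a[1] + tt * ab[1]
    py <- a[2] + tt * ab[2]
    d2 <- (pts[, 1] - px)^2 + (pts[, 2] - py)^2
    hit <- d2 < best_d2
    best_d2[hit] <- d2[hit]
    best_pt[hit, 1] <- px[hit]
    best_pt[hit, 2] <- py[hit]
    best_s[hit] <- cl[k] + tt[hit] * sqrt(len2)
  }
  list(point = best_pt, arclength = best_s, distance = sqrt(best_d2))
}
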