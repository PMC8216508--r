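# Plain-matrix polygon and polyline geometry (coordinates in nm unless noted).
# Polygons are n x 2 matrices of vertices in order, implicitly closed.

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_perimeter <- function(poly) {
  xs <- rbind(poly, poly[1, , drop = FALSE])
  sum(sqrt(rowSums(diff(xs)^2)))
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  a <- sum(cr) / 2
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

# Ray-casting point-in-polygon; boundary points count as inside.
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

# Distance from points (px, py) to a polyline (n x 2); minimum over segments.
dist_point_polyline <- function(px, py, pts) {
  if (nrow(pts) == 1) {
    return(sqrt((px - pts[1, 1])^2 + (py - pts[1, 2])^2))
  }
  d <- rep(Inf, length(px))
  for (k in seq_len(nrow(pts) - 1)) {
    d <- pmin(d, dist_point_segment(px, py,
                                    pts[k, 1], pts[k, 2],
                                    pts[k + 1, 1], pts[k + 1, 2]))
  }
  d
}

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Uniform sampling of n points inside a polygon by bounding-box rejection.
sample_in_polygon <- function(n, poly, max_tries = 10000) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  bb <- c(range(poly[, 1]), range(poly[, 2]))
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  for (i in seq_len(max_tries)) {
    m <- max(2L * (n - got), 32L)
    cand_x <- runif(m, bb[1], bb[2])
    cand_y <- runif(m, bb[3], bb[4])
    keep <- point_in_polygon(cand_x, cand_y, poly)
    k <- min(sum(keep), n - got)
    if (k > 0) {
      sel <- which(keep)[seq_len(k)]
      out[(got + 1):(got + k), ] <- cbind(cand_x[sel], cand_y[sel])
      got <- got + k
    }
    if (got == n) return(out)
  }
  abort("sample_in_polygon: rejection sampling failed (degenerate polygon?)")
}
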