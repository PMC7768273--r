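# small computational-geometry kernel used by the NRt scorer: proper segment
# crossings (orientation tests) and convex polygons with boundary-inclusive
# membership. Hulls come from grDevices::chull; everything here is 2-D.

orient <- function(ax, ay, bx, by, cx, cy) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  sign(v)
}

# proper crossing of segments p1-p2 and p3-p4; returns c(x, y) or NULL.
# Touching endpoints / collinear overlap do not count as a crossing.
segment_crossing <- function(p1, p2, p3, p4) {
  d1 <- orient(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- orient(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- orient(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- orient(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (d1 * d2 < 0 && d3 * d4 < 0) {
    # solve p1 + t (p2-p1) = p3 + u (p4-p3)
    rx <- p2[1] - p1[1]; ry <- p2[2] - p1[2]
    sx <- p4[1] - p3[1]; sy <- p4[2] - p3[2]
    den <- rx * sy - ry * sx
    t <- ((p3[1] - p1[1]) * sy - (p3[2] - p1[2]) * sx) / den
    return(c(p1[1] + t * rx, p1[2] + t * ry))
  }
  NULL
}

# convex polygon from a point cloud; vertices counter-clockwise, not closed
convex_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  h <- grDevices::chull(x, y)       # clockwise order
  h <- rev(h)                       # counter-clockwise
  tibble::tibble(x = x[h], y = y[h])
}

# boundary counts as inside (ties-at-edges rule); `strict` for open interior
point_in_polygon <- function(px, py, poly, strict = FALSE, eps = 1e-12) {
  n <- nrow(poly)
  vx <- poly$x; vy <- poly$y
  scale <- max(abs(c(vx, vy, 1)))
  tol <- eps * scale^2
  res <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    res <- res & if (strict) cr > tol else cr >= -tol
  }
  res
}

polygon_centroid <- function(poly) c(x = mean(poly$x), y = mean(poly$y))

polygons_overlap <- function(a, b) {
  if (any(point_in_polygon(a$x, a$y, b, strict = TRUE)) ||
      any(point_in_polygon(b$x, b$y, a, strict = TRUE))) return(TRUE)
  na <- nrow(a); nb <- nrow(b)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1L else i + 1L
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1L else j + 1L
      if (!is.null(segment_crossing(c(a$x[i], a$y[i]), c(a$x[i2], a$y[i2]),
                                    c(b$x[j], b$y[j]), c(b$x[j2], b$y[j2]))))
        return(TRUE)
    }
  }
  FALSE
}
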