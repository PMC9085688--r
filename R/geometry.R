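# Planar computational geometry for buffer/strip analyses.
#
# Polygons are two-column matrices (x, y) of vertices in order, not closed
# (last vertex != first). All coordinates are metres in a projected CRS;
# geographic coordinates are not supported.

#' @keywords internal
poly_close <- function(p) rbind(p, p[1, , drop = FALSE])

#' Signed polygon area (shoelace); positive for counter-clockwise rings.
#' @keywords internal
poly_area_signed <- function(p) {
  n <- nrow(p)
  if (is.null(n) || n < 3) return(0)
  x <- p[, 1]; y <- p[, 2]
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' @keywords internal
poly_area <- function(p) abs(poly_area_signed(p))

#' @keywords internal
poly_centroid <- function(p) {
  a <- poly_area_signed(p)
  if (abs(a) < 1e-12) return(colMeans(p))
  n <- nrow(p)
  j <- c(2:n, 1)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

#' @keywords internal
ensure_ccw <- function(p) if (poly_area_signed(p) < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p

#' @keywords internal
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Regular polygon approximation of a disc (counter-clockwise).
#' @keywords internal
circle_poly <- function(centre, r, n = 256L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = centre[1] + r * cos(th), y = centre[2] + r * sin(th))
}

# Sutherland-Hodgman step: keep the part of `poly` on the left of the
# directed line a -> b. Exact for any simple subject when the clip region
# is convex.
#' @keywords internal
clip_poly_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(NULL)
  dx <- b[1] - a[1]; dy <- b[2] - a[2]
  side <- dx * (poly[, 2] - a[2]) - dy * (poly[, 1] - a[1])
  if (all(side >= 0)) return(poly)
  if (all(side <= 0)) return(NULL)
  out <- matrix(0, n * 2L, 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    si <- side[i]; sj <- side[j]
    if (si >= 0) { m <- m + 1L; out[m, ] <- poly[i, ] }
    if ((si > 0 && sj < 0) || (si < 0 && sj > 0)) {
      t <- si / (si - sj)
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (m < 3L) return(NULL)
  out[seq_len(m), , drop = FALSE]
}

#' Clip a simple polygon to a convex polygon (counter-clockwise).
#' @keywords internal
clip_poly_convex <- function(subject, clip) {
  clip <- ensure_ccw(clip)
  res <- subject
  n <- nrow(clip)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    res <- clip_poly_halfplane(res, clip[i, ], clip[j, ])
    if (is.null(res)) return(NULL)
  }
  res
}

# Cyrus-Beck clipping of segment a->b against a convex CCW polygon.
# Returns c(t0, t1) in [0, 1] or NULL if fully outside.
#' @keywords internal
clip_segment_convex <- function(a, b, clip) {
  n <- nrow(clip)
  j <- c(2:n, 1L)
  # inward normals of the CCW clip edges
  nx <- -(clip[j, 2] - clip[, 2])
  ny <- clip[j, 1] - clip[, 1]
  d <- b - a
  denom <- nx * d[1] + ny * d[2]
  num <- nx * (a[1] - clip[, 1]) + ny * (a[2] - clip[, 2])
  par <- abs(denom) < 1e-300
  if (any(par & num < 0)) return(NULL)
  t <- -num / denom
  ent <- denom > 0 & !par
  ext <- denom < 0 & !par
  t0 <- if (any(ent)) max(0, t[ent]) else 0
  t1 <- if (any(ext)) min(1, t[ext]) else 1
  if (t0 > t1) return(NULL)
  c(t0, t1)
}

#' Clip a polyline to a convex polygon, returning connected pieces.
#'
#' Each piece is a two-column coordinate matrix; pieces are maximal runs of
#' consecutive clipped sub-segments whose endpoints coincide.
#' @keywords internal
clip_polyline_convex <- function(coords, clip) {
  clip <- ensure_ccw(clip)
  pieces <- list()
  cur <- NULL
  nseg <- nrow(coords) - 1L
  if (nseg < 1L) return(pieces)
  for (i in seq_len(nseg)) {
    a <- coords[i, ]; b <- coords[i + 1L, ]
    tt <- clip_segment_convex(a, b, clip)
    if (is.null(tt) || tt[2] - tt[1] < 1e-12) {
      if (!is.null(cur)) { pieces[[length(pieces) + 1L]] <- cur; cur <- NULL }
      next
    }
    p0 <- a + tt[1] * (b - a)
    p1 <- a + tt[2] * (b - a)
    if (!is.null(cur) && sum((cur[nrow(cur), ] - p0)^2) < 1e-12) {
      cur <- rbind(cur, p1)
    } else {
      if (!is.null(cur)) pieces[[length(pieces) + 1L]] <- cur
      cur <- rbind(p0, p1)
    }
    if (tt[2] < 1) { pieces[[length(pieces) + 1L]] <- cur; cur <- NULL }
  }
  if (!is.null(cur)) pieces[[length(pieces) + 1L]] <- cur
  pieces
}

#' @keywords internal
polyline_length <- function(coords) {
  if (is.null(nrow(coords)) || nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums((coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE])^2)))
}

#' Arc-length midpoint of a polyline.
#' @keywords internal
polyline_midpoint <- function(coords) {
  seg <- coords[-1, , drop = FALSE] - coords[-nrow(coords), , drop = FALSE]
  len <- sqrt(rowSums(seg^2))
  total <- sum(len)
  if (total == 0) return(coords[1, ])
  half <- total / 2
  cs <- cumsum(len)
  i <- which(cs >= half - 1e-12)[1]
  prev <- if (i == 1L) 0 else cs[i - 1L]
  t <- (half - prev) / len[i]
  coords[i, ] + t * seg[i, ]
}

#' @keywords internal
point_in_poly <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2])) {
      xint <- (xj - xi) * (pt[2] - yi) / (yj - yi) + xi
      if (pt[1] < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' @keywords internal
point_seg_dist <- function(p, a, b) {
  d <- b - a
  l2 <- sum(d^2)
  if (l2 == 0) return(sqrt(sum((p - a)^2)))
  t <- max(0, min(1, sum((p - a) * d) / l2))
  sqrt(sum((p - (a + t * d))^2))
}

#' @keywords internal
segs_intersect <- function(p1, p2, p3, p4) {
  d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
  d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
  d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
  d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
  if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) {
    # collinear: segments meet iff their projections overlap on both axes
    return(min(p1[1], p2[1]) <= max(p3[1], p4[1]) &&
           min(p3[1], p4[1]) <= max(p1[1], p2[1]) &&
           min(p1[2], p2[2]) <= max(p3[2], p4[2]) &&
           min(p3[2], p4[2]) <= max(p1[2], p2[2]))
  }
  (d1 * d2 <= 0) && (d3 * d4 <= 0)
}

#' @keywords internal
seg_seg_dist <- function(p1, p2, p3, p4) {
  if (segs_intersect(p1, p2, p3, p4)) return(0)
  min(point_seg_dist(p1, p3, p4), point_seg_dist(p2, p3, p4),
      point_seg_dist(p3, p1, p2), point_seg_dist(p4, p1, p2))
}

#' Validate a simple polygon: >= 3 vertices, positive area, no
#' self-intersection between non-adjacent edges.
#' @keywords internal
validate_polygon <- function(p, what = "polygon") {
  if (!is.matrix(p) || ncol(p) != 2 || nrow(p) < 3)
    stop(what, " must be a matrix with >= 3 rows and 2 columns", call. = FALSE)
  n <- nrow(p)
  idx <- function(i) ((i - 1L) %% n) + 1L
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i + 1L || (i == 1L && j == n)) next
      if (segs_intersect(p[i, ], p[idx(i + 1L), ], p[j, ], p[idx(j + 1L), ]))
        stop(what, " is self-intersecting", call. = FALSE)
    }
  }
  if (poly_area(p) <= 0) stop(what, " has zero area", call. = FALSE)
  invisible(p)
}

#' Minimum distance between two simple polygons (0 when overlapping).
#' @keywords internal
poly_distance <- function(A, B) {
  if (point_in_poly(A[1, ], B) || point_in_poly(B[1, ], A)) return(0)
  nA <- nrow(A); nB <- nrow(B)
  best <- Inf
  for (i in seq_len(nA)) {
    i2 <- if (i == nA) 1L else i + 1L
    for (j in seq_len(nB)) {
      j2 <- if (j == nB) 1L else j + 1L
      d <- seg_seg_dist(A[i, ], A[i2, ], B[j, ], B[j2, ])
      if (d < best) best <- d
      if (best == 0) return(0)
    }
  }
  best
}

#' Voronoi tessellation of a rectangle by half-plane intersection.
#'
#' Returns one convex counter-clockwise cell polygon per seed point. Cells
#' tile the rectangle exactly (up to floating point), which the mosaic
#' generator relies on for the cover-sum invariant.
#' @keywords internal
voronoi_cells <- function(pts, xmin, ymin, xmax, ymax) {
  n <- nrow(pts)
  base <- rect_poly(xmin, ymin, xmax, ymax)
  lapply(seq_len(n), function(i) {
    cell <- base
    for (j in seq_len(n)) {
      if (j == i || is.null(cell)) next
      # perpendicular bisector half-plane keeping the side of point i
      m <- (pts[i, ] + pts[j, ]) / 2
      d <- pts[j, ] - pts[i, ]
      # keep d . (x - m) <= 0  <=>  left of line through m with direction
      # rotate(d, +90) = (-d2, d1)
      a <- m
      b <- m + c(-d[2], d[1])
      cell <- clip_poly_halfplane(cell, a, b)
    }
    cell
  })
}

# Length of the overlap of two nearly collinear segments, used for shared
# parcel boundaries. Returns the overlapping sub-segment (2x2 matrix) or
# NULL. tol is the max perpendicular offset in metres.
#' @keywords internal
collinear_overlap <- function(s1, s2, tol = 1e-6) {
  d <- s1[2, ] - s1[1, ]
  len <- sqrt(sum(d^2))
  if (len < tol) return(NULL)
  u <- d / len
  # both endpoints of s2 must lie on the supporting line of s1
  off <- abs((s2[, 1] - s1[1, 1]) * (-u[2]) + (s2[, 2] - s1[1, 2]) * u[1])
  if (any(off > tol)) return(NULL)
  t1 <- c(0, len)
  t2 <- sort((s2[, 1] - s1[1, 1]) * u[1] + (s2[, 2] - s1[1, 2]) * u[2])
  lo <- max(t1[1], t2[1]); hi <- min(t1[2], t2[2])
  if (hi - lo <= tol) return(NULL)
  rbind(s1[1, ] + lo * u, s1[1, ] + hi * u)
}

#' @keywords internal
poly_edges <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  cbind(p, p[j, , drop = FALSE])
}
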