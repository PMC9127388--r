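#' Polygon utilities
#'
#' Closed polygons are n x 2 numeric matrices of vertices in mm; the
#' first vertex is not repeated. Orientation is counter-clockwise (CCW)
#' for all stored contours.
#'
#' @param poly n x 2 numeric matrix of vertices.
#' @return `polygonArea` returns the unsigned enclosed area (mm^2);
#'   `signedPolygonArea` keeps the orientation sign (positive = CCW).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' polygonArea(sq)  # 1
#' @export
polygonArea <- function(poly) abs(signedPolygonArea(poly))

#' @rdname polygonArea
#' @export
signedPolygonArea <- function(poly) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' @rdname polygonArea
#' @export
polygonCentroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' @rdname polygonArea
#' @export
isCCW <- function(poly) signedPolygonArea(poly) > 0

ensureCCW <- function(poly) if (isCCW(poly)) poly else poly[rev(seq_len(nrow(poly))), , drop = FALSE]

# O(n^2) proper-crossing test between non-adjacent edges; adequate at the
# 64-vertex contour resolution used throughout.
polygonIsSimple <- function(poly) {
  n <- nrow(poly)
  p <- rbind(poly, poly[1, ])
  seg_int <- function(a, b, c, d) {
    d1 <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d2 <- (b[1] - a[1]) * (d[2] - a[2]) - (b[2] - a[2]) * (d[1] - a[1])
    d3 <- (d[1] - c[1]) * (a[2] - c[2]) - (d[2] - c[2]) * (a[1] - c[1])
    d4 <- (d[1] - c[1]) * (b[2] - c[2]) - (d[2] - c[2]) * (b[1] - c[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    j <- i + 2
    while (j <= jmax) {
      if (seg_int(p[i, ], p[i + 1, ], p[j, ], p[j + 1, ])) return(FALSE)
      j <- j + 1
    }
  }
  TRUE
}

#' Point-in-polygon test
#'
#' Thin wrapper over [pracma::inpolygon()] for n x 2 polygon matrices.
#'
#' @param pts m x 2 matrix of query points.
#' @param poly n x 2 polygon matrix.
#' @return logical vector of length m.
#' @export
pointsInPolygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2)
  pracma::inpolygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2])
}

# Distance from `centre` to the polygon boundary along the ray at angle
# `theta`; used to resample arbitrary simple contours onto a common
# angular grid. Polygons around vessel lumens are star-shaped about the
# lumen centroid; the farthest intersection is taken for robustness.
rayPolygonDistance <- function(poly, centre, theta) {
  n <- nrow(poly)
  dx <- cos(theta); dy <- sin(theta)
  best <- -1
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ax <- poly[i, 1] - centre[1]; ay <- poly[i, 2] - centre[2]
    bx <- poly[j, 1] - centre[1]; by <- poly[j, 2] - centre[2]
    ex <- bx - ax; ey <- by - ay
    den <- dx * ey - dy * ex
    if (abs(den) < 1e-14) next
    t <- (ax * ey - ay * ex) / den     # distance along ray
    s <- (ax * dy - ay * dx) / den     # position along edge
    if (t > 0 && s >= -1e-12 && s <= 1 + 1e-12 && t > best) best <- t
  }
  if (best <= 0) stop("ray from centre does not intersect polygon; contour not star-shaped about centre")
  best
}

#' Resample a contour at equally spaced angles
#'
#' Casts rays from `centre` at `n` equally spaced angles and returns the
#' boundary intersections, giving every contour a common angular
#' parameterization (needed to pair lumen and EEM points when meshing).
#'
#' @param poly n x 2 polygon matrix.
#' @param centre length-2 numeric, ray origin (defaults to the polygon
#'   centroid).
#' @param n number of rays.
#' @return n x 2 matrix of resampled CCW vertices.
#' @export
resampleContour <- function(poly, centre = polygonCentroid(poly), n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  r <- vapply(th, function(t) rayPolygonDistance(poly, centre, t), numeric(1))
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# Uniform in-plane scaling about a fixed point.
scalePolygon <- function(poly, s, centre) {
  sweep(sweep(poly, 2, centre, "-") * s, 2, centre, "+")
}
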