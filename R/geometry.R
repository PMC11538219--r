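#' Spheroid geometry
#'
#' A closed planar polygon (vertices in micrometres, counter-clockwise) with
#' derived morphometric descriptors. Objects of this class are produced both by
#' the synthetic-data generator and by image segmentation, and are consumed by
#' the finite-element growth model.
#'
#' @param vertices two-column numeric matrix of polygon vertices (um). The
#'   polygon is implicitly closed; the first vertex must not be repeated.
#' @param area optional precomputed area in um^2. When segmentation derives the
#'   area from a pixel count (the particle-counting convention) it passes it
#'   here; otherwise the shoelace area of `vertices` is used.
#' @param metrics optional precomputed list with elements `solidity`,
#'   `eccentricity`, `centroid`; computed from the polygon when omitted.
#'
#' @return An object of class `spheroid_geometry`: a list with elements
#'   `vertices`, `area` (um^2), `solidity`, `eccentricity`, `centroid` (um).
#' @export
spheroid_geometry <- function(vertices, area = NULL, metrics = NULL) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("'vertices' must be an n x 2 matrix with n >= 3")
  if (anyNA(vertices)) stop("'vertices' contains NA")
  # drop a duplicated closing vertex if present
  n <- nrow(vertices)
  if (isTRUE(all.equal(vertices[1L, ], vertices[n, ], check.attributes = FALSE)))
    vertices <- vertices[-n, , drop = FALSE]
  if (polygon_signed_area(vertices) < 0)
    vertices <- vertices[rev(seq_len(nrow(vertices))), , drop = FALSE]
  if (is.null(metrics)) metrics <- polygon_metrics(vertices)
  if (is.null(area)) area <- metrics$area
  if (!is.finite(area) || area <= 0) stop("polygon area must be positive")
  structure(
    list(vertices = vertices, area = area, solidity = metrics$solidity,
         eccentricity = metrics$eccentricity, centroid = metrics$centroid),
    class = "spheroid_geometry")
}

#' @export
print.spheroid_geometry <- function(x, ...) {
  cat(sprintf(
    "spheroid_geometry: %d vertices, area %.1f um^2, solidity %.3f, eccentricity %.3f\n",
    nrow(x$vertices), x$area, x$solidity, x$eccentricity))
  invisible(x)
}

## ---- polygon primitives -------------------------------------------------

polygon_signed_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# second central moments of the polygon interior, as the covariance matrix of
# a uniform density over the region (um^2)
polygon_covariance <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12     # integral of y^2 dA
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12     # integral of x^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  m <- matrix(c(iyy / a - cx^2, ixy / a - cx * cy,
                ixy / a - cx * cy, ixx / a - cy^2), 2L, 2L)
  list(cov = m, centroid = c(cx, cy), area = a)
}

polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  idx <- c(seq_len(n), 1L)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in seq.int(i + 2L, jmax)) {
      if (segments_intersect(v[idx[i], ], v[idx[i + 1L], ],
                             v[idx[j], ], v[idx[j + 1L], ]))
        return(FALSE)
    }
  }
  TRUE
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- cross2(p4 - p3, p1 - p3)
  d2 <- cross2(p4 - p3, p2 - p3)
  d3 <- cross2(p2 - p1, p3 - p1)
  d4 <- cross2(p2 - p1, p4 - p1)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

cross2 <- function(a, b) a[1L] * b[2L] - a[2L] * b[1L]

# points strictly/boundary-inclusively inside polygon; px, py vectors.
# Even-odd rule, vectorised over points.
points_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1L]; yi <- v[i, 2L]
    xj <- v[j, 1L]; yj <- v[j, 2L]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# first intersection of the ray origin + t*dir (t > 0) with the polygon
# boundary; returns t or NA when the ray misses.
ray_polygon_intersection <- function(origin, direction, v) {
  n <- nrow(v)
  ts <- rep(NA_real_, n)
  j <- n
  for (i in seq_len(n)) {
    a <- v[j, ]; b <- v[i, ]
    e <- b - a
    denom <- cross2(direction, e)
    if (abs(denom) > 1e-14) {
      ao <- a - origin
      t <- cross2(ao, e) / denom
      s <- cross2(ao, direction) / denom
      if (t > 1e-12 && s >= -1e-12 && s <= 1 + 1e-12) ts[j] <- t
    }
    j <- i
  }
  if (all(is.na(ts))) return(NA_real_)
  min(ts, na.rm = TRUE)
}

#' Shape descriptors of a planar polygon
#'
#' Computes the morphometric descriptors used for spheroid outlines: area by
#' the shoelace formula, solidity as area over convex-hull area, and
#' eccentricity of the ellipse with the same second central moments
#' (`sqrt(1 - lambda2/lambda1)` for covariance eigenvalues
#' `lambda1 >= lambda2`). A circle has eccentricity 0; a 10:1 ellipse
#' `sqrt(1 - 1/100) ~ 0.995`.
#'
#' @param geometry a [spheroid_geometry] or an n x 2 vertex matrix (um).
#' @return list with `area` (um^2), `solidity`, `eccentricity`,
#'   `centroid` (um).
#' @export
shape_metrics <- function(geometry) {
  v <- if (inherits(geometry, "spheroid_geometry")) geometry$vertices
       else as.matrix(geometry)
  if (!polygon_is_simple(v)) stop("polygon is self-intersecting")
  polygon_metrics(v)
}

polygon_metrics <- function(v) {
  pc <- polygon_covariance(v)
  hull <- v[grDevices::chull(v), , drop = FALSE]
  hull_area <- abs(polygon_signed_area(hull))
  ev <- eigen(pc$cov, symmetric = TRUE, only.values = TRUE)$values
  ecc <- if (ev[1L] <= 0) 0 else sqrt(max(0, 1 - max(0, ev[2L]) / ev[1L]))
  list(area = abs(pc$area), solidity = min(1, abs(pc$area) / hull_area),
       eccentricity = ecc, centroid = pc$centroid)
}

# regular polygonal approximation of an ellipse (CCW), semi-axes (um),
# rotation phi (rad)
ellipse_polygon <- function(center, semi_major, semi_minor, phi = 0,
                            n_vertices = 64L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  x <- semi_major * cos(th); y <- semi_minor * sin(th)
  cbind(center[1L] + x * cos(phi) - y * sin(phi),
        center[2L] + x * sin(phi) + y * cos(phi))
}
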