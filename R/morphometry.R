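## Image-based morphometry: maximum-intensity projection, rolling-ball-style
## background subtraction, particle segmentation and live/dead counting.
## Raster primitives (thresholding, labelling, grayscale morphology, contour
## tracing) come from EBImage; polygon metrics are computed in geometry.R.
##
## Image layout convention (shared with the generators): matrices are indexed
## img[x + 1, y + 1] with pixel (x, y) 0-based from the top-left; physical
## coordinates are um with y up: x_um = (x + 0.5) * um_per_px,
## y_um = (height_px - y - 0.5) * um_per_px.

#' Maximum-intensity projection of a z-stack
#'
#' @param stack numeric array: `width x height x slices` (single channel) or
#'   `width x height x channels x slices`.
#' @return per-pixel maximum over z: a matrix, or a `width x height x
#'   channels` array for multi-channel stacks.
#' @export
max_intensity_projection <- function(stack) {
  d <- dim(stack)
  if (is.null(d) || length(d) < 2L || any(d == 0L))
    stop("input error: empty stack")
  if (length(d) == 2L) return(stack)
  if (length(d) == 3L) return(apply(stack, c(1L, 2L), max))
  if (length(d) == 4L) return(apply(stack, c(1L, 2L, 3L), max))
  stop("input error: stack must have 2-4 dimensions")
}

#' Rolling-ball-style background subtraction
#'
#' Estimates a slowly varying background as the grayscale morphological
#' opening of the image with a disc structuring element of the given radius
#' and subtracts it, clipping at zero. Structures wider than the disc are
#' treated as background and removed; compact bright objects are preserved.
#'
#' @param image 2-D numeric matrix in `[0, 1]`.
#' @param radius_px disc radius in pixels (>= 1, smaller than the image).
#' @return background-subtracted matrix, non-negative.
#' @export
subtract_background <- function(image, radius_px) {
  if (radius_px < 1) stop("parameter error: 'radius_px' must be >= 1")
  if (2 * radius_px + 1 > min(dim(image)[1:2]))
    stop("parameter error: 'radius_px' exceeds the image size")
  brush <- EBImage::makeBrush(2 * as.integer(radius_px) + 1L, shape = "disc")
  bg <- EBImage::opening(EBImage::Image(image), brush)
  pmax(image - as.matrix(bg), 0)
}

#' Segment spheroids in a single-channel image
#'
#' Particle analysis: global threshold (Otsu by default), 8-connected
#' components, removal of components below a minimum area, boundary tracing,
#' and conversion of pixel measurements to physical units. Component areas
#' follow the particle-counting convention (pixel count times
#' `um_per_px^2`); solidity and eccentricity are computed from the component
#' pixel set (convex hull of boundary pixels; moment-equivalent ellipse).
#' Touching spheroids merge into one component - there is no watershed split.
#'
#' @param image 2-D numeric matrix in `[0, 1]`.
#' @param threshold `"otsu"` or a fixed numeric threshold in `(0, 1)`.
#' @param min_area_px minimum component area in pixels (default 50, rejecting
#'   single cells and noise specks).
#' @param um_per_px physical pixel size (um/pixel).
#' @param min_area_um2 optional physical minimum area (um^2) overriding
#'   `min_area_px`.
#' @return list of [spheroid_geometry] (possibly empty) with attribute
#'   `table`: data frame (label, area_um2, solidity, eccentricity,
#'   centroid_x_um, centroid_y_um) and attribute `threshold` (value used).
#' @export
segment_spheroids <- function(image, threshold = "otsu", min_area_px = 50L,
                              um_per_px = 1, min_area_um2 = NULL) {
  if (length(dim(image)) != 2L) stop("'image' must be a 2-D matrix")
  if (!is.null(min_area_um2)) min_area_px <- min_area_um2 / um_per_px^2
  thr <- if (identical(threshold, "otsu"))
    EBImage::otsu(EBImage::Image(image)) else as.numeric(threshold)
  labels <- label_components(image > thr)
  n <- max(labels)
  empty <- structure(list(), table = empty_particle_table(), threshold = thr)
  if (n == 0L) return(empty)
  counts <- tabulate(labels, nbins = n)
  keep <- which(counts >= min_area_px)
  if (length(keep) == 0L) return(empty)
  h_px <- dim(image)[2L]
  contours <- EBImage::ocontour(labels)
  geoms <- vector("list", length(keep))
  tab <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    lab <- keep[k]
    pix <- which(labels == lab, arr.ind = TRUE) - 1L   # 0-based (x, y)
    m <- pixel_metrics(pix, h_px, um_per_px)
    poly_px <- contours[[lab]]
    if (nrow(poly_px) < 3L)
      poly_px <- cbind(pix[1L, 1L] + c(-0.5, 0.5, 0.5, -0.5),
                       pix[1L, 2L] + c(-0.5, -0.5, 0.5, 0.5))
    vert_um <- cbind((poly_px[, 1L] + 0.5) * um_per_px,
                     (h_px - poly_px[, 2L] - 0.5) * um_per_px)
    geoms[[k]] <- spheroid_geometry(vert_um, area = m$area_um2,
                                    metrics = list(solidity = m$solidity,
                                                   eccentricity = m$eccentricity,
                                                   centroid = m$centroid))
    tab[[k]] <- data.frame(label = lab, area_um2 = m$area_um2,
                           solidity = m$solidity, eccentricity = m$eccentricity,
                           centroid_x_um = m$centroid[1L],
                           centroid_y_um = m$centroid[2L])
  }
  structure(geoms, table = do.call(rbind, tab), threshold = thr)
}

empty_particle_table <- function() {
  data.frame(label = integer(), area_um2 = numeric(), solidity = numeric(),
             eccentricity = numeric(), centroid_x_um = numeric(),
             centroid_y_um = numeric())
}

# shape descriptors from a component's pixel set (0-based x, y pixel coords)
pixel_metrics <- function(pix, h_px, um_per_px) {
  npix <- nrow(pix)
  area_um2 <- npix * um_per_px^2
  x_um <- (pix[, 1L] + 0.5) * um_per_px
  y_um <- (h_px - pix[, 2L] - 0.5) * um_per_px
  centroid <- c(mean(x_um), mean(y_um))
  solidity <- 1
  if (npix >= 3L) {
    hull_idx <- grDevices::chull(x_um, y_um)
    if (length(hull_idx) >= 3L) {
      hull <- cbind(x_um[hull_idx], y_um[hull_idx])
      # hull through pixel centers; half-pixel dilation approximates the
      # true pixel-boundary hull
      ha <- abs(polygon_signed_area(hull)) +
        hull_perimeter(hull) * um_per_px / 2 + um_per_px^2
      solidity <- min(1, area_um2 / ha)
    }
  }
  ecc <- 0
  if (npix >= 3L) {
    # moment-equivalent ellipse; um_per_px^2/12 is the per-pixel variance
    cv <- stats::cov(cbind(x_um, y_um)) * (npix - 1) / npix +
      diag(um_per_px^2 / 12, 2L)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (ev[1L] > 0) ecc <- sqrt(max(0, 1 - max(0, ev[2L]) / ev[1L]))
  }
  list(area_um2 = area_um2, solidity = solidity, eccentricity = ecc,
       centroid = centroid)
}

hull_perimeter <- function(v) {
  vn <- rbind(v[-1L, , drop = FALSE], v[1L, , drop = FALSE])
  sum(sqrt(rowSums((vn - v)^2)))
}

# 8-connected components: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass over the label graph
label_components <- function(binary) {
  labels <- as.matrix(EBImage::bwlabel(EBImage::Image(binary * 1)))
  storage.mode(labels) <- "integer"
  n <- max(labels)
  if (n <= 1L) return(labels)
  nr <- nrow(labels); nc <- ncol(labels)
  a1 <- labels[-nr, -nc]; b1 <- labels[-1L, -1L]     # down-right diagonal
  a2 <- labels[-1L, -nc]; b2 <- labels[-nr, -1L]     # up-right diagonal
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1L]); rb <- find(pairs[r, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  remap <- match(roots, sort(unique(roots)))
  out <- labels
  out[labels > 0L] <- remap[labels[labels > 0L]]
  out
}

#' Viability from a two-channel live/dead stack
#'
#' Reproduces the live/dead counting pipeline: per channel, maximum-intensity
#' projection, background subtraction, uniform threshold, and particle
#' counting; channel 1 counts live cells, channel 2 dead cells. Viability is
#' live over total.
#'
#' @param stack array `width x height x 2 x slices` (or `width x height x 2`).
#' @param threshold `"otsu"` (per channel) or a fixed numeric threshold.
#' @param min_area_px minimum particle area in pixels (default 20).
#' @param bg_radius_px background-subtraction disc radius (default 50;
#'   `NULL` skips subtraction).
#' @param min_threshold floor applied to the automatic threshold (default
#'   0.2). Otsu's method assumes a bimodal histogram and degenerates on a
#'   channel with no cells, splitting the noise; the floor keeps such
#'   channels at zero counts.
#' @return object of class `viability_result`: list with `n_live`, `n_dead`,
#'   `viability` (fraction).
#' @export
count_live_dead <- function(stack, threshold = "otsu", min_area_px = 20L,
                            bg_radius_px = 50L, min_threshold = 0.2) {
  d <- dim(stack)
  if (length(d) == 3L && d[3L] == 2L) stack <- array(stack, c(d[1:3], 1L))
  d <- dim(stack)
  if (length(d) != 4L || d[3L] != 2L)
    stop("'stack' must have exactly two channels")
  counts <- integer(2L)
  for (ch in 1:2) {
    img <- max_intensity_projection(stack[, , ch, , drop = TRUE])
    if (is.null(dim(img))) img <- matrix(img, d[1L], d[2L])
    if (!is.null(bg_radius_px)) img <- subtract_background(img, bg_radius_px)
    thr <- if (identical(threshold, "otsu"))
      max(EBImage::otsu(EBImage::Image(img)), min_threshold)
      else as.numeric(threshold)
    labels <- label_components(img > thr)
    n <- max(labels)
    counts[ch] <- if (n == 0L) 0L
      else sum(tabulate(labels, nbins = n) >= min_area_px)
  }
  if (sum(counts) == 0L)
    stop("undefined-viability error: no live or dead cells detected")
  structure(list(n_live = counts[1L], n_dead = counts[2L],
                 viability = counts[1L] / sum(counts)),
            class = "viability_result")
}

#' @export
print.viability_result <- function(x, ...) {
  cat(sprintf("viability_result: %d live / %d dead -> %.1f%% viable\n",
              x$n_live, x$n_dead, 100 * x$viability))
  invisible(x)
}
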