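## Synthetic-data generators.
##
## Every generator draws from one explicit integer seed and returns the latent
## ground truth it sampled, so each downstream analysis stage has a recovery
## test. No generator touches the global RNG state.

# evaluate expr under a local RNG seeded with `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Specification of a synthetic spheroid population
#'
#' Describes a population of spheroid cross-sections to generate. Areas are
#' drawn from a lognormal distribution (spheroid areas are positive and
#' right-skewed) with the requested mean and coefficient of variation.
#'
#' @param n_spheroids number of spheroids (>= 1).
#' @param mean_area mean cross-sectional area, um^2.
#' @param cv_area coefficient of variation of the area distribution
#'   (default 0.5; 0 gives identical areas).
#' @param shape `"circle"`, `"ellipse"` or `"discoid"`. The discoid shape is a
#'   thin ellipse (aspect ratio >= 5) standing in for a gel microcrack opened
#'   by the growing spheroid.
#' @param aspect_ratio_range length-2 numeric, aspect ratios drawn uniformly
#'   from this interval (ellipse default `c(1.2, 2)`; discoid default
#'   `c(5, 10)`, values below 5 rejected).
#' @param seed integer seed; all randomness flows from it.
#' @return object of class `spheroid_population_spec`.
#' @export
spheroid_population_spec <- function(n_spheroids, mean_area, cv_area = 0.5,
                                     shape = c("circle", "ellipse", "discoid"),
                                     aspect_ratio_range = NULL, seed = 1L) {
  shape <- match.arg(shape)
  if (n_spheroids < 1L) stop("'n_spheroids' must be >= 1")
  if (!is.finite(mean_area) || mean_area <= 0) stop("'mean_area' must be > 0")
  if (!is.finite(cv_area) || cv_area < 0) stop("'cv_area' must be >= 0")
  if (is.null(aspect_ratio_range))
    aspect_ratio_range <- switch(shape, circle = c(1, 1), ellipse = c(1.2, 2),
                                 discoid = c(5, 10))
  aspect_ratio_range <- sort(as.numeric(aspect_ratio_range))
  if (shape == "discoid" && aspect_ratio_range[1L] < 5)
    stop("discoid spheroids require aspect ratio >= 5 (thin-ellipse microcrack surrogate)")
  if (shape == "circle") aspect_ratio_range <- c(1, 1)
  structure(list(n_spheroids = as.integer(n_spheroids), mean_area = mean_area,
                 cv_area = cv_area, shape = shape,
                 aspect_ratio_range = aspect_ratio_range,
                 seed = as.integer(seed)),
            class = "spheroid_population_spec")
}

#' Generate a population of spheroid geometries
#'
#' Draws areas from the lognormal law implied by `mean_area` and `cv_area`,
#' builds one simple counter-clockwise polygon per spheroid (64-gon scaled so
#' its shoelace area equals the sampled area exactly), and places the
#' spheroids without overlap in a square field by rejection sampling.
#'
#' @param spec a [spheroid_population_spec].
#' @param field_size_um side of the square placement field (um). Default sizes
#'   the field so the expected area fraction of spheroids is 10%.
#' @param margin_um minimum clearance between bounding circles (default 5 um).
#' @param max_tries rejection-sampling retry budget per spheroid (default
#'   1000); exhaustion raises a placement error.
#' @return list of [spheroid_geometry] with attributes `field_size_um` and
#'   `truth` (data frame of sampled areas, aspect ratios and centers).
#' @export
gen_spheroid_population <- function(spec, field_size_um = NULL,
                                    margin_um = 5, max_tries = 1000L) {
  stopifnot(inherits(spec, "spheroid_population_spec"))
  if (is.null(field_size_um))
    field_size_um <- sqrt(spec$n_spheroids * spec$mean_area / 0.10)
  with_seed(spec$seed, {
    areas <- rlnorm_mean_cv(spec$n_spheroids, spec$mean_area, spec$cv_area)
    aspects <- stats::runif(spec$n_spheroids, spec$aspect_ratio_range[1L],
                            spec$aspect_ratio_range[2L])
    phis <- stats::runif(spec$n_spheroids, 0, pi)
    semi_major <- sqrt(areas * aspects / pi)
    radii <- semi_major + margin_um / 2
    centers <- place_non_overlapping(radii, field_size_um, max_tries)
    geoms <- vector("list", spec$n_spheroids)
    for (i in seq_len(spec$n_spheroids)) {
      a <- semi_major[i]; b <- a / aspects[i]
      v <- ellipse_polygon(centers[i, ], a, b, phis[i])
      # scale so the polygon (not the continuous ellipse) has the sampled area
      s <- sqrt(areas[i] / abs(polygon_signed_area(v)))
      v <- sweep(sweep(v, 2L, centers[i, ]) * s, 2L, centers[i, ], "+")
      geoms[[i]] <- spheroid_geometry(v)
    }
    attr(geoms, "field_size_um") <- field_size_um
    attr(geoms, "truth") <- data.frame(
      area_um2 = areas, aspect_ratio = aspects, phi = phis,
      center_x_um = centers[, 1L], center_y_um = centers[, 2L])
    geoms
  })
}

# lognormal with exact mean m and coefficient of variation cv
rlnorm_mean_cv <- function(n, m, cv) {
  if (cv == 0) return(rep(m, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
}

# rejection-sample centers so bounding circles of given radii do not overlap
place_non_overlapping <- function(radii, field, max_tries) {
  n <- length(radii)
  centers <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    r <- radii[i]
    if (2 * r >= field)
      stop("placement error: object of radius ", round(r, 1),
           " um does not fit in a ", round(field, 1), " um field")
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(2L, r, field - r)
      if (i == 1L) { ok <- TRUE } else {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        d2 <- (prev[, 1L] - p[1L])^2 + (prev[, 2L] - p[2L])^2
        ok <- all(d2 >= (radii[seq_len(i - 1L)] + r)^2)
      }
      if (ok) { centers[i, ] <- p; break }
    }
    if (!ok)
      stop("placement error: could not place spheroid ", i, " of ", n,
           " within ", max_tries, " tries; enlarge the field or reduce n")
  }
  centers
}

#' Specification of a synthetic microscopy image
#'
#' @param width_px,height_px image size in pixels.
#' @param um_per_px physical pixel size (um/pixel, > 0).
#' @param channels 1 or 2.
#' @param background_level background intensity in the normalized `[0, 1]`
#'   range (default 0.1).
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (default 0.02); intensities are clipped back to `[0, 1]`.
#' @param seed integer seed.
#' @return object of class `image_spec`.
#' @export
image_spec <- function(width_px, height_px, um_per_px = 1, channels = 1L,
                       background_level = 0.1, noise_sd = 0.02, seed = 1L) {
  if (um_per_px <= 0) stop("'um_per_px' must be > 0")
  if (!channels %in% c(1L, 2L)) stop("'channels' must be 1 or 2")
  if (background_level < 0 || background_level > 1)
    stop("'background_level' must be in [0, 1]")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px), um_per_px = um_per_px,
                 channels = as.integer(channels),
                 background_level = background_level, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "image_spec")
}

# polygon vertices (um, y up) -> pixel-center coordinates (0-based, y down)
um_to_px <- function(v, spec) {
  cbind(v[, 1L] / spec$um_per_px - 0.5,
        spec$height_px - v[, 2L] / spec$um_per_px - 0.5)
}

#' Render spheroid geometries into a synthetic image
#'
#' Rasterizes polygons onto a pixel grid: a pixel belongs to a spheroid when
#' its center lies inside the polygon. Foreground pixels take
#' `foreground_level`, background `background_level`, and additive Gaussian
#' noise with the spec's `noise_sd` is applied and clipped to `[0, 1]`.
#' Image matrices follow the EBImage layout: `img[x + 1, y + 1]` with pixel
#' `(x, y)` 0-based from the top-left; geometry coordinates are um with y up,
#' so `x_um = (x + 0.5) * um_per_px`, `y_um = (height_px - y - 0.5) * um_per_px`.
#'
#' @param geometries list of [spheroid_geometry].
#' @param spec an [image_spec] (single channel).
#' @param foreground_level foreground intensity (default 0.9).
#' @return list with `image` (width x height matrix in `[0, 1]`) and `mask`
#'   (integer label matrix, 0 background, i for `geometries[[i]]`).
#' @export
render_image <- function(geometries, spec, foreground_level = 0.9) {
  stopifnot(inherits(spec, "image_spec"))
  w <- spec$width_px; h <- spec$height_px
  mask <- matrix(0L, w, h)
  for (i in seq_along(geometries)) {
    g <- geometries[[i]]
    vp <- um_to_px(g$vertices, spec)
    if (min(vp) < -0.5 || max(vp[, 1L]) > w - 0.5 || max(vp[, 2L]) > h - 0.5)
      stop("bounds error: geometry ", i, " lies outside the image field")
    xr <- max(0L, floor(min(vp[, 1L]))):min(w - 1L, ceiling(max(vp[, 1L])))
    yr <- max(0L, floor(min(vp[, 2L]))):min(h - 1L, ceiling(max(vp[, 2L])))
    gx <- rep(xr, times = length(yr))
    gy <- rep(yr, each = length(xr))
    ins <- points_in_polygon(gx, gy, vp)
    if (any(ins)) mask[cbind(gx[ins] + 1L, gy[ins] + 1L)] <- i
  }
  img <- matrix(spec$background_level, w, h)
  img[mask > 0L] <- foreground_level
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(w * h, 0, spec$noise_sd), w, h))
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, mask = mask)
}

#' Generate a two-channel live/dead z-stack with known counts
#'
#' Emulates a calcein-AM / propidium-iodide viability acquisition: live cells
#' are bright disks in channel 1, dead cells in channel 2, distributed over
#' `n_slices` z-slices. Cell centers are placed with minimum separation
#' `min_sep_factor * cell_radius` (default 3x) so that downstream particle
#' counting can recover the exact counts.
#'
#' @param n_live,n_dead number of live / dead cells (either may be 0, not
#'   both).
#' @param cell_radius cell radius, um.
#' @param spec an [image_spec] with `channels = 2`.
#' @param n_slices number of z-slices (default 5).
#' @param min_sep_factor minimum center separation in units of `cell_radius`.
#' @param max_tries placement retry budget per cell.
#' @return list with `stack` (array width x height x 2 x n_slices in
#'   `[0, 1]`), `n_live`, `n_dead`, and `centers` data frame (um, channel,
#'   slice).
#' @export
gen_livedead_stack <- function(n_live, n_dead, cell_radius, spec,
                               n_slices = 5L, min_sep_factor = 3,
                               max_tries = 1000L) {
  stopifnot(inherits(spec, "image_spec"))
  if (spec$channels != 2L) stop("'spec' must declare 2 channels")
  n <- n_live + n_dead
  if (n < 1L) stop("need at least one cell")
  field_w <- spec$width_px * spec$um_per_px
  field_h <- spec$height_px * spec$um_per_px
  sep <- min_sep_factor * cell_radius
  with_seed(spec$seed, {
    centers <- place_min_separation(n, field_w, field_h, sep, cell_radius,
                                    max_tries)
    channel <- rep(c(1L, 2L), c(n_live, n_dead))
    slice <- sample.int(n_slices, n, replace = TRUE)
    stack <- array(spec$background_level,
                   dim = c(spec$width_px, spec$height_px, 2L, n_slices))
    for (i in seq_len(n)) {
      v <- ellipse_polygon(centers[i, ], cell_radius, cell_radius,
                           n_vertices = 32L)
      vp <- um_to_px(v, spec)
      xr <- max(0L, floor(min(vp[, 1L]))):min(spec$width_px - 1L,
                                              ceiling(max(vp[, 1L])))
      yr <- max(0L, floor(min(vp[, 2L]))):min(spec$height_px - 1L,
                                              ceiling(max(vp[, 2L])))
      gx <- rep(xr, times = length(yr)); gy <- rep(yr, each = length(xr))
      ins <- points_in_polygon(gx, gy, vp)
      idx <- cbind(gx[ins] + 1L, gy[ins] + 1L, channel[i], slice[i])
      stack[idx] <- 0.9
    }
    if (spec$noise_sd > 0) {
      stack <- stack + array(stats::rnorm(length(stack), 0, spec$noise_sd),
                             dim = dim(stack))
      stack <- pmin(pmax(stack, 0), 1)
    }
    list(stack = stack, n_live = n_live, n_dead = n_dead,
         centers = data.frame(x_um = centers[, 1L], y_um = centers[, 2L],
                              channel = channel, slice = slice))
  })
}

place_min_separation <- function(n, field_w, field_h, sep, radius, max_tries) {
  centers <- matrix(NA_real_, n, 2L)
  lo <- radius + 1
  if (field_w - 2 * lo <= 0 || field_h - 2 * lo <= 0)
    stop("placement error: field too small for cell radius")
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- c(stats::runif(1L, lo, field_w - lo),
             stats::runif(1L, lo, field_h - lo))
      if (i == 1L) { ok <- TRUE } else {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        ok <- all((prev[, 1L] - p[1L])^2 + (prev[, 2L] - p[2L])^2 >= sep^2)
      }
      if (ok) { centers[i, ] <- p; break }
    }
    if (!ok)
      stop("placement error: overcrowded field, could not place cell ", i,
           " of ", n)
  }
  centers
}

#' Generate a synthetic unconfined-compression stress-strain curve
#'
#' Produces an engineering stress-strain record with a quadratic toe region
#' smoothly joining a linear segment of slope `E_true`, mimicking the
#' compliance of imperfect platen contact before the linear elastic response:
#' `stress = E * strain^2 / (2 * toe_strain)` for `strain <= toe_strain`, then
#' `E * (strain - toe_strain / 2)` (continuous in value and slope). Additive
#' Gaussian noise with standard deviation `noise_sd_frac` times the peak
#' stress is applied.
#'
#' @param E_true ground-truth Young's modulus, Pa (> 0).
#' @param toe_strain strain extent of the toe region (0 disables it).
#' @param max_strain final strain, at most 0.5 (compression tests here run to
#'   50% deformation).
#' @param n_points number of samples (>= 10).
#' @param noise_sd_frac noise standard deviation as a fraction of peak stress.
#' @param seed integer seed.
#' @return a `stress_strain_curve`: data frame with columns `strain`,
#'   `stress_pa` and attribute `E_true`.
#' @export
gen_stress_strain <- function(E_true, toe_strain = 0.05, max_strain = 0.4,
                              n_points = 200L, noise_sd_frac = 0.01,
                              seed = 1L) {
  if (!is.finite(E_true) || E_true <= 0)
    stop("parameter error: 'E_true' must be > 0")
  if (toe_strain < 0 || toe_strain >= max_strain || max_strain > 0.5)
    stop("parameter error: need 0 <= toe_strain < max_strain <= 0.5")
  if (n_points < 10L) stop("'n_points' must be >= 10")
  strain <- seq(0, max_strain, length.out = n_points)
  stress <- toe_linear_stress(strain, E_true, toe_strain)
  if (noise_sd_frac > 0)
    stress <- with_seed(seed, stress + stats::rnorm(n_points, 0,
                                                    noise_sd_frac * max(stress)))
  stress_strain_curve(strain, stress,
                      meta = list(E_true = E_true, toe_strain = toe_strain,
                                  seed = seed))
}

toe_linear_stress <- function(strain, E, toe) {
  if (toe == 0) return(E * strain)
  ifelse(strain <= toe, E * strain^2 / (2 * toe), E * (strain - toe / 2))
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Inverts the 2^-ddCt transform: for each target gene the cycle-threshold
#' value is the gene's base Ct minus log2 of the condition's true fold change,
#' plus Gaussian measurement noise; the housekeeping (reference) gene is drawn
#' around its own base Ct. The downstream ddCt pipeline anchored at a
#' control-condition sample then recovers `true_fold` exactly in the
#' noiseless case.
#'
#' @param conditions character vector of condition labels; the first is the
#'   control unless `control_condition` says otherwise.
#' @param genes character vector of gene labels, including `reference_gene`.
#' @param reference_gene housekeeping gene label.
#' @param true_fold matrix (conditions x target genes, dimnames required) or
#'   a single number applied to every condition x gene; all folds must be > 0.
#'   Control-condition folds must be 1.
#' @param base_ct base Ct per target gene (scalar or named vector), cycles.
#' @param ref_base_ct base Ct of the reference gene (default 20).
#' @param replicates biological replicates per condition.
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param seed integer seed.
#' @param control_condition control condition label.
#' @return a `ct_table`: data frame with columns `sample_id`, `condition`,
#'   `gene`, `ct`, plus attributes `reference_gene`, `control_condition`,
#'   `true_fold`.
#' @export
gen_ct_table <- function(conditions, genes, reference_gene, true_fold,
                         base_ct = 25, ref_base_ct = 20, replicates = 3L,
                         ct_noise_sd = 0, seed = 1L,
                         control_condition = conditions[1L]) {
  if (!reference_gene %in% genes) stop("'reference_gene' must be in 'genes'")
  targets <- setdiff(genes, reference_gene)
  if (length(targets) == 0L) stop("need at least one target gene")
  if (is.numeric(true_fold) && is.null(dim(true_fold))) {
    true_fold <- matrix(true_fold, length(conditions), length(targets),
                        dimnames = list(conditions, targets))
    true_fold[control_condition, ] <- 1
  }
  if (any(true_fold <= 0)) stop("parameter error: folds must be > 0")
  if (any(true_fold[control_condition, ] != 1))
    stop("control-condition folds must be 1")
  if (length(base_ct) == 1L)
    base_ct <- stats::setNames(rep(base_ct, length(targets)), targets)
  with_seed(seed, {
    rows <- list()
    for (cond in conditions) for (r in seq_len(replicates)) {
      sid <- sprintf("%s_r%02d", cond, r)
      ct_ref <- ref_base_ct + stats::rnorm(1L, 0, ct_noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sid, condition = cond, gene = reference_gene, ct = ct_ref)
      for (g in targets) {
        ct <- base_ct[[g]] - log2(true_fold[cond, g]) +
          stats::rnorm(1L, 0, ct_noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, condition = cond, gene = g, ct = ct)
      }
    }
    tab <- do.call(rbind, rows)
    ct_table(tab, reference_gene = reference_gene,
             control_condition = control_condition, true_fold = true_fold)
  })
}
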