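test_that("maximum-intensity projection dominates every slice", {
  set.seed(1)
  stack <- array(runif(40 * 40 * 4), c(40, 40, 4))
  mip <- max_intensity_projection(stack)
  for (k in 1:4) expect_true(all(mip >= stack[, , k]))

  one <- array(runif(40 * 40), c(40, 40, 1))
  expect_equal(max_intensity_projection(one), one[, , 1])

  # disjoint bright disks on different slices both survive projection
  s <- array(0, c(60, 60, 2))
  s[10:15, 10:15, 1] <- 1
  s[40:45, 40:45, 2] <- 1
  mip2 <- max_intensity_projection(s)
  expect_equal(sum(mip2 == 1), 2 * 36)

  expect_error(max_intensity_projection(array(0, c(5, 5, 0))), "empty stack")
})

test_that("background subtraction flattens background and keeps compact peaks", {
  const <- matrix(0.4, 60, 60)
  expect_true(all(subtract_background(const, 10) == 0))

  # small bright disk on a linear gradient background
  grad <- matrix(rep(seq(0.1, 0.3, length.out = 80), each = 80), 80, 80)
  img <- grad
  xs <- rep(1:80, 80); ys <- rep(1:80, each = 80)
  disk <- (xs - 40)^2 + (ys - 40)^2 <= 5^2
  img[cbind(xs[disk], ys[disk])] <- img[cbind(xs[disk], ys[disk])] + 0.5
  out <- subtract_background(img, 15)
  peak_in <- max(img[cbind(xs[disk], ys[disk])] - grad[cbind(xs[disk], ys[disk])])
  expect_equal(max(out), peak_in, tolerance = 0.05)
  # residual off the disk stays far below the disk amplitude (the opening
  # tracks the gradient up to its slope over one brush width)
  expect_lt(max(out[!disk]), 0.05)

  # idempotence once flattened
  out2 <- subtract_background(out, 15)
  expect_equal(out2, out, tolerance = 1e-6)

  expect_error(subtract_background(matrix(0, 20, 20), 50), "parameter error")
  expect_error(subtract_background(matrix(0, 20, 20), 0), "parameter error")
})

test_that("segmentation recovers a rendered circle's morphometry", {
  g <- list(circle_geometry(50, center = c(100, 100)))
  ren <- render_image(g, image_spec(200, 200, 1, noise_sd = 0, seed = 1))
  seg <- segment_spheroids(ren$image, um_per_px = 1)
  expect_length(seg, 1L)
  tab <- attr(seg, "table")
  expect_lt(abs(tab$area_um2 - pi * 2500) / (pi * 2500), 0.02)
  expect_lt(tab$eccentricity, 0.1)
  expect_gt(tab$solidity, 0.97)
  expect_equal(c(tab$centroid_x_um, tab$centroid_y_um), c(100, 100),
               tolerance = 0.5)
})

test_that("touching disks merge into one component and blank images give none", {
  g <- list(circle_geometry(30, center = c(70, 100)),
            circle_geometry(30, center = c(128, 100)))  # 2 um gap < pixel
  ren <- render_image(g, image_spec(200, 200, 1, noise_sd = 0, seed = 1))
  seg <- segment_spheroids(ren$image, um_per_px = 1, threshold = 0.5)
  expect_length(seg, 1L)

  blank <- matrix(0.1, 50, 50)
  expect_length(segment_spheroids(blank, threshold = 0.5), 0L)
})

test_that("areas scale with the square of the pixel size (scale equivariance)", {
  g <- list(circle_geometry(50, center = c(100, 100)))
  ren <- render_image(g, image_spec(200, 200, 1, noise_sd = 0, seed = 1))
  a1 <- attr(segment_spheroids(ren$image, um_per_px = 1), "table")$area_um2
  a2 <- attr(segment_spheroids(ren$image, um_per_px = 2), "table")$area_um2
  expect_equal(a2, 4 * a1, tolerance = 1e-12)
})

test_that("morphometry is rotation invariant within 1% for rendered shapes", {
  base <- NULL
  for (phi in c(0, 0.4, 1.1)) {
    v <- ellipse_polygon(c(150, 150), 60, 30, phi = phi, n_vertices = 128L)
    ren <- render_image(list(spheroid_geometry(v)),
                        image_spec(300, 300, 1, noise_sd = 0, seed = 1))
    tab <- attr(segment_spheroids(ren$image, um_per_px = 1), "table")
    if (is.null(base)) base <- tab
    expect_equal(tab$area_um2 / base$area_um2, 1, tolerance = 0.01)
    expect_equal(tab$solidity / base$solidity, 1, tolerance = 0.01)
    expect_equal(tab$eccentricity / base$eccentricity, 1, tolerance = 0.01)
  }
})

test_that("live/dead counting recovers ground-truth counts on seeded stacks", {
  for (seed in 1:6) {
    n_live <- sample(15:30, 1)
    n_dead <- sample(0:8, 1)
    if (n_live + n_dead == 0) n_live <- 1
    isp <- image_spec(250, 250, 1, channels = 2, noise_sd = 0.02,
                      seed = seed)
    ld <- gen_livedead_stack(n_live, n_dead, cell_radius = 6, isp,
                             n_slices = 3)
    via <- count_live_dead(ld$stack, bg_radius_px = 30)
    expect_identical(via$n_live, ld$n_live)
    expect_identical(via$n_dead, ld$n_dead)
  }
})

test_that("viability edge cases behave as defined", {
  isp <- image_spec(150, 150, 1, channels = 2, noise_sd = 0.02, seed = 2)
  ld <- gen_livedead_stack(10, 0, 6, isp, n_slices = 2)
  via <- count_live_dead(ld$stack, bg_radius_px = 30)
  expect_equal(via$viability, 1)

  ld0 <- gen_livedead_stack(0, 10, 6, isp, n_slices = 2)
  via0 <- count_live_dead(ld0$stack, bg_radius_px = 30)
  expect_identical(via0$n_live, 0L)
  expect_identical(via0$n_dead, 10L)

  blank <- array(0.1, c(100, 100, 2, 2))
  expect_error(count_live_dead(blank, threshold = 0.5, bg_radius_px = 20),
               "undefined-viability")
})
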