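test_that("Lame annulus solution satisfies its boundary conditions", {
  expect_equal(analytic_annulus(5, 500, 250, 5), 250, tolerance = 1e-12)
  expect_equal(analytic_annulus(5, 500, 250, 500), 0, tolerance = 1e-12)
  # closed-form evaluation at r = 50
  A <- 250 * 5 / (5^2 - 500^2); B <- -A * 500^2
  expect_equal(analytic_annulus(5, 500, 250, 50), A * 50 + B / 50)
  expect_equal(analytic_annulus(5, 500, 250, 50), 24.75, tolerance = 1e-2)
  expect_error(analytic_annulus(10, 5, 1, 7), "parameter error")
})

test_that("annulus mesh respects sizing, tags and element quality", {
  mesh <- annulus_mesh(5, 500, 1)
  cav <- mesh$nodes[mesh$cavity_nodes, ]
  d <- sqrt(rowSums((cav - cav[c(2:nrow(cav), 1), ])^2))
  expect_true(all(d <= 1 + 1e-9))
  expect_equal(sqrt(rowSums(cav^2)), rep(5, nrow(cav)), tolerance = 1e-12)
  expect_equal(sqrt(rowSums(mesh$nodes[mesh$outer_nodes, ]^2)),
               rep(500, length(mesh$outer_nodes)), tolerance = 1e-12)
  expect_length(intersect(mesh$cavity_nodes, mesh$outer_nodes), 0)

  # refinement at h/2 multiplies the element count by >= ~3
  fine <- annulus_mesh(5, 500, 0.5)
  expect_gte(nrow(fine$triangles) / nrow(mesh$triangles), 3)

  # minimum interior angle >= 20 degrees
  p <- mesh$nodes; tr <- mesh$triangles
  min_angle <- function(i) {
    a <- p[tr[i, 1], ]; b <- p[tr[i, 2], ]; c <- p[tr[i, 3], ]
    l <- c(sqrt(sum((b - c)^2)), sqrt(sum((a - c)^2)), sqrt(sum((a - b)^2)))
    min(acos(pmin(1, pmax(-1, c(
      (l[2]^2 + l[3]^2 - l[1]^2) / (2 * l[2] * l[3]),
      (l[1]^2 + l[3]^2 - l[2]^2) / (2 * l[1] * l[3]),
      (l[1]^2 + l[2]^2 - l[3]^2) / (2 * l[1] * l[2]))))))
  }
  angles <- vapply(seq_len(nrow(tr)), min_angle, numeric(1))
  expect_gte(min(angles) * 180 / pi, 20)
})

test_that("boundary map sends cavity nodes radially onto the final outline", {
  mat <- elastic_material(19830)
  prob <- growth_problem(circle_geometry(255), mat, seed_radius = 5,
                         seed_center = c(0, 0))
  mesh <- build_mesh(prob, h_cavity = 1)
  u <- boundary_displacement_map(prob, mesh$nodes[mesh$cavity_nodes, ])
  expect_equal(sqrt(rowSums(u^2)), rep(250, nrow(u)), tolerance = 1e-3)

  # no growth: final outline equal to the seed circle gives zero displacement
  degenerate <- list(final_geometry = circle_geometry(5, n = 512L),
                     seed_center = c(0, 0))
  cavity <- mesh$nodes[mesh$cavity_nodes, ]
  u0 <- boundary_displacement_map(degenerate, cavity)
  expect_lt(max(abs(u0)), 1e-3)

  # 10:1 ellipse: 95 um along the major axis, 5 um along the minor axis
  ell <- list(final_geometry = spheroid_geometry(
    ellipse_polygon(c(0, 0), 100, 10, n_vertices = 4096L)),
    seed_center = c(0, 0))
  ue <- boundary_displacement_map(ell, rbind(c(5, 0), c(0, 5)))
  expect_equal(ue[1, 1], 95, tolerance = 1e-3)
  expect_equal(ue[2, 2], 5, tolerance = 1e-3)
})

test_that("growth problem validation enforces geometry invariants", {
  mat <- elastic_material(2000)
  expect_error(growth_problem(circle_geometry(255), mat, outer_radius = 500),
               "at least 10 x")
  expect_error(growth_problem(circle_geometry(4), mat, seed_radius = 5,
                              outer_radius = 500),
               "strictly contain")
  expect_error(elastic_material(1000, nu = 0.5), "strictly")
  expect_error(elastic_material(-3), "must be > 0")
})

test_that("linear elements reproduce a uniform-strain field to machine precision", {
  mesh <- annulus_mesh(5, 100, 1)
  F <- matrix(c(0.01, 0.003, -0.002, 0.005), 2, 2)
  bnodes <- c(mesh$cavity_nodes, mesh$outer_nodes)
  ub <- mesh$nodes[bnodes, ] %*% t(F)
  field <- fem_solve(mesh, elastic_material(19830, 0.45),
                     cbind(bnodes, ub))
  uexact <- mesh$nodes %*% t(F)
  expect_lt(max(abs(field$u - uexact)), 1e-10 * max(abs(uexact)))
  # strain constant across elements
  expect_lt(max(abs(field$strain[, "exx"] - 0.01)), 1e-12)
  expect_lt(max(abs(field$strain[, "eyy"] - 0.005)), 1e-12)
  expect_lt(max(abs(field$strain[, "gxy"] - 0.001)), 1e-12)
})

test_that("FEM matches the Lame oracle and converges under refinement", {
  mat <- elastic_material(19830, 0.45)
  errs <- vapply(c(1, 0.5), function(h) {
    mesh <- annulus_mesh(5, 500, h)
    field <- fem_solve(mesh, mat, radial_dirichlet(mesh, 250))
    annulus_linf_error(field, 5, 500, 250)
  }, numeric(1))
  expect_lt(errs[1], 0.01)
  expect_lt(errs[2], errs[1])
})

test_that("pure-Dirichlet scaling laws hold", {
  mesh <- annulus_mesh(5, 200, 1)
  d <- radial_dirichlet(mesh, 100)
  f1 <- fem_solve(mesh, elastic_material(2000, 0.45), d)
  f10 <- fem_solve(mesh, elastic_material(20000, 0.45), d)
  expect_equal(f1$u, f10$u, tolerance = 1e-9)
  expect_equal(10 * f1$stress, f10$stress, tolerance = 1e-9)
  expect_equal(10 * f1$von_mises, f10$von_mises, tolerance = 1e-9)

  f2 <- fem_solve(mesh, elastic_material(2000, 0.45),
                  radial_dirichlet(mesh, 200))
  expect_equal(2 * f1$u, f2$u, tolerance = 1e-9)
})

test_that("axisymmetric displacement is nu-independent and axisymmetric", {
  mesh <- annulus_mesh(5, 200, 1)
  d <- radial_dirichlet(mesh, 50)
  fa <- fem_solve(mesh, elastic_material(5000, 0.2), d)
  fb <- fem_solve(mesh, elastic_material(5000, 0.45), d)
  ua <- sqrt(rowSums(fa$u^2)); ub <- sqrt(rowSums(fb$u^2))
  expect_lt(max(abs(ua - ub)) / max(ua), 0.01)

  # across rings: radial profile identical on every angle to < 1%
  r <- round(sqrt(rowSums(mesh$nodes^2)), 9)
  for (ri in unique(r)[c(3, 10, 20)]) {
    u_ring <- ua[r == ri]
    expect_lt((max(u_ring) - min(u_ring)) / max(ua), 0.01)
  }
})

test_that("field summary reports max displacement and deformation extent", {
  mat <- elastic_material(19830, 0.45)
  prob <- growth_problem(circle_geometry(255), mat, seed_radius = 5,
                         seed_center = c(0, 0))
  field <- solve_growth(prob, build_mesh(prob, h_cavity = 1))
  fs <- field_summary(field)
  expect_equal(fs$max_displacement, 250, tolerance = 1e-2)
  expect_error(field_summary(field, threshold = 2), "parameter error")

  # zero growth: zero displacement everywhere
  mesh <- annulus_mesh(5, 100, 1)
  zero <- fem_solve(mesh, mat, radial_dirichlet(mesh, 0))
  expect_equal(field_summary(zero)$max_displacement, 0)

  # extent radius within 5% of the analytic radius where u = 0.05 u_a
  mesh5 <- annulus_mesh(5, 500, 0.5)
  f5 <- fem_solve(mesh5, mat, radial_dirichlet(mesh5, 250))
  fs5 <- field_summary(f5, threshold = 0.05)
  r_star <- uniroot(function(r) analytic_annulus(5, 500, 250, r) - 0.05 * 250,
                    c(5, 500))$root
  expect_lt(abs(fs5$extent_radius - r_star) / r_star, 0.05)
})

test_that("VTK and CSV field exports are well-formed", {
  mesh <- annulus_mesh(5, 50, 1.5)
  field <- fem_solve(mesh, elastic_material(2000), radial_dirichlet(mesh, 10))
  vtk <- tempfile(fileext = ".vtk")
  write_vtk_field(field, vtk)
  lines <- readLines(vtk)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS ", lines)))
  expect_true(any(grepl("^VECTORS u", lines)))
  expect_true(any(grepl("von_mises", lines)))
  npts <- as.integer(strsplit(grep("^POINTS", lines, value = TRUE), " ")[[1]][2])
  expect_equal(npts, nrow(mesh$nodes))

  csv <- tempfile(fileext = ".csv")
  write_field_csv(field, csv)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), nrow(mesh$nodes))
  expect_equal(max(tab$u_mag_um), 10, tolerance = 1e-9)
})
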