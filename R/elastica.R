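## 2-D plane-strain linear-elastic model of growth-induced gel deformation.
##
## The spheroid is represented as a cavity in the gel: the reference domain is
## the annulus between the 5-um seed circle (the single cell the spheroid grew
## from) and a far outer circle. Growth is imposed as prescribed displacement
## of the cavity boundary onto the observed final spheroid outline via a
## radial ray map; the outer boundary is fixed. The spheroid interior is
## excluded - the model estimates deformation of the gel adjacent to the
## spheroid, not stress inside it. One linear solve on the reference
## configuration is used even though displacements are geometrically large;
## this small-strain idealization is a stated fidelity limitation of the
## approach, not of the implementation.

#' Linear elastic material for plane-strain analysis
#'
#' @param E Young's modulus, Pa (> 0).
#' @param nu Poisson ratio, in (-1, 0.5) strictly so the plane-strain
#'   operator stays nonsingular. Default 0.45 (agarose, near-incompressible).
#' @return object of class `elastic_material`.
#' @export
elastic_material <- function(E, nu = 0.45) {
  if (!is.finite(E) || E <= 0) stop("'E' must be > 0")
  if (!is.finite(nu) || nu <= -1 || nu >= 0.5)
    stop("'nu' must lie strictly in (-1, 0.5)")
  structure(list(E = E, nu = nu), class = "elastic_material")
}

# plane-strain constitutive matrix (Voigt order exx, eyy, gxy)
plane_strain_D <- function(material) {
  E <- material$E; nu <- material$nu
  f <- E / ((1 + nu) * (1 - 2 * nu))
  f * matrix(c(1 - nu, nu, 0,
               nu, 1 - nu, 0,
               0, 0, (1 - 2 * nu) / 2), 3L, 3L)
}

#' Growth problem: expand a seed circle to an observed spheroid outline
#'
#' @param final_geometry a [spheroid_geometry]: the observed final spheroid
#'   outline (um). Must strictly contain the seed circle and be star-shaped
#'   about `seed_center` (checked), as required by the radial boundary map.
#' @param material an [elastic_material] for the gel.
#' @param seed_radius initial radius of the single founding cell, um
#'   (default 5).
#' @param seed_center center of the seed circle (um); default the centroid of
#'   the final geometry.
#' @param outer_radius radius of the fixed outer boundary, um; default 20
#'   times the equivalent final radius `sqrt(area / pi)`, at least 10 times.
#' @return object of class `growth_problem`.
#' @export
growth_problem <- function(final_geometry, material, seed_radius = 5,
                           seed_center = NULL, outer_radius = NULL) {
  stopifnot(inherits(final_geometry, "spheroid_geometry"),
            inherits(material, "elastic_material"))
  if (is.null(seed_center)) seed_center <- final_geometry$centroid
  r_eq <- sqrt(final_geometry$area / pi)
  if (is.null(outer_radius)) outer_radius <- 20 * r_eq
  if (outer_radius < 10 * r_eq)
    stop("'outer_radius' must be at least 10 x the equivalent final radius")
  rad <- boundary_radius_about(final_geometry, seed_center,
                               n_check = 256L)
  if (any(!is.finite(rad)))
    stop("geometry error: final geometry is not star-shaped about the seed center")
  if (min(rad) <= seed_radius)
    stop("final geometry must strictly contain the seed circle")
  structure(list(seed_radius = seed_radius, seed_center = seed_center,
                 final_geometry = final_geometry, outer_radius = outer_radius,
                 material = material),
            class = "growth_problem")
}

# radius of the final boundary along rays at n_check angles about a center;
# NA where a ray misses or crosses more than once (non-star-shaped)
boundary_radius_about <- function(geometry, center, n_check = 256L) {
  v <- sweep(geometry$vertices, 2L, center)
  th <- seq(0, 2 * pi, length.out = n_check + 1L)[-(n_check + 1L)]
  vapply(th, function(t) {
    tt <- ray_polygon_intersection(c(0, 0), c(cos(t), sin(t)), v)
    if (is.na(tt)) NA_real_ else tt
  }, numeric(1L))
}

#' Build a graded triangular mesh of the annular gel domain
#'
#' Structured triangulation of the annulus between the seed circle and the
#' outer circle: rings of nodes at geometrically graded radii, element size
#' `h_cavity` at the cavity growing proportionally to radius (capped at
#' `grading * h_cavity` when `grading` is given), with each quad split into
#' two positively oriented triangles. The proportional-to-radius grading
#' keeps triangles near-isotropic at every radius.
#'
#' @param problem a [growth_problem].
#' @param h_cavity target element size at the cavity boundary, um; must be
#'   smaller than the seed radius.
#' @param grading optional cap on element size at the outer boundary as a
#'   multiple of `h_cavity`; `NULL` (default) lets size grow proportionally
#'   to radius.
#' @return object of class `fem_mesh`: list with `nodes` (n x 2 um,
#'   relative to the seed center), `triangles` (m x 3 node indices, CCW),
#'   `cavity_nodes`, `outer_nodes` (index vectors), `seed_center`.
#' @export
build_mesh <- function(problem, h_cavity = problem$seed_radius / 5,
                       grading = NULL) {
  annulus_mesh(problem$seed_radius, problem$outer_radius, h_cavity,
               grading = grading, seed_center = problem$seed_center)
}

#' Triangulated annulus between two concentric circles
#'
#' The mesh builder underlying [build_mesh()], also usable on its own for
#' verification problems where the annulus radii are given directly.
#'
#' @param a cavity (inner) radius, um.
#' @param R outer radius, um.
#' @param h_cavity target element size at the cavity boundary, um (< a).
#' @param grading optional cap on outer element size (multiple of
#'   `h_cavity`).
#' @param seed_center physical center of the annulus (um); node coordinates
#'   stay relative to it.
#' @return a `fem_mesh` (see [build_mesh()]).
#' @export
annulus_mesh <- function(a, R, h_cavity = a / 5, grading = NULL,
                         seed_center = c(0, 0)) {
  if (a >= R) stop("mesh error: need a < R")
  if (h_cavity >= a) stop("'h_cavity' must be smaller than the seed radius")
  n_theta <- max(16L, ceiling(2 * pi * a / h_cavity))
  radii <- ring_radii(a, R, h_cavity, n_theta, grading)
  n_rings <- length(radii)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  nodes <- cbind(as.vector(outer(cos(th), radii)),
                 as.vector(outer(sin(th), radii)))
  node_id <- function(ring, j) (ring - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  tris <- vector("list", n_rings - 1L)
  for (k in seq_len(n_rings - 1L)) {
    j <- seq_len(n_theta)
    i00 <- node_id(k, j);     i10 <- node_id(k, j + 1L)
    i01 <- node_id(k + 1L, j); i11 <- node_id(k + 1L, j + 1L)
    tris[[k]] <- rbind(cbind(i00, i11, i10), cbind(i00, i01, i11))
  }
  triangles <- do.call(rbind, tris)
  mesh <- structure(list(nodes = nodes, triangles = triangles,
                         cavity_nodes = seq_len(n_theta),
                         outer_nodes = node_id(n_rings, seq_len(n_theta)),
                         seed_center = seed_center,
                         h_cavity = h_cavity),
                    class = "fem_mesh")
  areas <- triangle_areas(mesh)
  if (any(areas <= 0)) stop("mesh error: non-positive triangle area")
  mesh
}

# geometrically graded ring radii from a to R with first gap ~ h at the
# cavity; gap growth follows radius, optionally capped at grading*h
ring_radii <- function(a, R, h, n_theta, grading) {
  radii <- a
  r <- a
  q <- 1 + 2 * pi / n_theta     # per-ring growth for isotropic triangles
  repeat {
    gap <- r * (q - 1)
    if (!is.null(grading)) gap <- min(gap, grading * h)
    gap <- max(gap, h)
    r <- r + gap
    if (r >= R - gap / 2) break
    radii <- c(radii, r)
  }
  c(radii, R)
}

triangle_areas <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  x1 <- p[t[, 1L], 1L]; y1 <- p[t[, 1L], 2L]
  x2 <- p[t[, 2L], 1L]; y2 <- p[t[, 2L], 2L]
  x3 <- p[t[, 3L], 1L]; y3 <- p[t[, 3L], 2L]
  ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)) / 2
}

#' Prescribed displacement of cavity nodes onto the final spheroid outline
#'
#' Radial ray correspondence: a cavity node at angle `theta` on the seed
#' circle moves along the ray at `theta` from the seed center to where that
#' ray crosses the final boundary. Requires the final geometry to be
#' star-shaped about the seed center.
#'
#' @param problem a [growth_problem].
#' @param cavity_points n x 2 matrix of cavity node positions relative to the
#'   seed center (um), e.g. `mesh$nodes[mesh$cavity_nodes, ]`.
#' @return n x 2 matrix of prescribed displacement vectors (um).
#' @export
boundary_displacement_map <- function(problem, cavity_points) {
  v <- sweep(problem$final_geometry$vertices, 2L, problem$seed_center)
  n <- nrow(cavity_points)
  u <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    p <- cavity_points[i, ]
    r0 <- sqrt(sum(p^2))
    dirv <- p / r0
    t <- ray_polygon_intersection(c(0, 0), dirv, v)
    if (is.na(t))
      stop("geometry error: ray from seed center misses the final boundary")
    u[i, ] <- dirv * (t - r0)
  }
  u
}

#' Solve the plane-strain growth problem
#'
#' Assembles linear (constant-strain) triangular elements into the sparse
#' symmetric stiffness matrix, applies Dirichlet conditions (prescribed
#' displacement on the cavity, zero on the outer boundary), and solves with a
#' sparse Cholesky factorization. Strain is recovered from shape-function
#' gradients per element and stress via the plane-strain constitutive matrix.
#'
#' @param problem a [growth_problem].
#' @param mesh a [build_mesh()] result; built at default resolution when
#'   omitted.
#' @param prescribed cavity-node displacements; computed with
#'   [boundary_displacement_map()] when omitted.
#' @return object of class `displacement_field`: list with `u` (n x 2, um),
#'   `strain` (m x 3 Voigt: exx, eyy, gxy), `stress` (m x 3, Pa),
#'   `von_mises` (m, Pa), `mesh`, `material`, `residual` (relative).
#' @export
solve_growth <- function(problem, mesh = NULL, prescribed = NULL) {
  stopifnot(inherits(problem, "growth_problem"))
  if (is.null(mesh)) mesh <- build_mesh(problem)
  if (is.null(prescribed))
    prescribed <- boundary_displacement_map(
      problem, mesh$nodes[mesh$cavity_nodes, , drop = FALSE])
  dirichlet <- rbind(
    cbind(mesh$cavity_nodes, prescribed),
    cbind(mesh$outer_nodes, 0, 0))
  fem_solve(mesh, problem$material, dirichlet)
}

#' Low-level plane-strain finite-element solve with Dirichlet data
#'
#' @param mesh a `fem_mesh`.
#' @param material an [elastic_material].
#' @param dirichlet 3-column matrix: node index, prescribed ux, uy (um).
#'   Every listed node is constrained; all others are free.
#' @return a `displacement_field` (see [solve_growth()]).
#' @export
fem_solve <- function(mesh, material, dirichlet) {
  p <- mesh$nodes; tri <- mesh$triangles
  n <- nrow(p); m <- nrow(tri)
  D <- plane_strain_D(material)
  x1 <- p[tri[, 1L], 1L]; y1 <- p[tri[, 1L], 2L]
  x2 <- p[tri[, 2L], 1L]; y2 <- p[tri[, 2L], 2L]
  x3 <- p[tri[, 3L], 1L]; y3 <- p[tri[, 3L], 2L]
  area2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)   # 2*area
  if (any(area2 <= 0)) stop("mesh error: non-positively-oriented triangle")
  # shape-function gradients: b_i = dN_i/dx * 2A, c_i = dN_i/dy * 2A
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)
  # assemble triplets: per element the 6x6 stiffness K_e = A * B' D B
  ii <- jj <- vv <- vector("list", 36L)
  dof <- cbind(2L * tri[, 1L] - 1L, 2L * tri[, 1L],
               2L * tri[, 2L] - 1L, 2L * tri[, 2L],
               2L * tri[, 3L] - 1L, 2L * tri[, 3L])
  # B matrix rows (per element, vectorized over elements):
  # Bx holds d/dx of shape fns, By d/dy, both divided by 2A
  Bx <- b / area2; By <- cc / area2
  idx <- 0L
  for (ai in 1:6) for (aj in 1:6) {
    ni <- (ai + 1L) %/% 2L; di <- 2L - (ai %% 2L)    # node, direction (1=x,2=y)
    nj <- (aj + 1L) %/% 2L; dj <- 2L - (aj %% 2L)
    # strain-displacement columns for dof (ni, di): [exx, eyy, gxy]
    Bi1 <- if (di == 1L) Bx[, ni] else 0
    Bi2 <- if (di == 2L) By[, ni] else 0
    Bi3 <- if (di == 1L) By[, ni] else Bx[, ni]
    Bj1 <- if (dj == 1L) Bx[, nj] else 0
    Bj2 <- if (dj == 2L) By[, nj] else 0
    Bj3 <- if (dj == 1L) By[, nj] else Bx[, nj]
    kij <- (Bi1 * (D[1, 1] * Bj1 + D[1, 2] * Bj2 + D[1, 3] * Bj3) +
            Bi2 * (D[2, 1] * Bj1 + D[2, 2] * Bj2 + D[2, 3] * Bj3) +
            Bi3 * (D[3, 1] * Bj1 + D[3, 2] * Bj2 + D[3, 3] * Bj3)) *
      (area2 / 2)
    idx <- idx + 1L
    ii[[idx]] <- dof[, ai]; jj[[idx]] <- dof[, aj]; vv[[idx]] <- kij
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(2L * n, 2L * n))
  # Dirichlet partition
  u <- numeric(2L * n)
  cn <- as.integer(dirichlet[, 1L])
  cdof <- c(2L * cn - 1L, 2L * cn)
  u[2L * cn - 1L] <- dirichlet[, 2L]
  u[2L * cn] <- dirichlet[, 3L]
  free <- setdiff(seq_len(2L * n), cdof)
  rhs <- -K[free, cdof, drop = FALSE] %*% u[cdof]
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  sol <- tryCatch(Matrix::solve(Kff, rhs),
                  error = function(e) stop("solver error: ", conditionMessage(e)))
  u[free] <- as.numeric(sol)
  res <- as.numeric(sqrt(sum((Kff %*% u[free] - rhs)^2)) /
                      max(sqrt(sum(rhs^2)), .Machine$double.eps))
  U <- matrix(u, ncol = 2L, byrow = TRUE)
  # element strains and stresses
  ue1x <- U[tri[, 1L], 1L]; ue1y <- U[tri[, 1L], 2L]
  ue2x <- U[tri[, 2L], 1L]; ue2y <- U[tri[, 2L], 2L]
  ue3x <- U[tri[, 3L], 1L]; ue3y <- U[tri[, 3L], 2L]
  exx <- Bx[, 1L] * ue1x + Bx[, 2L] * ue2x + Bx[, 3L] * ue3x
  eyy <- By[, 1L] * ue1y + By[, 2L] * ue2y + By[, 3L] * ue3y
  gxy <- By[, 1L] * ue1x + By[, 2L] * ue2x + By[, 3L] * ue3x +
         Bx[, 1L] * ue1y + Bx[, 2L] * ue2y + Bx[, 3L] * ue3y
  strain <- cbind(exx = exx, eyy = eyy, gxy = gxy)
  stress <- strain %*% t(D)
  colnames(stress) <- c("sxx", "syy", "sxy")
  szz <- material$nu * (stress[, 1L] + stress[, 2L])   # plane strain
  vm <- sqrt(0.5 * ((stress[, 1L] - stress[, 2L])^2 +
                    (stress[, 2L] - szz)^2 +
                    (szz - stress[, 1L])^2) + 3 * stress[, 3L]^2)
  structure(list(u = U, strain = strain, stress = stress, von_mises = vm,
                 mesh = mesh, material = material, residual = res),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  cat(sprintf(
    "displacement_field: %d nodes, %d elements, max |u| = %.2f um, max von Mises = %.3g Pa\n",
    nrow(x$u), nrow(x$strain), max(sqrt(rowSums(x$u^2))), max(x$von_mises)))
  invisible(x)
}

#' Closed-form radial displacement in a pressurized annulus (Lame solution)
#'
#' Axisymmetric plane-strain displacement `u(r) = A r + B / r` for an annulus
#' `a < r < R` with prescribed radial displacement `u_a` at the cavity and
#' zero at the outer boundary: `A = u_a a / (a^2 - R^2)`, `B = -A R^2`. Holds
#' for every admissible Poisson ratio, which is why it anchors the
#' finite-element verification.
#'
#' @param a cavity radius, um.
#' @param R outer radius, um (> a).
#' @param u_a prescribed radial displacement at `r = a`, um.
#' @param r radii at which to evaluate (a <= r <= R), um; vectorized.
#' @return radial displacement at `r`, um.
#' @export
analytic_annulus <- function(a, R, u_a, r) {
  if (a >= R) stop("parameter error: need a < R")
  A <- u_a * a / (a^2 - R^2)
  B <- -A * R^2
  A * r + B / r
}

#' Summarize a solved displacement field
#'
#' @param field a `displacement_field`.
#' @param threshold fraction of the maximum displacement defining the
#'   deformation extent (default 0.05); must lie in (0, 1).
#' @param n_rays number of rays from the seed center for decay profiles.
#' @return list with `max_displacement` (um), `profiles` (data frame: ray
#'   angle, r, u_mag from nodes binned to the nearest ray), `extent_radius`
#'   (largest radius where |u| still exceeds `threshold * max`, um).
#' @export
field_summary <- function(field, threshold = 0.05, n_rays = 8L) {
  if (threshold <= 0 || threshold >= 1)
    stop("parameter error: 'threshold' must be in (0, 1)")
  umag <- sqrt(rowSums(field$u^2))
  umax <- max(umag)
  p <- field$mesh$nodes
  r <- sqrt(rowSums(p^2))
  ang <- atan2(p[, 2L], p[, 1L]) %% (2 * pi)
  ray_angles <- seq(0, 2 * pi, length.out = n_rays + 1L)[-(n_rays + 1L)]
  ray <- vapply(ang, function(a) {
    d <- abs(((a - ray_angles + pi) %% (2 * pi)) - pi)
    which.min(d)
  }, integer(1L))
  sel <- abs((((ang - ray_angles[ray]) + pi) %% (2 * pi)) - pi) < 1e-6
  profiles <- data.frame(ray = ray[sel], angle = ray_angles[ray[sel]],
                         r = r[sel], u_mag = umag[sel])
  profiles <- profiles[order(profiles$ray, profiles$r), ]
  extent <- if (umax == 0) 0 else max(r[umag >= threshold * umax])
  list(max_displacement = umax, profiles = profiles, extent_radius = extent)
}
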