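# shared fixtures: small geometric and FEM helpers used across test files

circle_geometry <- function(radius, center = c(0, 0), n = 128L) {
  spheroid_geometry(ellipse_polygon(center, radius, radius, n_vertices = n))
}

# Dirichlet data for a purely radial cavity expansion on an annulus mesh
radial_dirichlet <- function(mesh, u_a) {
  cav <- mesh$nodes[mesh$cavity_nodes, , drop = FALSE]
  dirv <- cav / sqrt(rowSums(cav^2))
  rbind(cbind(mesh$cavity_nodes, dirv * u_a),
        cbind(mesh$outer_nodes, 0, 0))
}

# relative L-infinity error of a radial FEM solution vs the Lame solution
annulus_linf_error <- function(field, a, R, u_a) {
  r <- sqrt(rowSums(field$mesh$nodes^2))
  uex <- analytic_annulus(a, R, u_a, r)
  umag <- sqrt(rowSums(field$u^2))
  max(abs(umag - uex)) / max(abs(uex))
}

# two-sided exact permutation p-value for the Mann-Whitney U, by full
# enumeration of the choose(nx+ny, nx) group assignments
brute_force_mw_p <- function(x, y) {
  nx <- length(x)
  rk <- rank(c(x, y))
  U <- sum(rk[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(rk), nx)
  us <- colSums(matrix(rk[combs], nrow = nx)) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9)))
}

# minimal two-sample Ct table (one target gene, one reference gene)
two_sample_ct <- function(ct_ctrl_target, ct_ctrl_ref, ct_trt_target,
                          ct_trt_ref, gene = "Ki67", ref = "GAPDH") {
  ct_table(data.frame(
    sample_id = c("ctrl_1", "ctrl_1", "trt_1", "trt_1"),
    condition = c("control", "control", "treated", "treated"),
    gene = c(gene, ref, gene, ref),
    ct = c(ct_ctrl_target, ct_ctrl_ref, ct_trt_target, ct_trt_ref)),
    reference_gene = ref, control_condition = "control")
}
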