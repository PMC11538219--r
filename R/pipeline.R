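## Pipeline orchestration: generate -> analyze -> model -> report from a
## single JSON config, with a manifest recording every artifact.

#' Default pipeline configuration
#'
#' A compact three-condition study mirroring the standard design: agarose
#' concentrations 0.5/1/2% with condition-mean spheroid areas, compression
#' samples per concentration, a Ki67-style Ct table, and one growth
#' simulation per concentration. Small enough to run end-to-end in well under
#' five minutes on one CPU.
#'
#' @param seed master seed for every stage.
#' @return nested configuration list accepted by [run_pipeline()].
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(synthetic = TRUE, morphometry = TRUE, rheology = TRUE,
                  qpcr = TRUE, elastica = TRUE, report = TRUE),
    spheroids = list(
      conditions = list(
        list(name = "agarose_0.5pct", mean_area_um2 = 5484),
        list(name = "agarose_1pct", mean_area_um2 = 2669),
        list(name = "agarose_2pct", mean_area_um2 = 1316)),
      n_spheroids = 60L, cv_area = 0.5, um_per_px = 2, n_fields = 2L,
      spheroids_per_field = 30L),
    viability = list(n_live = 190L, n_dead = 10L, cell_radius_um = 6,
                     width_px = 400L, height_px = 400L, um_per_px = 1),
    compression = list(
      samples = list(
        list(name = "agarose_0.5pct", E_true_pa = 3800),
        list(name = "agarose_1pct", E_true_pa = 12100),
        list(name = "agarose_2pct", E_true_pa = 44800)),
      n_replicates = 3L, toe_strain = 0.05, max_strain = 0.4,
      n_points = 200L, noise_sd_frac = 0.01),
    qpcr = list(conditions = c("agarose_1pct", "agarose_2pct"),
                genes = c("Ki67", "GAPDH"), reference_gene = "GAPDH",
                fold_treated = 0.23, replicates = 4L, ct_noise_sd = 0.15),
    elastica = list(
      materials = list(
        list(name = "agarose_0.5pct", E_pa = 2000),
        list(name = "agarose_1pct", E_pa = 19830),
        list(name = "agarose_2pct", E_pa = 99596)),
      nu = 0.45, seed_radius_um = 5, h_cavity_um = 1,
      outer_radius_factor = 20))
}

known_config_keys <- c("seed", "stages", "spheroids", "viability",
                       "compression", "qpcr", "elastica", "output_dir")

validate_config <- function(config) {
  unknown <- setdiff(names(config), known_config_keys)
  if (length(unknown) > 0L)
    stop("validation error: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("validation error: config needs a 'seed'")
  invisible(config)
}

#' Run the full pipeline from a configuration
#'
#' Executes the enabled stages in dependency order - synthetic data
#' generation, then morphometry / rheology / qPCR analytics, then the
#' growth-model simulations, then the report - writing every artifact under
#' `output_dir` and recording it in the returned manifest (stage, file, md5,
#' parameters). Reruns with the same config and seed reproduce the same
#' artifact hashes.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   JSON file with the same structure.
#' @param output_dir output directory (created if needed); overrides
#'   `config$output_dir`.
#' @return object of class `run_manifest`: list with `artifacts` (data
#'   frame), `config`, `summaries`.
#' @export
run_pipeline <- function(config = default_config(), output_dir = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  validate_config(config)
  out <- output_dir %||% config$output_dir %||% tempfile("spherostress_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages %||% list()
  on_stage <- function(name) isTRUE(stages[[name]] %||% TRUE)
  manifest <- list()
  add <- function(stage, path, params = list()) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)),
      params = jsonlite::toJSON(params, auto_unbox = TRUE))
  }
  summaries <- list()
  seed <- as.integer(config$seed)

  ## ---- spheroid populations: generate, render, segment ------------------
  if (on_stage("synthetic") && !is.null(config$spheroids)) {
    sp <- config$spheroids
    area_rows <- list()
    for (ci in seq_along(sp$conditions)) {
      cond <- sp$conditions[[ci]]
      geoms_cond <- list()
      for (f in seq_len(sp$n_fields)) {
        spec <- spheroid_population_spec(
          n_spheroids = sp$spheroids_per_field, mean_area = cond$mean_area_um2,
          cv_area = sp$cv_area, shape = "ellipse",
          aspect_ratio_range = c(1, 1.3),
          seed = seed + 1000L * ci + f)
        geoms <- gen_spheroid_population(spec)
        side_px <- ceiling(attr(geoms, "field_size_um") / sp$um_per_px)
        ispec <- image_spec(side_px, side_px, um_per_px = sp$um_per_px,
                            noise_sd = 0.02, seed = seed + 1000L * ci + f)
        ren <- render_image(geoms, ispec)
        img_path <- file.path(out, sprintf("spheroids_%s_f%d.tiff",
                                           cond$name, f))
        write_image_tiff(ren$image, img_path)
        add("synthetic", img_path, list(condition = cond$name, field = f))
        if (on_stage("morphometry")) {
          seg <- segment_spheroids(ren$image, um_per_px = sp$um_per_px)
          geoms_cond <- c(geoms_cond, seg)
          tabf <- attr(seg, "table")
          if (nrow(tabf) > 0L) tabf$condition <- cond$name
          area_rows[[length(area_rows) + 1L]] <- tabf
        }
      }
      if (on_stage("morphometry") && length(geoms_cond) > 0L) {
        gj <- file.path(out, sprintf("geometries_%s.json", cond$name))
        write_geometry_json(geoms_cond, gj)
        add("morphometry", gj, list(condition = cond$name))
      }
    }
    if (on_stage("morphometry")) {
      areas <- do.call(rbind, area_rows)
      ap <- file.path(out, "areas.csv")
      utils::write.csv(areas, ap, row.names = FALSE)
      add("morphometry", ap)
      summaries$areas <- areas
    }
  }

  ## ---- viability --------------------------------------------------------
  if (on_stage("synthetic") && on_stage("morphometry") &&
      !is.null(config$viability)) {
    vb <- config$viability
    ispec <- image_spec(vb$width_px, vb$height_px, um_per_px = vb$um_per_px,
                        channels = 2L, noise_sd = 0.02, seed = seed + 77L)
    ld <- gen_livedead_stack(vb$n_live, vb$n_dead, vb$cell_radius_um, ispec)
    sp_path <- file.path(out, "livedead_stack.tiff")
    write_image_tiff(ld$stack, sp_path)
    add("synthetic", sp_path, list(n_live = vb$n_live, n_dead = vb$n_dead))
    via <- count_live_dead(ld$stack)
    vp <- file.path(out, "viability.csv")
    utils::write.csv(data.frame(n_live = via$n_live, n_dead = via$n_dead,
                                viability = via$viability), vp,
                     row.names = FALSE)
    add("morphometry", vp)
    summaries$viability <- via
  }

  ## ---- compression / modulus fits ---------------------------------------
  if (on_stage("synthetic") && on_stage("rheology") &&
      !is.null(config$compression)) {
    cp <- config$compression
    fit_rows <- list()
    for (si in seq_along(cp$samples)) {
      s <- cp$samples[[si]]
      for (r in seq_len(cp$n_replicates)) {
        curve <- gen_stress_strain(s$E_true_pa, cp$toe_strain, cp$max_strain,
                                   cp$n_points, cp$noise_sd_frac,
                                   seed = seed + 100L * si + r)
        cpath <- file.path(out, sprintf("compression_%s_r%d.csv", s$name, r))
        write_curve_csv(curve, cpath)
        add("synthetic", cpath, list(sample = s$name, E_true = s$E_true_pa))
        fit <- young_modulus(curve)
        fit_rows[[length(fit_rows) + 1L]] <- data.frame(
          sample = s$name, replicate = r, E_pa = fit$E,
          r2 = fit$r_squared, region_lo = fit$region[1L],
          region_hi = fit$region[2L], E_true_pa = s$E_true_pa)
      }
    }
    fits <- do.call(rbind, fit_rows)
    fp <- file.path(out, "moduli.csv")
    utils::write.csv(fits, fp, row.names = FALSE)
    add("rheology", fp)
    summaries$moduli <- fits
  }

  ## ---- qPCR -------------------------------------------------------------
  if (on_stage("synthetic") && on_stage("qpcr") && !is.null(config$qpcr)) {
    q <- config$qpcr
    target <- setdiff(q$genes, q$reference_gene)
    folds <- matrix(1, length(q$conditions), length(target),
                    dimnames = list(q$conditions, target))
    folds[-1L, ] <- q$fold_treated
    tab <- gen_ct_table(q$conditions, q$genes, q$reference_gene, folds,
                        replicates = q$replicates,
                        ct_noise_sd = q$ct_noise_sd, seed = seed + 55L)
    tp <- file.path(out, "ct_table.csv")
    write_ct_csv(tab, tp)
    add("synthetic", tp, list(fold_treated = q$fold_treated))
    fc <- delta_delta_ct(tab, outlier_alpha = 0.05)
    pf <- file.path(out, "folds.csv")
    utils::write.csv(fc$per_sample, pf, row.names = FALSE)
    add("qpcr", pf)
    sf <- file.path(out, "folds_summary.csv")
    utils::write.csv(fc$per_condition, sf, row.names = FALSE)
    add("qpcr", sf)
    summaries$folds <- fc
  }

  ## ---- growth simulations ------------------------------------------------
  if (on_stage("elastica") && !is.null(config$elastica)) {
    el <- config$elastica
    fem_rows <- list()
    for (mi in seq_along(el$materials)) {
      mat_cfg <- el$materials[[mi]]
      mean_area <- fem_target_area(summaries$areas, config, mat_cfg$name)
      geom <- spheroid_geometry(ellipse_polygon(
        c(0, 0), sqrt(mean_area / pi), sqrt(mean_area / pi)))
      prob <- growth_problem(geom, elastic_material(mat_cfg$E_pa, el$nu),
                             seed_radius = el$seed_radius_um,
                             seed_center = c(0, 0),
                             outer_radius = el$outer_radius_factor *
                               sqrt(mean_area / pi))
      field <- solve_growth(prob, build_mesh(prob, el$h_cavity_um))
      fs <- field_summary(field)
      vtk <- file.path(out, sprintf("field_%s.vtk", mat_cfg$name))
      write_vtk_field(field, vtk)
      add("elastica", vtk, list(E_pa = mat_cfg$E_pa, nu = el$nu))
      fem_rows[[length(fem_rows) + 1L]] <- data.frame(
        condition = mat_cfg$name, E_pa = mat_cfg$E_pa,
        final_area_um2 = mean_area,
        max_displacement_um = fs$max_displacement,
        extent_radius_um = fs$extent_radius)
    }
    fem_tab <- do.call(rbind, fem_rows)
    fj <- file.path(out, "fem_summary.json")
    jsonlite::write_json(fem_tab, fj, dataframe = "rows", digits = NA)
    add("elastica", fj)
    summaries$fem <- fem_tab
  }

  manifest_df <- if (length(manifest) > 0L) do.call(rbind, manifest)
    else data.frame(stage = character(), file = character(),
                    md5 = character(), params = character())
  res <- structure(list(artifacts = manifest_df, config = config,
                        summaries = summaries, output_dir = out),
                   class = "run_manifest")
  if (on_stage("report")) {
    rep <- report(res)
    for (nm in names(rep)) {
      rp <- file.path(out, sprintf("report_%s.csv", nm))
      utils::write.csv(rep[[nm]], rp, row.names = FALSE)
    }
    res$report <- rep
  }
  mp <- file.path(out, "manifest.csv")
  utils::write.csv(manifest_df, mp, row.names = FALSE)
  res
}

# mean segmented area for a condition, falling back to the configured
# generator mean when morphometry did not run
fem_target_area <- function(areas, config, condition) {
  if (!is.null(areas)) {
    sub <- areas[areas$condition == condition, , drop = FALSE]
    if (nrow(sub) > 0L) return(mean(sub$area_um2))
  }
  for (cond in config$spheroids$conditions)
    if (cond$name == condition) return(cond$mean_area_um2)
  stop("report error: no area information for condition '", condition, "'")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest:", nrow(x$artifacts), "artifacts in", x$output_dir, "\n")
  print(table(x$artifacts$stage))
  invisible(x)
}

#' Summary tables from a completed pipeline run
#'
#' Condition-wise aggregates: spheroid area mean +/- SEM with the
#' Kruskal-Wallis / Dunn group comparison (when >= 3 conditions), modulus
#' means per concentration, per-condition fold changes with Mann-Whitney
#' p-values against the control, and the growth-model field summaries.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @return named list of data frames.
#' @export
report <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  s <- manifest$summaries
  if (length(s) == 0L) stop("report error: manifest has no stage outputs")
  out <- list()
  if (!is.null(s$areas)) {
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    ag <- do.call(rbind, lapply(split(s$areas, s$areas$condition), function(d)
      data.frame(condition = d$condition[1L], n = nrow(d),
                 mean_area_um2 = mean(d$area_um2),
                 sem_area_um2 = sem(d$area_um2))))
    rownames(ag) <- NULL
    groups <- split(s$areas$area_um2, s$areas$condition)
    if (length(groups) >= 3L && all(lengths(groups) >= 2L)) {
      kw <- kruskal_dunn(groups)
      ag$kruskal_p <- kw$p
    }
    out$areas <- ag
  }
  if (!is.null(s$viability))
    out$viability <- data.frame(n_live = s$viability$n_live,
                                n_dead = s$viability$n_dead,
                                viability_pct = 100 * s$viability$viability)
  if (!is.null(s$moduli)) {
    mg <- do.call(rbind, lapply(split(s$moduli, s$moduli$sample), function(d)
      data.frame(sample = d$sample[1L], n = nrow(d),
                 E_mean_pa = mean(d$E_pa),
                 E_sem_pa = stats::sd(d$E_pa) / sqrt(nrow(d)),
                 E_true_pa = d$E_true_pa[1L])))
    rownames(mg) <- NULL
    out$moduli <- mg
  }
  if (!is.null(s$folds)) {
    pc <- s$folds$per_condition
    ps <- s$folds$per_sample
    ctrl <- attr(manifest$config, "control") %||% unique(ps$condition)[1L]
    pvals <- rep(NA_real_, nrow(pc))
    for (i in seq_len(nrow(pc))) {
      if (pc$condition[i] == ctrl) next
      xi <- ps$fold[ps$condition == pc$condition[i] & ps$gene == pc$gene[i]]
      yi <- ps$fold[ps$condition == ctrl & ps$gene == pc$gene[i]]
      if (length(xi) > 0L && length(yi) > 0L)
        pvals[i] <- mann_whitney(xi, yi)$p
    }
    pc$mann_whitney_p <- pvals
    out$folds <- pc
  }
  if (!is.null(s$fem)) out$fem <- s$fem
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
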