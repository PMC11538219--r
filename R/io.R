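## File interfaces: CSV curves and Ct tables, JSON geometries, TIFF images,
## legacy-VTK field export.

#' Write / read a stress-strain curve as CSV
#'
#' Columns `strain,stress_pa`. [read_curve_csv()] also accepts raw
#' force-displacement records (`force_n,displacement_mm`), converting them
#' with [force_to_stress_strain()].
#'
#' @param curve a [stress_strain_curve].
#' @param path file path.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("strain", "stress_pa")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param diameter_mm,height_mm sample geometry used when converting a
#'   force-displacement record.
#' @export
read_curve_csv <- function(path, diameter_mm = 6, height_mm = 2) {
  d <- utils::read.csv(path)
  if (all(c("strain", "stress_pa") %in% names(d)))
    return(stress_strain_curve(d$strain, d$stress_pa))
  if (all(c("force_n", "displacement_mm") %in% names(d)))
    return(force_to_stress_strain(d$force_n, d$displacement_mm,
                                  diameter_mm, height_mm))
  stop("unrecognized curve CSV: need (strain,stress_pa) or (force_n,displacement_mm)")
}

#' Write / read a Ct table as CSV
#'
#' Columns `sample_id,condition,gene,ct`.
#'
#' @param table a [ct_table].
#' @param path file path.
#' @export
write_ct_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table)[, c("sample_id", "condition",
                                            "gene", "ct")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_csv
#' @param reference_gene,control_condition labels attached on read.
#' @export
read_ct_csv <- function(path, reference_gene, control_condition) {
  ct_table(utils::read.csv(path), reference_gene, control_condition)
}

#' Write / read spheroid geometries as JSON
#'
#' A JSON list of objects, each with a `vertices` array (n x 2, um).
#'
#' @param geometries list of [spheroid_geometry].
#' @param path file path.
#' @export
write_geometry_json <- function(geometries, path) {
  payload <- lapply(geometries, function(g)
    list(vertices = unname(g$vertices), area_um2 = g$area,
         solidity = g$solidity, eccentricity = g$eccentricity))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  lapply(payload, function(g) spheroid_geometry(g$vertices))
}

#' Write an image or stack as TIFF
#'
#' 2-D matrices become single-page TIFFs; `width x height x channels x
#' slices` arrays become multi-page TIFFs (channel-major page order). Label
#' masks are written as 16-bit.
#'
#' @param x image matrix or stack array, values in `[0, 1]`, or an integer
#'   label mask.
#' @param path file path.
#' @param label `TRUE` to write an integer label mask (16-bit).
#' @export
write_image_tiff <- function(x, path, label = FALSE) {
  if (label) {
    EBImage::writeImage(EBImage::Image(x / 65535), path, type = "tiff",
                        bits.per.sample = 16L)
    return(invisible(path))
  }
  d <- dim(x)
  if (length(d) == 4L) x <- array(x, c(d[1L], d[2L], d[3L] * d[4L]))
  EBImage::writeImage(EBImage::Image(x), path, type = "tiff",
                      bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, label = FALSE) {
  img <- EBImage::imageData(EBImage::readImage(path))
  if (label) img <- round(img * 65535)
  img
}

#' Export a displacement field as a legacy VTK unstructured grid
#'
#' ASCII legacy format: triangle cells, nodal displacement vectors `u`,
#' per-cell stress tensors and von Mises scalars. Readable by ParaView and
#' VTK-based tools.
#'
#' @param field a `displacement_field` from [solve_growth()].
#' @param path output path (conventionally `.vtk`).
#' @export
write_vtk_field <- function(field, path) {
  p <- field$mesh$nodes; tri <- field$mesh$triangles
  n <- nrow(p); m <- nrow(tri)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("# vtk DataFile Version 3.0")
  w("gel displacement field around an expanding spheroid")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS ", n, " double")
  utils::write.table(cbind(p, 0), con, row.names = FALSE, col.names = FALSE)
  w("CELLS ", m, " ", 4L * m)
  utils::write.table(cbind(3L, tri - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  w("CELL_TYPES ", m)
  writeLines(as.character(rep(5L, m)), con)
  w("POINT_DATA ", n)
  w("VECTORS u double")
  utils::write.table(cbind(field$u, 0), con, row.names = FALSE,
                     col.names = FALSE)
  w("CELL_DATA ", m)
  w("TENSORS stress double")
  s <- field$stress
  utils::write.table(cbind(s[, 1L], s[, 3L], 0, s[, 3L], s[, 2L], 0, 0, 0, 0),
                     con, row.names = FALSE, col.names = FALSE)
  w("SCALARS von_mises double 1")
  w("LOOKUP_TABLE default")
  writeLines(format(field$von_mises, scientific = TRUE), con)
  invisible(path)
}

#' Write a displacement field as a CSV table
#'
#' One row per node: position (um), displacement (um), displacement
#' magnitude.
#'
#' @param field a `displacement_field`.
#' @param path file path.
#' @export
write_field_csv <- function(field, path) {
  p <- field$mesh$nodes
  utils::write.csv(data.frame(x_um = p[, 1L], y_um = p[, 2L],
                              ux_um = field$u[, 1L], uy_um = field$u[, 2L],
                              u_mag_um = sqrt(rowSums(field$u^2))),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a morphometry table as CSV
#'
#' @param geometries result of [segment_spheroids()].
#' @param path file path.
#' @export
write_particles_csv <- function(geometries, path) {
  utils::write.csv(attr(geometries, "table"), path, row.names = FALSE)
  invisible(path)
}
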