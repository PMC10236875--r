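# Geometry and field exports: ASCII STL (geometry only), legacy ASCII VTK
# (geometry plus per-element or per-node scalars), landmark and field CSVs.
# Units are fixed package-wide: mm, mm^2, MPa, N, degrees.

node_xyz <- function(model) {
  th <- model$theta * pi / 180
  x <- outer(rep(1, model$n_z), cos(th)) * model$radius
  y <- outer(rep(1, model$n_z), sin(th)) * model$radius
  z <- matrix(rep(model$z, model$n_theta), nrow = model$n_z)
  list(x = x, y = y, z = z)
}

#' Export the wall mesh as ASCII STL
#'
#' Each quad panel is written as two triangles; geometry only.
#'
#' @param model An `aortic_root`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_stl <- function(model, path) {
  p <- node_xyz(model)
  el <- model$elements
  v <- function(r, c) c(p$x[r, c], p$y[r, c], p$z[r, c])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid aortic_root", con)
  tri <- function(a, b, d) {
    n <- cross3(b - a, d - a)
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(sprintf("facet normal %g %g %g", n[1], n[2], n[3]),
                 "  outer loop",
                 sprintf("    vertex %g %g %g", a[1], a[2], a[3]),
                 sprintf("    vertex %g %g %g", b[1], b[2], b[3]),
                 sprintf("    vertex %g %g %g", d[1], d[2], d[3]),
                 "  endloop", "endfacet"), con)
  }
  for (i in seq_len(nrow(el))) {
    a <- v(el$row[i], el$col[i]);      b <- v(el$row[i], el$col2[i])
    cc <- v(el$row[i] + 1L, el$col2[i]); d <- v(el$row[i] + 1L, el$col[i])
    tri(a, b, cc); tri(a, cc, d)
  }
  writeLines("endsolid aortic_root", con)
  invisible(path)
}

cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

#' Export the wall mesh (and optional scalars) as legacy ASCII VTK
#'
#' @param model An `aortic_root`.
#' @param path Output file path.
#' @param cell_scalars Optional named list of per-element numeric vectors
#'   (e.g. `list(pressure = field$pressure)`).
#' @param point_scalars Optional named list of n_z x n_theta matrices.
#' @return The path, invisibly.
#' @export
write_vtk <- function(model, path, cell_scalars = NULL, point_scalars = NULL) {
  p <- node_xyz(model)
  n_pts <- model$n_z * model$n_theta
  pid <- function(r, c) (c - 1L) * model$n_z + (r - 1L)  # zero-based
  el <- model$elements
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "aortic root wall", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n_pts)), con)
  writeLines(sprintf("%g %g %g", as.vector(p$x), as.vector(p$y),
                     as.vector(p$z)), con)
  ncell <- nrow(el)
  writeLines(sprintf("CELLS %d %d", ncell, ncell * 5), con)
  writeLines(sprintf("4 %d %d %d %d",
                     pid(el$row, el$col), pid(el$row, el$col2),
                     pid(el$row + 1L, el$col2), pid(el$row + 1L, el$col)), con)
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(rep("9", ncell), con)  # VTK_QUAD
  if (!is.null(cell_scalars)) {
    writeLines(sprintf("CELL_DATA %d", ncell), con)
    for (nm in names(cell_scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%g", cell_scalars[[nm]]), con)
    }
  }
  if (!is.null(point_scalars)) {
    writeLines(sprintf("POINT_DATA %d", n_pts), con)
    for (nm in names(point_scalars)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%g", as.vector(point_scalars[[nm]])), con)
    }
  }
  invisible(path)
}

#' Export the landmark registry as CSV
#'
#' @param model An `aortic_root`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_landmarks_csv <- function(model, path) {
  utils::write.csv(model$landmarks, path, row.names = FALSE)
  invisible(path)
}

#' Export a contact pressure field as CSV
#'
#' One row per element: element id, centroid angle and axial position,
#' area and pressure.
#'
#' @param field A `pressure_field`.
#' @param model The `aortic_root` it lives on.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_field_csv <- function(field, model, path) {
  el <- model$elements
  df <- data.frame(element = seq_len(nrow(el)),
                   theta = centroid_theta(model),
                   z = 0.5 * (model$z[el$row] + model$z[el$row + 1L]),
                   area = field$area,
                   pressure = field$pressure)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read root parameters as YAML
#'
#' @param params A [root_params()].
#' @param path File path.
#' @return `read_root_params` returns a `root_params`.
#' @export
write_root_params <- function(params, path) {
  yaml::write_yaml(list(
    diameters = as.list(params$diameters),
    axial_heights = as.list(params$axial_heights),
    ms_depths = as.list(params$ms_depths),
    ms_angles = as.list(params$ms_angles),
    cusp_angles = as.list(params$cusp_angles),
    calcium_volumes = apply(params$calcium_volumes, 1, as.list, simplify = FALSE)
  ), path)
  invisible(path)
}

#' @rdname write_root_params
#' @export
read_root_params <- function(path) {
  y <- yaml::read_yaml(path)
  vols <- zero_calcium()
  for (region in names(y$calcium_volumes)) {
    for (cusp in names(y$calcium_volumes[[region]])) {
      vols[region, cusp] <- y$calcium_volumes[[region]][[cusp]]
    }
  }
  root_params(
    lvot_diameter = y$diameters$lvot,
    annulus_diameter = y$diameters$annulus,
    sinus_diameter = y$diameters$sinus,
    stj_diameter = y$diameters$stj,
    ascending_diameter = y$diameters$ascending,
    axial_heights = unlist(y$axial_heights),
    ms_depth_ncc = y$ms_depths$ncc, ms_depth_mid = y$ms_depths$mid,
    ms_depth_rcc = y$ms_depths$rcc,
    calcium_volumes = vols,
    cusp_angles = unlist(y$cusp_angles),
    ms_angles = unlist(y$ms_angles))
}
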