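# Parametric synthetic aortic-root anatomy.
#
# Geometry is a surface of revolution: five named diameter levels (LVOT,
# annulus, sinus of Valsalva, sinotubular junction, ascending aorta) joined
# by a monotone-cubic axial radius profile. The annulus plane is z = 0 and
# the caudal (ventricular) direction is negative z. Angles are in degrees,
# with the non-coronary cusp nadir at theta = 0 by default.

#' Parametric aortic-root anatomy description
#'
#' Bundles the geometric and calcific parameters that define one synthetic
#' aortic root: the five cross-section diameters, their axial positions,
#' the membranous-septum depths at the three landmarks (non-coronary cusp,
#' mid-course, right-coronary cusp), per-region and per-cusp calcium volumes,
#' and the angular positions of the three cusp nadirs.
#'
#' @param lvot_diameter,annulus_diameter,sinus_diameter,stj_diameter,ascending_diameter
#'   Perimeter-derived diameters (mm) at the five levels. Defaults are the
#'   cohort means of a current-generation self-expanding TAVR population.
#' @param axial_heights Named numeric vector giving the axial position (mm,
#'   annulus plane = 0) of each diameter level.
#' @param ms_depth_ncc,ms_depth_mid,ms_depth_rcc Membranous-septum depth (mm)
#'   below the annulus at the three landmarks.
#' @param calcium_volumes Numeric matrix (regions x cusps) of calcium volumes
#'   in mm^3; rows `leaflet`, `upper_leaflet`, `landing_zone`, `lvot`;
#'   columns `NCC`, `RCC`, `LCC`.
#' @param cusp_angles Named numeric vector, angular position (degrees) of the
#'   three cusp nadirs.
#' @param ms_angles Named numeric vector, angular position (degrees) of the
#'   three membranous-septum landmarks.
#'
#' @return An object of class `root_params`.
#' @export
root_params <- function(lvot_diameter = 25.4,
                        annulus_diameter = 25.1,
                        sinus_diameter = 34.3,
                        stj_diameter = 28.9,
                        ascending_diameter = 32.1,
                        axial_heights = c(lvot = -10, annulus = 0, sinus = 12,
                                          stj = 22, ascending = 30),
                        ms_depth_ncc = 5.1,
                        ms_depth_mid = 3.5,
                        ms_depth_rcc = 1.7,
                        calcium_volumes = zero_calcium(),
                        cusp_angles = c(NCC = 0, RCC = 120, LCC = 240),
                        ms_angles = c(ncc = 30, mid = 60, rcc = 90)) {
  diams <- c(lvot = lvot_diameter, annulus = annulus_diameter,
             sinus = sinus_diameter, stj = stj_diameter,
             ascending = ascending_diameter)
  if (any(!is.finite(diams)) || any(diams <= 0)) {
    stop("invalid-parameter: all diameters must be finite and > 0",
         call. = FALSE)
  }
  ms <- c(ncc = ms_depth_ncc, mid = ms_depth_mid, rcc = ms_depth_rcc)
  if (any(ms < 0)) {
    stop("invalid-parameter: membranous-septum depths must be >= 0",
         call. = FALSE)
  }
  calcium_volumes <- validate_calcium_volumes(calcium_volumes)
  if (anyDuplicated(round(cusp_angles %% 360, 8)) > 0) {
    stop("invalid-parameter: cusp angles must be distinct modulo 360",
         call. = FALSE)
  }
  if (!all(names(axial_heights) == names(diams)) ||
      is.unsorted(axial_heights, strictly = TRUE)) {
    stop("invalid-parameter: axial_heights must be strictly increasing and ",
         "named lvot, annulus, sinus, stj, ascending", call. = FALSE)
  }
  structure(list(diameters = diams,
                 axial_heights = axial_heights,
                 ms_depths = ms,
                 ms_angles = ms_angles,
                 calcium_volumes = calcium_volumes,
                 cusp_angles = cusp_angles),
            class = "root_params")
}

calcium_regions <- c("leaflet", "upper_leaflet", "landing_zone", "lvot")
calcium_cusps <- c("NCC", "RCC", "LCC")

#' All-zero calcium volume matrix
#'
#' @return A 4 x 3 matrix (region x cusp) of zeros, in mm^3.
#' @export
zero_calcium <- function() {
  matrix(0, nrow = 4, ncol = 3,
         dimnames = list(calcium_regions, calcium_cusps))
}

validate_calcium_volumes <- function(v) {
  if (is.null(v)) v <- zero_calcium()
  if (!is.matrix(v) || !identical(rownames(v), calcium_regions) ||
      !identical(colnames(v), calcium_cusps)) {
    stop("invalid-parameter: calcium_volumes must be a matrix with rows ",
         paste(calcium_regions, collapse = "/"), " and columns ",
         paste(calcium_cusps, collapse = "/"), call. = FALSE)
  }
  if (any(v < 0)) {
    stop("invalid-parameter: calcium volumes must be >= 0", call. = FALSE)
  }
  v
}

#' @export
print.root_params <- function(x, ...) {
  cat("Aortic-root parameters\n")
  cat(sprintf("  diameters (mm): LVOT %.1f | annulus %.1f | sinus %.1f | STJ %.1f | ascending %.1f\n",
              x$diameters["lvot"], x$diameters["annulus"], x$diameters["sinus"],
              x$diameters["stj"], x$diameters["ascending"]))
  cat(sprintf("  MS depths (mm): NCC %.1f / mid %.1f / RCC %.1f\n",
              x$ms_depths["ncc"], x$ms_depths["mid"], x$ms_depths["rcc"]))
  cat(sprintf("  total calcium: %.1f mm^3\n", sum(x$calcium_volumes)))
  invisible(x)
}

# Default mechanical constants for the root wall model. The wall is a linear
# elastic thin shell (E = 2 MPa, nu = 0.45) of configurable thickness;
# leaflets contribute an extra radial resistance band (E = 0.6 MPa) between
# annulus and sinus; calcium is stiffer (E = 4 MPa) and elastic-perfectly-
# plastic with a 0.6 MPa yield cap. Spring foundations at every wall node
# stand in for the surrounding cardiac structures.
#' Mechanical material and foundation defaults for the root wall
#'
#' @param E_wall,nu_wall Elastic modulus (MPa) and Poisson ratio of the wall.
#' @param E_leaflet,nu_leaflet Leaflet modulus (MPa) and Poisson ratio.
#' @param E_calcium,nu_calcium,yield_calcium Calcium modulus (MPa), Poisson
#'   ratio and yield stress cap (MPa).
#' @param wall_thickness Shell thickness (mm) used for the hoop-stiffness
#'   approximation.
#' @param leaflet_thickness Effective leaflet thickness (mm) in the
#'   annulus-to-sinus resistance band.
#' @param foundation_stiffness Foundation-spring stiffness (N/mm) per node
#'   at the reference mesh resolution (72 x 0.5 mm); internally scaled by
#'   node tributary area so the wall's stiffness density does not depend on
#'   the mesh.
#' @return A named list of material parameters.
#' @export
material_params <- function(E_wall = 2.0, nu_wall = 0.45,
                            E_leaflet = 0.6, nu_leaflet = 0.3,
                            E_calcium = 4.0, nu_calcium = 0.3,
                            yield_calcium = 0.6,
                            wall_thickness = 2.0,
                            leaflet_thickness = 1.5,
                            foundation_stiffness = 0.02) {
  stopifnot(E_wall > 0, E_leaflet > 0, E_calcium > 0,
            nu_wall >= 0, nu_wall < 0.5,
            nu_leaflet >= 0, nu_leaflet < 0.5,
            nu_calcium >= 0, nu_calcium < 0.5,
            yield_calcium > 0, wall_thickness > 0,
            foundation_stiffness > 0)
  list(E_wall = E_wall, nu_wall = nu_wall,
       E_leaflet = E_leaflet, nu_leaflet = nu_leaflet,
       E_calcium = E_calcium, nu_calcium = nu_calcium,
       yield_calcium = yield_calcium,
       wall_thickness = wall_thickness,
       leaflet_thickness = leaflet_thickness,
       foundation_stiffness = foundation_stiffness)
}

#' Generate a discretized aortic-root wall model
#'
#' Builds a surface-of-revolution wall mesh from [root_params()]: a node grid
#' of `n_theta` circumferential angles by axial rows spaced `dz` mm over
#' `z_range`, with quad elements, per-node tributary areas and radial wall
#' stiffness (thin-shell hoop term plus foundation spring, plus a leaflet
#' resistance band between annulus and sinus), a calcium map (initially
#' empty), and a landmark registry (cusp nadirs, commissures, membranous-
#' septum landmarks).
#'
#' The radius profile interpolates the five requested diameters with a
#' monotone cubic through their axial positions and extends each end level
#' as a constant.
#'
#' @param params A [root_params()] object.
#' @param n_theta Circumferential node count (>= 16).
#' @param dz Axial node spacing, mm.
#' @param z_range Axial extent `c(zmin, zmax)` in mm; must cover at least
#'   \[-20, 30\].
#' @param materials Mechanical constants, see [material_params()].
#' @param seed Integer seed for the per-node perturbation hook (the default
#'   generator is deterministic and unperturbed; the seed is recorded).
#'
#' @return An object of class `aortic_root` with components `theta` (deg),
#'   `z` (mm), `radius` (n_z x n_theta matrix, mm), `elements`, element
#'   areas, per-node stiffness (N/mm), calcium map, and `landmarks`.
#' @export
generate_root <- function(params, n_theta = 72, dz = 0.5,
                          z_range = c(-20, 30),
                          materials = material_params(),
                          seed = 1L) {
  stopifnot(inherits(params, "root_params"))
  if (n_theta < 16 || dz <= 0) {
    stop("invalid-parameter: need >= 16 circumferential nodes and dz > 0",
         call. = FALSE)
  }
  if (z_range[1] > -20 || z_range[2] < 30) {
    stop("invalid-parameter: axial extent must cover [-20, 30] mm",
         call. = FALSE)
  }
  theta <- seq(0, 360, length.out = n_theta + 1)[seq_len(n_theta)]
  z <- seq(z_range[1], z_range[2], by = dz)
  n_z <- length(z)

  # monotone-cubic radius profile through the five levels, constant beyond
  lv <- params$axial_heights
  rv <- params$diameters / 2
  prof <- stats::splinefun(lv, rv, method = "monoH.FC")
  z_cl <- pmin(pmax(z, min(lv)), max(lv))
  r_axial <- prof(z_cl)
  radius <- matrix(rep(r_axial, times = n_theta), nrow = n_z, ncol = n_theta)

  elements <- build_quads(n_z, n_theta)
  geom <- mesh_geometry(radius, z, theta, elements)

  # radial stiffness per node: thin-shell hoop term E t A / r^2 over the
  # tributary area, a leaflet band between annulus and sinus, and the
  # foundation spring standing in for surrounding structures
  r_node <- radius
  a_node <- geom$node_area
  k_shell <- materials$E_wall * materials$wall_thickness * a_node / r_node^2
  k_leaf <- matrix(0, n_z, n_theta)
  leaf_rows <- z >= lv["annulus"] & z <= lv["sinus"]
  k_leaf[leaf_rows, ] <- materials$E_leaflet * materials$leaflet_thickness *
    a_node[leaf_rows, ] / r_node[leaf_rows, ]^2
  # foundation stiffness is stated per node at the reference resolution
  # (72 x 0.5 mm on a 12.5 mm radius); scaling by tributary area keeps the
  # stiffness density, and hence the contact solution, mesh-independent
  a_ref <- 12.5 * (2 * pi / 72) * 0.5
  k_found <- materials$foundation_stiffness * a_node / a_ref

  landmarks <- data.frame(
    name = c("ncc_nadir", "rcc_nadir", "lcc_nadir",
             "comm_ncc_rcc", "comm_rcc_lcc", "comm_lcc_ncc",
             "ms_ncc", "ms_mid", "ms_rcc"),
    theta = c(params$cusp_angles[["NCC"]], params$cusp_angles[["RCC"]],
              params$cusp_angles[["LCC"]],
              mean(c(params$cusp_angles[["NCC"]], params$cusp_angles[["RCC"]])),
              mean(c(params$cusp_angles[["RCC"]], params$cusp_angles[["LCC"]])),
              mean(c(params$cusp_angles[["LCC"]], params$cusp_angles[["NCC"]] + 360)) %% 360,
              params$ms_angles[["ncc"]], params$ms_angles[["mid"]],
              params$ms_angles[["rcc"]]),
    z = c(0, 0, 0, 0, 0, 0,
          -params$ms_depths[["ncc"]], -params$ms_depths[["mid"]],
          -params$ms_depths[["rcc"]]),
    stringsAsFactors = FALSE
  )

  structure(list(
    params = params,
    materials = materials,
    theta = theta, z = z, dz = dz, n_theta = n_theta, n_z = n_z,
    radius = radius,
    elements = elements,
    element_area = geom$element_area,
    node_area = a_node,
    node_n_elements = geom$node_n_elements,
    k_shell = k_shell, k_leaflet = k_leaf, k_foundation = k_found,
    calcium_multiplier = matrix(1, n_z, n_theta),
    calcium_volume = matrix(0, n_z, n_theta),
    calcium_yield = matrix(Inf, n_z, n_theta),
    landmarks = landmarks,
    seed = as.integer(seed)
  ), class = "aortic_root")
}

# quad elements as (row, col) of their lower-left node; columns wrap
build_quads <- function(n_z, n_theta) {
  g <- expand.grid(row = seq_len(n_z - 1), col = seq_len(n_theta))
  g$col2 <- g$col %% n_theta + 1L
  g
}

# frustum-panel areas and node tributary data for a revolution mesh
mesh_geometry <- function(radius, z, theta, elements) {
  n_z <- nrow(radius); n_theta <- ncol(radius)
  dtheta <- 2 * pi / n_theta
  r1 <- radius[cbind(elements$row, elements$col)]
  r2 <- radius[cbind(elements$row + 1L, elements$col)]
  dzv <- z[elements$row + 1L] - z[elements$row]
  slant <- sqrt((r2 - r1)^2 + dzv^2)
  element_area <- 0.5 * (r1 + r2) * dtheta * slant

  # incidence counts: interior rows touch 4 quads, end rows 2
  n_inc <- matrix(4L, n_z, n_theta)
  n_inc[1, ] <- 2L
  n_inc[n_z, ] <- 2L

  # tributary node area: quarter of each incident element
  add <- element_area / 4
  node_area <- matrix(0, n_z, n_theta)
  for (k in seq_len(4)) {
    idx <- switch(k,
      cbind(elements$row, elements$col),
      cbind(elements$row, elements$col2),
      cbind(elements$row + 1L, elements$col),
      cbind(elements$row + 1L, elements$col2))
    lin <- (idx[, 2] - 1L) * n_z + idx[, 1]
    acc <- tabulate_weighted(lin, add, n_z * n_theta)
    node_area <- node_area + matrix(acc, n_z, n_theta)
  }
  list(element_area = element_area, node_area = node_area,
       node_n_elements = n_inc)
}

tabulate_weighted <- function(bins, w, nbins) {
  out <- numeric(nbins)
  s <- rowsum(w, group = bins)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Total per-node radial wall stiffness
#'
#' Sum of the (calcium-scaled) shell hoop term, leaflet band and foundation
#' spring, in N per mm of radial displacement.
#'
#' @param model An `aortic_root`.
#' @return Matrix (n_z x n_theta) of stiffness values, N/mm.
#' @export
node_stiffness <- function(model) {
  model$calcium_multiplier * model$k_shell + model$k_leaflet + model$k_foundation
}

#' Measure perimeter-derived diameters of a generated mesh
#'
#' Reconstructs the cross-section diameter at each of the five named levels
#' from the discrete circumference (sum of arc segments divided by pi), the
#' same convention as perimeter-derived sizing on CT.
#'
#' @param model An `aortic_root`.
#' @return Named numeric vector of diameters (mm) at the five levels.
#' @export
measure_diameters <- function(model) {
  lv <- model$params$axial_heights
  dtheta <- 2 * pi / model$n_theta
  vapply(names(lv), function(nm) {
    row <- which.min(abs(model$z - lv[[nm]]))
    sum(model$radius[row, ] * dtheta) / pi
  }, numeric(1))
}

#' Total lateral surface area of the wall mesh
#'
#' @param model An `aortic_root`.
#' @return Total element area, mm^2.
#' @export
total_area <- function(model) sum(model$element_area)

# --- calcium placement -------------------------------------------------------

# axial band (mm, annulus plane = 0) of each calcium region
calcium_region_bands <- function(params) {
  hs <- params$axial_heights
  list(leaflet = c(hs[["annulus"]], hs[["sinus"]]),
       upper_leaflet = c(0.5 * (hs[["annulus"]] + hs[["sinus"]]), hs[["sinus"]]),
       landing_zone = c(-4, 4),
       lvot = c(hs[["lvot"]], -4))
}

# angular half-sector of each cusp (60 deg either side of the nadir)
cusp_sector <- function(params, cusp) {
  centre <- params$cusp_angles[[cusp]]
  c(centre - 60, centre + 60)
}

angle_in_sector <- function(theta, sector) {
  d <- (theta - sector[1]) %% 360
  d < (sector[2] - sector[1]) %% 360 | (sector[2] - sector[1]) %% 360 == 0
}

#' Deposit calcium onto a root model
#'
#' Realizes the per-region, per-cusp calcium volumes of the model's
#' [root_params()] as contiguous node patches: for each (region, cusp) cell
#' with positive volume, nodes inside the cusp's angular sector and the
#' region's axial band are claimed by breadth-first growth from a seeded
#' start node until the patch can carry the requested volume, which is then
#' spread evenly over the patch. Calcium nodes get a stiffness multiplier
#' `E_calcium / E_wall` and an elastic-plastic yield cap.
#'
#' @param model An `aortic_root`.
#' @param params Optional [root_params()] override; defaults to the model's.
#' @param seed Integer seed controlling patch start positions.
#' @return The model with calcium volume, multiplier and yield maps filled.
#' @export
place_calcium <- function(model, params = model$params, seed = 1L) {
  stopifnot(inherits(model, "aortic_root"))
  vols <- validate_calcium_volumes(params$calcium_volumes)
  if (all(vols == 0)) return(model)

  set.seed(as.integer(seed))
  bands <- calcium_region_bands(params)
  nominal_thickness <- 1.5  # mm: node patch volume = tributary area x thickness

  for (region in rownames(vols)) {
    for (cusp in colnames(vols)) {
      v <- vols[region, cusp]
      if (v <= 0) next
      band <- bands[[region]]
      sector <- cusp_sector(params, cusp)
      rows <- which(model$z >= band[1] & model$z <= band[2])
      cols <- which(angle_in_sector(model$theta, sector))
      cand <- as.matrix(expand.grid(row = rows, col = cols))
      cap_per_node <- model$node_area[cand] * nominal_thickness
      if (sum(cap_per_node) < v) {
        stop(sprintf("capacity: requested %.1f mm^3 of %s/%s calcium exceeds region capacity %.1f mm^3",
                     v, region, cusp, sum(cap_per_node)), call. = FALSE)
      }
      n_needed <- which(cumsum(sort(cap_per_node, decreasing = TRUE)) >= v)[1]
      # contiguous patch: breadth-first growth in (row, col) grid distance
      # from a random start among the candidates
      start <- cand[sample.int(nrow(cand), 1L), ]
      dr <- abs(cand[, "row"] - start[["row"]])
      dcol_raw <- abs(cand[, "col"] - start[["col"]])
      dc <- pmin(dcol_raw, model$n_theta - dcol_raw)
      ord <- order(dr + dc, dr, dc)
      take <- cand[ord[seq_len(n_needed)], , drop = FALSE]
      per_node <- v / n_needed
      model$calcium_volume[take] <- model$calcium_volume[take] + per_node
      model$calcium_multiplier[take] <-
        model$materials$E_calcium / model$materials$E_wall
      model$calcium_yield[take] <- model$materials$yield_calcium
    }
  }
  model
}

#' Sample anatomy parameter sets from cohort distributions
#'
#' Draws `n` independent [root_params()] sets from Gaussian marginals with
#' the configured means and standard deviations; membranous-septum depths
#' and calcium volumes are truncated at zero, diameters at a small positive
#' floor. Defaults reproduce a published self-expanding TAVR cohort's
#' baseline CT anatomy.
#'
#' @param n Number of parameter sets (>= 1).
#' @param table1_config Named list of `mean`/`sd` pairs; see
#'   [default_anatomy_distribution()].
#' @param seed Integer seed.
#' @return A list of `root_params` objects.
#' @export
sample_root_params <- function(n, table1_config = default_anatomy_distribution(),
                               seed = 1L) {
  stopifnot(n >= 1)
  cfg <- table1_config
  if (any(vapply(cfg, function(x) x$sd < 0, logical(1)))) {
    stop("invalid-parameter: sds must be >= 0", call. = FALSE)
  }
  set.seed(as.integer(seed))
  draw <- function(nm, lower) pmax(stats::rnorm(n, cfg[[nm]]$mean, cfg[[nm]]$sd), lower)
  d_lv <- draw("lvot_diameter", 5); d_an <- draw("annulus_diameter", 5)
  d_si <- draw("sinus_diameter", 5); d_st <- draw("stj_diameter", 5)
  d_as <- draw("ascending_diameter", 5)
  ms_n <- draw("ms_depth_ncc", 0); ms_m <- draw("ms_depth_mid", 0)
  ms_r <- draw("ms_depth_rcc", 0)
  ca <- lapply(calcium_regions, function(region) {
    vapply(calcium_cusps, function(cusp) {
      nm <- paste0("calcium_", region, "_", tolower(cusp))
      if (is.null(cfg[[nm]])) rep(0, n) else draw(nm, 0)
    }, numeric(n))
  })
  if (n == 1) ca <- lapply(ca, function(x) matrix(x, nrow = 1,
                                                  dimnames = list(NULL, calcium_cusps)))
  names(ca) <- calcium_regions
  lapply(seq_len(n), function(i) {
    vols <- zero_calcium()
    for (region in calcium_regions) vols[region, ] <- ca[[region]][i, ]
    root_params(lvot_diameter = d_lv[i], annulus_diameter = d_an[i],
                sinus_diameter = d_si[i], stj_diameter = d_st[i],
                ascending_diameter = d_as[i],
                ms_depth_ncc = ms_n[i], ms_depth_mid = ms_m[i],
                ms_depth_rcc = ms_r[i],
                calcium_volumes = vols)
  })
}

#' Default anatomy sampling distributions
#'
#' Means and SDs of the root diameters, membranous-septum depths and leaflet
#' calcium volumes matching the baseline CT characteristics of an 80-patient
#' self-expanding TAVR cohort.
#'
#' @return Named list of `list(mean=, sd=)` entries.
#' @export
default_anatomy_distribution <- function() {
  list(
    lvot_diameter = list(mean = 25.4, sd = 3.1),
    annulus_diameter = list(mean = 25.1, sd = 2.5),
    sinus_diameter = list(mean = 34.3, sd = 4.0),
    stj_diameter = list(mean = 28.9, sd = 3.5),
    ascending_diameter = list(mean = 32.1, sd = 3.2),
    ms_depth_ncc = list(mean = 5.1, sd = 3.0),
    ms_depth_mid = list(mean = 3.5, sd = 2.3),
    ms_depth_rcc = list(mean = 1.7, sd = 2.2),
    calcium_leaflet_ncc = list(mean = 172.1, sd = 198.4),
    calcium_leaflet_rcc = list(mean = 80.2, sd = 95.4),
    calcium_leaflet_lcc = list(mean = 91.5, sd = 99.7),
    calcium_upper_leaflet_ncc = list(mean = 164.1, sd = 188.8),
    calcium_upper_leaflet_rcc = list(mean = 78.2, sd = 93.3),
    calcium_upper_leaflet_lcc = list(mean = 82.8, sd = 91.0),
    calcium_landing_zone_ncc = list(mean = 10.0, sd = 25.3),
    calcium_landing_zone_rcc = list(mean = 1.7, sd = 4.9),
    calcium_landing_zone_lcc = list(mean = 11.8, sd = 23.3),
    calcium_lvot_ncc = list(mean = 4.2, sd = 14.7),
    calcium_lvot_rcc = list(mean = 0.1, sd = 1.1),
    calcium_lvot_lcc = list(mean = 12.5, sd = 29.6)
  )
}

#' @export
print.aortic_root <- function(x, ...) {
  cat(sprintf("Aortic-root mesh: %d x %d nodes (theta x z), dz = %.2f mm\n",
              x$n_theta, x$n_z, x$dz))
  cat(sprintf("  surface area %.0f mm^2, calcium %.1f mm^3 on %d nodes\n",
              total_area(x), sum(x$calcium_volume), sum(x$calcium_volume > 0)))
  invisible(x)
}
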