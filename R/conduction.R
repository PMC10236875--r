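# Conduction-disturbance scoring over the membranous-septum region of
# interest. The membranous septum is located at three landmarks (NCC,
# mid-course, RCC); the region of interest spans from the NCC landmark
# angle through the mid-course to the RCC landmark angle extended 25 deg
# laterally (away from the NCC, along the course of the bundle), and runs
# 15 mm caudal from the aortic annulus plane. The region is the anatomical
# surrogate for the atrioventricular bundle and proximal left bundle branch.

#' Build the membranous-septum region of interest
#'
#' @param model An `aortic_root` carrying membranous-septum landmarks.
#' @param lateral_extension_deg Lateral angular extension beyond the RCC
#'   landmark, degrees (default 25).
#' @param caudal_extent_mm Caudal extent below the annulus plane, mm
#'   (default 15).
#' @return An object of class `conduction_roi` with the member element
#'   indices, total area (mm^2), and the angular/axial spans.
#' @export
build_roi <- function(model, lateral_extension_deg = 25, caudal_extent_mm = 15) {
  stopifnot(inherits(model, "aortic_root"))
  lm <- model$landmarks
  need <- c("ms_ncc", "ms_mid", "ms_rcc")
  if (!all(need %in% lm$name)) {
    stop("configuration: model lacks membranous-septum landmarks", call. = FALSE)
  }
  th_ncc <- lm$theta[lm$name == "ms_ncc"]
  th_rcc <- lm$theta[lm$name == "ms_rcc"]
  th_start <- th_ncc
  th_end <- th_rcc + lateral_extension_deg
  z_span <- c(-caudal_extent_mm, 0)

  el <- model$elements
  # element centroids
  th_c <- centroid_theta(model)
  z_c <- 0.5 * (model$z[el$row] + model$z[el$row + 1L])
  span <- (th_end - th_start) %% 360
  in_theta <- ((th_c - th_start) %% 360) <= span
  in_z <- z_c >= z_span[1] & z_c <= z_span[2]
  idx <- which(in_theta & in_z)
  if (length(idx) == 0) {
    stop("empty-region: region of interest contains no elements", call. = FALSE)
  }
  structure(list(elements = idx,
                 area = sum(model$element_area[idx]),
                 theta_span = c(th_start, th_end),
                 z_span = z_span,
                 ms_landmarks = lm[lm$name %in% need, ]),
            class = "conduction_roi")
}

centroid_theta <- function(model) {
  el <- model$elements
  dtheta <- 360 / model$n_theta
  (model$theta[el$col] + dtheta / 2) %% 360
}

#' Contact pressure index over a region of interest
#'
#' Area fraction (percent) of the region of interest subject to contact
#' pressure by the frame: 100 x (area of region elements whose pressure
#' exceeds `contact_threshold`) / (total region area). Area-weighted, not
#' element-count-weighted.
#'
#' @param field A `pressure_field`.
#' @param roi A `conduction_roi` sharing the field's mesh.
#' @param contact_threshold Pressure above which an element counts as in
#'   contact, MPa. Default is a numerical zero.
#' @return CPI in percent, in \[0, 100\].
#' @export
compute_cpi <- function(field, roi, contact_threshold = 1e-6) {
  stopifnot(inherits(field, "pressure_field"), inherits(roi, "conduction_roi"))
  if (length(roi$elements) == 0 || roi$area <= 0) {
    stop("empty-region: region of interest is empty", call. = FALSE)
  }
  p <- field$pressure[roi$elements]
  a <- field$area[roi$elements]
  100 * sum(a[p > contact_threshold]) / roi$area
}

#' Maximum contact pressure over a region of interest
#'
#' @inheritParams compute_cpi
#' @return CPMax in MPa (0 when the region carries no contact).
#' @export
compute_cpmax <- function(field, roi) {
  stopifnot(inherits(field, "pressure_field"), inherits(roi, "conduction_roi"))
  if (length(roi$elements) == 0) {
    stop("empty-region: region of interest is empty", call. = FALSE)
  }
  max(field$pressure[roi$elements], 0)
}

#' Measure implantation depth of a deployed frame
#'
#' Depth at a cusp is the axial distance from the annulus plane (z = 0) down
#' to the frame's inflow edge at that cusp's angle, measured at the
#' non-coronary and left-coronary cusps; the mean depth is their arithmetic
#' mean. A frame whose inflow edge sits entirely above the annulus returns
#' zero depths with `above_annulus = TRUE`.
#'
#' @param frame Deployed frame state (`$frame` of a [deploy()] result).
#' @param model The `aortic_root` the frame was deployed into.
#' @return List with `depth_ncc`, `depth_lcc`, `depth_mean` (mm) and the
#'   `above_annulus` warning flag.
#' @export
measure_depth <- function(frame, model) {
  stopifnot(inherits(model, "aortic_root"))
  if (is.null(frame$inflow_z)) stop("measure_depth: no deployed frame", call. = FALSE)
  # coaxial (possibly laterally offset) deployment: the inflow edge is a
  # horizontal ring, so the depth is the same at both measured cusps
  if (frame$inflow_z > 0) {
    warning("frame inflow edge lies above the annulus plane; depth reported as 0")
    return(list(depth_ncc = 0, depth_lcc = 0, depth_mean = 0,
                above_annulus = TRUE))
  }
  d <- -frame$inflow_z
  list(depth_ncc = d, depth_lcc = d, depth_mean = d, above_annulus = FALSE)
}

#' Conduction metrics of a deployment
#'
#' Convenience wrapper computing CPI, CPMax, implantation depths and the
#' clinical risk flags (CPI >= 20%, CPMax >= 0.40 MPa, depth >= 5 mm) for
#' one deployed patient model.
#'
#' @param deployment A [deploy()] result.
#' @param model The `aortic_root` deployed into.
#' @param roi Optional precomputed `conduction_roi`.
#' @param contact_threshold Passed to [compute_cpi()].
#' @return An object of class `conduction_metrics`.
#' @export
conduction_metrics <- function(deployment, model, roi = build_roi(model),
                               contact_threshold = 1e-6) {
  cpi <- compute_cpi(deployment$field, roi, contact_threshold)
  cpmax <- compute_cpmax(deployment$field, roi)
  dep <- measure_depth(deployment$frame, model)
  structure(list(cpi = cpi, cpmax = cpmax,
                 depth_ncc = dep$depth_ncc, depth_lcc = dep$depth_lcc,
                 depth_mean = dep$depth_mean,
                 flags = list(cpi_ge_20 = cpi >= 20,
                              cpmax_ge_040 = cpmax >= 0.40,
                              depth_ge_5 = dep$depth_mean >= 5)),
            class = "conduction_metrics")
}

#' @export
print.conduction_metrics <- function(x, ...) {
  cat(sprintf("CPI %.1f%% | CPMax %.3f MPa | depth %.1f mm (NCC %.1f / LCC %.1f)\n",
              x$cpi, x$cpmax, x$depth_mean, x$depth_ncc, x$depth_lcc))
  cat(sprintf("  risk flags: CPI>=20%%: %s, CPMax>=0.40 MPa: %s, depth>=5 mm: %s\n",
              x$flags$cpi_ge_20, x$flags$cpmax_ge_040, x$flags$depth_ge_5))
  invisible(x)
}

#' Serialize conduction metrics to a one-row data frame
#'
#' @param x A `conduction_metrics`.
#' @param patient_id,device Optional identifying columns.
#' @return A one-row data.frame suitable for CSV export.
#' @export
metrics_row <- function(x, patient_id = NA, device = NA) {
  data.frame(patient_id = patient_id, device = device,
             depth_ncc = x$depth_ncc, depth_lcc = x$depth_lcc,
             depth_mean = x$depth_mean, cpi = x$cpi, cpmax = x$cpmax,
             cpi_ge_20 = x$flags$cpi_ge_20,
             cpmax_ge_040 = x$flags$cpmax_ge_040,
             depth_ge_5 = x$flags$depth_ge_5,
             stringsAsFactors = FALSE)
}
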