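# Self-expanding THV frame models.
#
# Each device is a frame-height diameter profile plus a chronic-outward-force
# characteristic: outward radial force per mm of frame height as a function
# of local diameter, flat (plateau) at small diameters and decaying linearly
# to zero at the local free diameter. Frame dimensions and force magnitudes
# are engineering configuration values recorded in the catalog, not measured
# quantities; analyses in this package never depend on their absolute scale.

#' Built-in device catalog
#'
#' Geometry and force-curve parameters of the four supported self-expanding
#' frames: Evolut PRO 23/26/29 mm (with outer pericardial wrap) and Evolut R
#' 34 mm (without). The wrap is metadata only; it carries no mechanical
#' effect in this model.
#'
#' @return Named list of device parameter lists.
#' @export
device_catalog <- function() {
  make <- function(name, size, frame_height, wrap, plateau) {
    # diameter profile knots (height mm from inflow edge, diameter mm):
    # constant inflow segment, constricted waist, flared outflow
    knots_h <- c(0, 0.22, 0.50, 1.00) * frame_height
    knots_d <- c(size, size, 0.82 * size, size + 8)
    list(model_name = name, size = size, frame_height = frame_height,
         has_pericardial_wrap = wrap,
         profile_h = knots_h, profile_d = knots_d,
         crimped_diameter = 6.0,
         force_plateau = plateau,    # N per mm frame height at full crimp
         knee_fraction = 0.65)       # plateau ends at this fraction of free diameter
  }
  list(
    "EvolutPRO-23" = make("EvolutPRO-23", 23, 45, TRUE, 1.6),
    "EvolutPRO-26" = make("EvolutPRO-26", 26, 45, TRUE, 1.8),
    "EvolutPRO-29" = make("EvolutPRO-29", 29, 45, TRUE, 2.0),
    "EvolutR-34"   = make("EvolutR-34", 34, 50, FALSE, 2.4)
  )
}

#' Retrieve a supported THV device
#'
#' @param model_name One of `"EvolutPRO-23"`, `"EvolutPRO-26"`,
#'   `"EvolutPRO-29"`, `"EvolutR-34"`, or a custom name previously registered
#'   in `catalog`.
#' @param catalog Device catalog, defaults to [device_catalog()].
#' @return An object of class `thv_device`.
#' @export
get_device <- function(model_name, catalog = device_catalog()) {
  if (!model_name %in% names(catalog)) {
    stop(sprintf("unsupported-device: '%s' (supported: %s)", model_name,
                 paste(names(catalog), collapse = ", ")), call. = FALSE)
  }
  structure(catalog[[model_name]], class = "thv_device")
}

#' Unloaded frame diameter at a height along the frame
#'
#' @param device A `thv_device`.
#' @param ring_height Height (mm) from the inflow edge, in
#'   \[0, frame_height\].
#' @return Free (unloaded) diameter, mm.
#' @export
free_diameter <- function(device, ring_height) {
  if (any(ring_height < 0 | ring_height > device$frame_height)) {
    stop("out-of-range: ring_height outside [0, frame_height]", call. = FALSE)
  }
  stats::approx(device$profile_h, device$profile_d, xout = ring_height,
                rule = 2)$y
}

#' Outward radial force of the frame at a given height and diameter
#'
#' Two-segment chronic-outward-force characteristic per mm of frame height:
#' a plateau at `force_plateau` for diameters at or below
#' `knee_fraction x` local free diameter, then linear decay to zero at the
#' local free diameter. Zero at and above the free diameter; continuous and
#' non-increasing in diameter.
#'
#' @param device A `thv_device`.
#' @param ring_height Height (mm) from the inflow edge.
#' @param diameter Current ring diameter, mm (> 0).
#' @return Outward force in N per mm of frame height.
#' @export
radial_force <- function(device, ring_height, diameter) {
  stopifnot(all(diameter > 0))
  d_free <- free_diameter(device, ring_height)
  d_knee <- device$knee_fraction * d_free
  f <- ifelse(diameter >= d_free, 0,
              ifelse(diameter <= d_knee, device$force_plateau,
                     device$force_plateau * (d_free - diameter) / (d_free - d_knee)))
  unname(f)
}

#' Write / read a device catalog as YAML
#'
#' Users can register custom devices by editing the YAML and reloading it;
#' the schema is the field set of [device_catalog()] entries.
#'
#' @param catalog Device catalog list.
#' @param path File path.
#' @return `read_device_catalog` returns a catalog list.
#' @export
write_device_catalog <- function(catalog, path) {
  yaml::write_yaml(catalog, path)
  invisible(path)
}

#' @rdname write_device_catalog
#' @export
read_device_catalog <- function(path) {
  cat_in <- yaml::read_yaml(path)
  lapply(cat_in, function(d) {
    d$profile_h <- as.numeric(d$profile_h)
    d$profile_d <- as.numeric(d$profile_d)
    d
  })
}

#' @export
print.thv_device <- function(x, ...) {
  cat(sprintf("%s: %d mm self-expanding frame, height %.0f mm, wrap %s\n",
              x$model_name, x$size, x$frame_height,
              if (x$has_pericardial_wrap) "yes" else "no"))
  invisible(x)
}
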