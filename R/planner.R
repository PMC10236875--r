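# Patient-specific positioning: scan candidate implantation depths and
# report the depth minimizing the contact metrics. Smaller depth values mean
# a higher (more aortic) implant.

#' Scan candidate implantation depths
#'
#' Runs one deployment solve per candidate depth and tabulates CPI and CPMax
#' at each. The recommended depth minimizes CPI, with CPMax as tiebreaker
#' and the lowest depth winning remaining ties. The residual-risk flag is
#' set when CPMax at the recommended depth still reaches 0.40 MPa, i.e. the
#' patient is predicted to remain at risk of major conduction disturbance
#' even at the best achievable position.
#'
#' @param model An `aortic_root`.
#' @param device A `thv_device`.
#' @param base_config A [deployment_config()]; its depth target is replaced
#'   by each grid value in turn.
#' @param depth_grid Candidate depths (mm, >= 0), default 0-10 mm by 1 mm.
#'   The high-implant preset of `high_implant_grid()` targets 0-3 mm.
#' @return An object of class `depth_scan` with the scan table (`$grid`),
#'   `recommended_depth`, the nominal-depth row, and
#'   `predicted_residual_risk`.
#' @export
depth_scan <- function(model, device, base_config = deployment_config(),
                       depth_grid = seq(0, 10, by = 1)) {
  if (length(depth_grid) == 0 || any(depth_grid < 0)) {
    stop("invalid-parameter: depth grid must be non-empty with depths >= 0",
         call. = FALSE)
  }
  depth_grid <- sort(depth_grid)
  roi <- build_roi(model)
  rows <- lapply(depth_grid, function(d) {
    cfg <- base_config
    cfg$implantation_depth_target <- d
    res <- tryCatch(deploy(model, device, cfg), thvcpi_nonconvergence = identity)
    if (inherits(res, "thvcpi_nonconvergence")) {
      return(data.frame(depth = d, cpi = NA_real_, cpmax = NA_real_,
                        converged = FALSE))
    }
    data.frame(depth = d,
               cpi = compute_cpi(res$field, roi),
               cpmax = compute_cpmax(res$field, roi),
               converged = TRUE)
  })
  grid <- do.call(rbind, rows)
  ok <- grid[grid$converged, , drop = FALSE]
  if (nrow(ok) == 0) stop("depth_scan: no depth converged", call. = FALSE)
  ord <- order(ok$cpi, ok$cpmax, ok$depth)
  best <- ok[ord[1], ]
  nominal <- base_config$implantation_depth_target
  structure(list(grid = grid,
                 recommended_depth = best$depth,
                 recommended_cpi = best$cpi,
                 recommended_cpmax = best$cpmax,
                 nominal_depth = nominal,
                 predicted_residual_risk = best$cpmax >= 0.40),
            class = "depth_scan")
}

#' High-implant depth preset (0-3 mm)
#'
#' @return Numeric vector of candidate depths for a high-implant strategy.
#' @export
high_implant_grid <- function() c(0, 1, 2, 3)

#' @export
print.depth_scan <- function(x, ...) {
  cat("Implantation-depth scan\n")
  print(x$grid, row.names = FALSE)
  cat(sprintf("Recommended depth: %.1f mm (CPI %.1f%%, CPMax %.3f MPa)\n",
              x$recommended_depth, x$recommended_cpi, x$recommended_cpmax))
  if (isTRUE(x$predicted_residual_risk)) {
    cat("WARNING: CPMax >= 0.40 MPa even at the recommended depth; residual conduction-disturbance risk predicted.\n")
  }
  cat("Note: very high implants carry a device-embolization risk that is outside the scope of this mechanical model.\n")
  invisible(x)
}
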