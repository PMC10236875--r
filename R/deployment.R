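# Quasi-static frame-wall contact equilibrium.
#
# Mechanical idealization: the frame is a stack of independent circumferential
# rings, one per mesh row it overlaps, coupled to the wall by radial penalty
# contact. Each wall node responds with a local radial stiffness (shell hoop
# term + leaflet band + foundation spring); calcium scales the shell term and
# caps the nodal contact pressure with an elastic-perfectly-plastic law.
# Each ring's equilibrium diameter balances the frame's chronic outward force
# against the summed nodal reactions, solved by a damped Newton fixed-point
# iteration on the ring radius. Sheath retraction is staged from the outflow
# (distal) end toward the inflow over a configurable number of steps, rings
# reaching equilibrium as they are released.

#' Deployment solver configuration
#'
#' @param implantation_depth_target Target implantation depth (mm below the
#'   annulus plane at the non-coronary cusp).
#' @param lateral_offset_fraction Prescribed lateral offset of the frame axis
#'   toward the aorta's outer curvature, as a fraction of the annulus radius
#'   (0 = coaxial). Stands in for the outer-curvature displacement force.
#' @param lateral_offset_direction Angular direction (degrees) of the offset.
#' @param n_retraction_steps Number of staged sheath-retraction steps.
#' @param contact_penalty Penalty stiffness per node, N per mm penetration.
#' @param convergence_tol Ring-radius update tolerance, mm.
#' @param max_iterations Iteration cap per ring.
#' @param relaxation Under-relaxation factor of the Newton update.
#' @return An object of class `deployment_config`.
#' @export
deployment_config <- function(implantation_depth_target = 6.2,
                              lateral_offset_fraction = 0,
                              lateral_offset_direction = 180,
                              n_retraction_steps = 20,
                              contact_penalty = 10,
                              convergence_tol = 1e-4,
                              max_iterations = 10000,
                              relaxation = 0.5) {
  stopifnot(implantation_depth_target >= 0, n_retraction_steps >= 1,
            convergence_tol > 0, contact_penalty > 0, max_iterations >= 1,
            relaxation > 0, relaxation <= 1)
  structure(list(implantation_depth_target = implantation_depth_target,
                 lateral_offset_fraction = lateral_offset_fraction,
                 lateral_offset_direction = lateral_offset_direction,
                 n_retraction_steps = n_retraction_steps,
                 contact_penalty = contact_penalty,
                 convergence_tol = convergence_tol,
                 max_iterations = max_iterations,
                 relaxation = relaxation),
            class = "deployment_config")
}

# nodal reaction force law for one ring: penalty spring in series with the
# wall spring, elastic-perfectly-plastic (1% post-yield slope) where a
# calcium yield cap applies. Returns a function of ring radius R giving the
# per-node forces, plus the per-node tangent stiffness.
ring_force_law <- function(r_wall, k_wall, area, yield_cap, c_pen) {
  k_eff <- 1 / (1 / c_pen + 1 / k_wall)
  f_y <- yield_cap * area            # Inf where uncapped
  d_y <- f_y / k_eff
  list(
    force = function(R) {
      pen <- pmax(0, R - r_wall)
      ifelse(pen <= d_y, k_eff * pen, f_y + 0.01 * k_eff * (pen - d_y))
    },
    tangent = function(R) {
      pen <- pmax(0, R - r_wall)
      ifelse(pen <= 0, 0, ifelse(pen <= d_y, k_eff, 0.01 * k_eff))
    }
  )
}

# equilibrium of a single ring: frame outward force (N, already scaled by the
# ring's axial tributary length) vs summed nodal reactions. Damped Newton on
# the ring radius; monotone force laws make the root unique.
solve_ring <- function(r_wall, k_wall, area, yield_cap,
                       force_total, free_d, crimped_d, config) {
  R_free <- free_d / 2
  law <- ring_force_law(r_wall, k_wall, area, yield_cap, config$contact_penalty)
  if (all(r_wall >= R_free)) {
    return(list(R = R_free, forces = rep(0, length(r_wall)),
                converged = TRUE, iterations = 1L))
  }
  R <- R_free
  R_min <- crimped_d / 2
  h_fd <- 1e-7
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    f_nodes <- law$force(R)
    g <- force_total(2 * R) - sum(f_nodes)
    dF <- (force_total(2 * (R + h_fd)) - force_total(2 * (R - h_fd))) / (2 * h_fd)
    slope <- -dF + sum(law$tangent(R))
    if (slope <= 0) slope <- 1e-8
    step <- config$relaxation * g / slope
    R_new <- min(max(R + step, R_min), R_free)
    moved <- abs(R_new - R)
    R <- R_new
    if (moved < config$convergence_tol) { converged <- TRUE; break }
    if (iter >= config$max_iterations) break
  }
  list(R = R, forces = law$force(R), converged = converged, iterations = iter)
}

#' Deploy a THV frame into an aortic-root model
#'
#' Runs the staged sheath-retraction contact solve: the frame inflow edge is
#' placed `implantation_depth_target` mm below the annulus plane, rings are
#' released distal-to-proximal over `n_retraction_steps`, and each ring's
#' contact equilibrium is solved against the local wall stiffness. Contact
#' forces are then converted to per-element pressures with
#' [extract_pressure()].
#'
#' @param model An `aortic_root`.
#' @param device A `thv_device` from [get_device()].
#' @param config A [deployment_config()].
#' @return An object of class `deployment` with components `field` (a
#'   `pressure_field`), `frame` (per-ring state) and `config`.
#' @export
deploy <- function(model, device, config = deployment_config()) {
  stopifnot(inherits(model, "aortic_root"), inherits(device, "thv_device"),
            inherits(config, "deployment_config"))
  z0 <- -config$implantation_depth_target   # inflow edge axial position
  rows <- which(model$z >= z0 & model$z <= z0 + device$frame_height)
  if (length(rows) == 0) {
    stop("deployment: frame axial span does not overlap the meshed extent",
         call. = FALSE)
  }
  k_tot <- node_stiffness(model)
  offset <- config$lateral_offset_fraction * model$params$diameters[["annulus"]] / 2
  th_rad <- model$theta * pi / 180
  dir_rad <- config$lateral_offset_direction * pi / 180

  nodal_force <- matrix(0, model$n_z, model$n_theta)
  ring_state <- data.frame(row = rows, z = model$z[rows],
                           height = model$z[rows] - z0,
                           R = NA_real_, free_diameter = NA_real_,
                           total_force = NA_real_, converged = NA,
                           iterations = NA_integer_)
  # staged retraction: release rings from the outflow end down to the inflow
  release_order <- order(ring_state$height, decreasing = TRUE)
  steps <- split(release_order,
                 ceiling(seq_along(release_order) /
                         max(1, ceiling(length(release_order) / config$n_retraction_steps))))
  residual_history <- list()
  for (stage in steps) {
    for (i in stage) {
      row <- ring_state$row[i]
      h <- ring_state$height[i]
      r_w <- model$radius[row, ]
      if (offset != 0) {
        # wall radius measured from the offset frame axis
        r_w <- sqrt(r_w^2 + offset^2 - 2 * r_w * offset * cos(th_rad - dir_rad))
      }
      d_free <- free_diameter(device, h)
      f_tot <- function(d) radial_force(device, h, d) * model$dz
      sol <- solve_ring(r_w, k_tot[row, ], model$node_area[row, ],
                        model$calcium_yield[row, ],
                        f_tot, d_free, device$crimped_diameter, config)
      nodal_force[row, ] <- sol$forces
      ring_state$R[i] <- sol$R
      ring_state$free_diameter[i] <- d_free
      ring_state$total_force[i] <- sum(sol$forces)
      ring_state$converged[i] <- sol$converged
      ring_state$iterations[i] <- sol$iterations
    }
  }
  if (!all(ring_state$converged)) {
    bad <- ring_state[!ring_state$converged, ]
    err <- structure(class = c("thvcpi_nonconvergence", "error", "condition"),
                     list(message = sprintf(
                       "deployment: %d ring(s) failed to converge within %d iterations",
                       nrow(bad), config$max_iterations),
                       call = sys.call(-1), rings = bad))
    stop(err)
  }
  field <- extract_pressure(nodal_force, model)
  field$converged <- all(ring_state$converged)
  field$iterations <- max(ring_state$iterations)
  frame <- list(inflow_z = z0, device = device$model_name,
                rings = ring_state[order(ring_state$height), ],
                lateral_offset = offset,
                offset_direction = config$lateral_offset_direction)
  structure(list(field = field, frame = frame, config = config),
            class = "deployment")
}

#' Convert nodal contact forces to per-element pressures
#'
#' Each element's pressure is the sum of its incident nodal normal forces,
#' each node contributing `1 / (number of elements incident to it)` of its
#' force, divided by the element area. This weighting conserves total force
#' exactly: the sum of pressure times area over elements equals the sum of
#' nodal force magnitudes.
#'
#' @param nodal_forces Matrix (n_z x n_theta) of outward normal forces, N.
#' @param mesh An `aortic_root` whose grid the forces live on.
#' @return An object of class `pressure_field` with per-element `pressure`
#'   (MPa), `area` (mm^2), the nodal force matrix, and bookkeeping flags.
#' @export
extract_pressure <- function(nodal_forces, mesh) {
  stopifnot(inherits(mesh, "aortic_root"))
  if (!all(dim(nodal_forces) == c(mesh$n_z, mesh$n_theta))) {
    stop("shape: nodal force matrix must be n_z x n_theta", call. = FALSE)
  }
  w <- nodal_forces / mesh$node_n_elements
  el <- mesh$elements
  f_el <- w[cbind(el$row, el$col)] + w[cbind(el$row, el$col2)] +
    w[cbind(el$row + 1L, el$col)] + w[cbind(el$row + 1L, el$col2)]
  structure(list(pressure = f_el / mesh$element_area,
                 area = mesh$element_area,
                 nodal_force = nodal_forces,
                 converged = TRUE, iterations = 0L),
            class = "pressure_field")
}

#' Mesh sensitivity study of the conduction scores
#'
#' Re-runs the same deployment at a sequence of mesh refinements and reports
#' the relative change of CPI and CPMax between successive levels. The study
#' passes when the final change of both metrics is below `threshold`.
#'
#' @param model_generator Function `(n_theta, dz) -> aortic_root` producing
#'   the same anatomy at a given resolution.
#' @param device A `thv_device`.
#' @param config A [deployment_config()].
#' @param levels List of `c(n_theta =, dz =)` resolutions, strictly
#'   increasing refinement (at least two).
#' @param threshold Pass threshold on the final relative change (default 5%).
#' @return A data.frame with one row per level: resolution, CPI, CPMax and
#'   relative changes; attribute `pass` gives the verdict.
#' @export
mesh_sensitivity <- function(model_generator, device, config, levels,
                             threshold = 0.05) {
  stopifnot(length(levels) >= 2)
  res <- lapply(levels, function(lv) {
    model <- model_generator(lv[["n_theta"]], lv[["dz"]])
    dep <- deploy(model, device, config)
    roi <- build_roi(model)
    list(n_theta = lv[["n_theta"]], dz = lv[["dz"]],
         cpi = compute_cpi(dep$field, roi),
         cpmax = compute_cpmax(dep$field, roi))
  })
  out <- data.frame(n_theta = vapply(res, `[[`, numeric(1), "n_theta"),
                    dz = vapply(res, `[[`, numeric(1), "dz"),
                    cpi = vapply(res, `[[`, numeric(1), "cpi"),
                    cpmax = vapply(res, `[[`, numeric(1), "cpmax"))
  relchg <- function(x) c(NA, abs(diff(x)) / pmax(abs(x[-length(x)]), 1e-12))
  out$cpi_rel_change <- relchg(out$cpi)
  out$cpmax_rel_change <- relchg(out$cpmax)
  last <- nrow(out)
  attr(out, "pass") <- isTRUE(out$cpi_rel_change[last] < threshold &&
                              out$cpmax_rel_change[last] < threshold)
  attr(out, "threshold") <- threshold
  out
}

#' Total contact force carried by a pressure field
#'
#' @param field A `pressure_field`.
#' @return Sum of element pressure times element area, N.
#' @export
total_contact_force <- function(field) sum(field$pressure * field$area)

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("Contact pressure field: %d elements, %d in contact, max %.3f MPa, total force %.2f N\n",
              length(x$pressure), sum(x$pressure > 1e-6), max(x$pressure),
              total_contact_force(x)))
  invisible(x)
}

#' @export
print.deployment <- function(x, ...) {
  cat(sprintf("Deployment of %s at depth %.1f mm: %d rings, converged: %s\n",
              x$frame$device, -x$frame$inflow_z, nrow(x$frame$rings),
              x$field$converged))
  print(x$field)
  invisible(x)
}
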