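# Shared fixtures: built in code, small enough for fast solves.

# reference anatomy at the cohort means
ref_params <- function(...) root_params(...)

# pure cylinder of given diameter over the default axial extent
cylinder_params <- function(diameter = 25) {
  root_params(lvot_diameter = diameter, annulus_diameter = diameter,
              sinus_diameter = diameter, stj_diameter = diameter,
              ascending_diameter = diameter)
}

small_mesh <- function(params = ref_params(), n_theta = 36, dz = 1) {
  generate_root(params, n_theta = n_theta, dz = dz)
}

# a high-radial-force custom device (catalog schema) used to push the
# simplified solver's contact pressures above the clinical CPMax cutoff
stiff_device <- function(plateau = 60) {
  cat0 <- device_catalog()
  d <- cat0[["EvolutPRO-29"]]
  d$model_name <- "StiffTest-29"
  d$force_plateau <- plateau
  cat0[["StiffTest-29"]] <- d
  get_device("StiffTest-29", catalog = cat0)
}

# uniform synthetic pressure field over a mesh, for score arithmetic tests
uniform_field <- function(model, pressure) {
  structure(list(pressure = rep(pressure, nrow(model$elements)),
                 area = model$element_area,
                 nodal_force = matrix(0, model$n_z, model$n_theta),
                 converged = TRUE, iterations = 0L),
            class = "pressure_field")
}
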