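test_that("an undersized frame makes no contact and converges immediately", {
  m <- small_mesh(cylinder_params(40))
  dep <- deploy(m, get_device("EvolutPRO-23"))
  expect_true(dep$field$converged)
  expect_true(all(dep$field$pressure == 0))
  expect_equal(total_contact_force(dep$field), 0)
  expect_true(all(dep$frame$rings$iterations == 1))
})

test_that("a rigid narrow wall forces the frame to conform: ring force matches the force curve", {
  rigid <- material_params(foundation_stiffness = 1e5)
  m <- generate_root(cylinder_params(22), n_theta = 36, dz = 1,
                     materials = rigid)
  dev <- get_device("EvolutPRO-29")
  dep <- deploy(m, dev, deployment_config(implantation_depth_target = 6,
                                          contact_penalty = 1e5,
                                          convergence_tol = 1e-9,
                                          max_iterations = 1e5))
  rings <- dep$frame$rings
  mid <- rings[rings$height > 2 & rings$height < 8, ]
  expect_true(all(abs(mid$R * 2 - 22) < 0.01))
  for (i in seq_len(nrow(mid))) {
    expected <- radial_force(dev, mid$height[i], 22) * m$dz
    expect_equal(mid$total_force[i], expected, tolerance = 0.01)
  }
})

test_that("single-ring equilibrium matches the algebraic closed form to 1e-6 mm", {
  # linear frame force F(d) = a - b d against linear wall springs of total
  # diameter-stiffness k gives d* = (a + k d_wall) / (b + k)
  a <- 10; b <- 0.4
  k_node <- rep(0.05, 72)
  d_wall <- 22
  cfg <- deployment_config(convergence_tol = 1e-9, contact_penalty = 1e8,
                           max_iterations = 1e5)
  sol <- thvcpi:::solve_ring(rep(d_wall / 2, 72), k_node, rep(0.5, 72),
                             rep(Inf, 72),
                             function(d) pmax(a - b * d, 0),
                             free_d = a / b, crimped_d = 6, config = cfg)
  k_diam <- sum(k_node) / 2
  d_star <- (a + k_diam * d_wall) / (b + k_diam)
  expect_true(sol$converged)
  expect_lt(abs(2 * sol$R - d_star), 1e-6)

  # stiffness monotonicity: stiffer wall carries more contact force
  forces <- vapply(c(0.02, 0.05, 0.1, 0.3), function(k) {
    s <- thvcpi:::solve_ring(rep(d_wall / 2, 72), rep(k, 72), rep(0.5, 72),
                             rep(Inf, 72),
                             function(d) pmax(a - b * d, 0),
                             free_d = a / b, crimped_d = 6, config = cfg)
    sum(s$forces)
  }, numeric(1))
  expect_true(all(diff(forces) > 0))
})

test_that("every converged solve conserves force between nodes and elements", {
  cases <- list(
    list(p = ref_params(), dev = "EvolutPRO-29", depth = 6.2),
    list(p = ref_params(), dev = "EvolutR-34", depth = 3),
    list(p = cylinder_params(24), dev = "EvolutPRO-26", depth = 8))
  for (cs in cases) {
    m <- small_mesh(cs$p)
    dep <- deploy(m, get_device(cs$dev),
                  deployment_config(implantation_depth_target = cs$depth))
    expect_true(dep$field$converged)
    lhs <- total_contact_force(dep$field)
    rhs <- sum(abs(dep$field$nodal_force))
    expect_lt(abs(lhs - rhs), 0.001 * max(rhs, 1e-12))
  }
})

test_that("pressure extraction obeys null, uniform and area-scaling laws", {
  m <- small_mesh(cylinder_params(25))
  zero <- extract_pressure(matrix(0, m$n_z, m$n_theta), m)
  expect_true(all(zero$pressure == 0))

  # uniform force density (nodal force proportional to tributary area)
  # gives a uniform pressure equal to total force / total area everywhere
  phi <- 0.005
  f <- phi * m$node_area
  fld <- extract_pressure(f, m)
  expect_equal(total_contact_force(fld), sum(f))
  expect_equal(fld$pressure, rep(phi, length(fld$pressure)))
  expect_equal(phi, sum(f) / total_area(m))

  # doubling all element areas at fixed forces halves all pressures
  m2 <- m
  m2$element_area <- 2 * m$element_area
  fld2 <- extract_pressure(f, m2)
  expect_equal(fld2$pressure, fld$pressure / 2)

  expect_error(extract_pressure(matrix(0, 3, 3), m), "shape")
})

test_that("larger devices never lower the peak contact pressure on the same anatomy", {
  m <- small_mesh()
  roi <- build_roi(m)
  cpmax <- vapply(c("EvolutPRO-23", "EvolutPRO-26", "EvolutPRO-29",
                    "EvolutR-34"), function(nm) {
    dep <- deploy(m, get_device(nm))
    compute_cpmax(dep$field, roi)
  }, numeric(1))
  expect_true(all(diff(cpmax) >= -1e-12))
})

test_that("the solver is deterministic: identical inputs give identical outputs", {
  m <- small_mesh()
  d1 <- deploy(m, get_device("EvolutPRO-29"))
  d2 <- deploy(m, get_device("EvolutPRO-29"))
  expect_identical(d1$field$pressure, d2$field$pressure)
  expect_identical(d1$frame$rings, d2$frame$rings)
})

test_that("mesh sensitivity reports zero change for identical levels and converges on a cylinder", {
  pars <- cylinder_params(22)
  # negligible leaflet band keeps the wall stiffness uniform along z, so the
  # whole contact patch is governed by the single-ring closed form
  mat <- material_params(E_leaflet = 1e-9)
  gen <- function(n_theta, dz) generate_root(pars, n_theta = n_theta, dz = dz,
                                             materials = mat)
  dev <- get_device("EvolutPRO-29")
  cfg <- deployment_config(implantation_depth_target = 6,
                           contact_penalty = 1e6, convergence_tol = 1e-8)

  same <- mesh_sensitivity(gen, dev, cfg,
                           levels = list(c(n_theta = 36, dz = 1),
                                         c(n_theta = 36, dz = 1)))
  expect_equal(same$cpi_rel_change[2], 0)
  expect_equal(same$cpmax_rel_change[2], 0)
  expect_true(attr(same, "pass"))

  # closed-form 1-DOF oracle for the cylinder: uniform wall below the
  # annulus, rings in the frame's constant-diameter inflow segment
  r_w <- 11
  mat <- material_params()
  a_ref <- 12.5 * (2 * pi / 72) * 0.5
  k_density <- mat$E_wall * mat$wall_thickness / r_w^2 +
    mat$foundation_stiffness / a_ref                    # N/mm per mm^2
  K <- k_density * 2 * pi * r_w                          # N/mm penetration per mm height
  d_free <- 29; d_knee <- 0.65 * 29; plateau <- 2.0
  # decay segment: q(d) = plateau (d_free - d) / (d_free - d_knee)
  slope <- plateau / (d_free - d_knee)
  R_star <- (slope * d_free / 2 + K * r_w / 2) / (slope + K / 2)
  p_star <- k_density * (R_star - r_w)

  tab <- mesh_sensitivity(gen, dev, cfg,
                          levels = list(c(n_theta = 36, dz = 1),
                                        c(n_theta = 72, dz = 0.5),
                                        c(n_theta = 144, dz = 0.25)))
  err <- abs(tab$cpmax - p_star) / p_star
  expect_lt(err[3], 0.02)
  expect_lte(err[3], err[1] + 1e-6)
})
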