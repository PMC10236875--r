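write_config <- function(..., path = tempfile(fileext = ".yaml")) {
  yaml::write_yaml(list(...), path)
  path
}

test_that("single-patient simulation runs end-to-end from a config file", {
  cfgp <- write_config(
    seed = 1,
    mesh = list(n_theta = 36, dz = 1),
    patient = list(device = "EvolutPRO-29",
                   deployment = list(implantation_depth_target = 6.2)))
  out <- withr::local_tempfile(fileext = ".json")
  res <- suppressMessages(cli_simulate(cfgp, out_json = out))
  expect_true(file.exists(out))
  j <- jsonlite::read_json(out)
  expect_true(all(c("cpi", "cpmax", "depth_mean") %in% names(j)))
  expect_equal(j$depth_mean, 6.2)
  expect_gte(j$cpi, 0)

  # determinism: identical config + seed give identical JSON
  out2 <- withr::local_tempfile(fileext = ".json")
  suppressMessages(cli_simulate(cfgp, out_json = out2))
  expect_identical(readLines(out), readLines(out2))
})

test_that("an undersized device yields the null-contact metrics", {
  cfgp <- write_config(
    seed = 1,
    mesh = list(n_theta = 36, dz = 1),
    patient = list(
      anatomy = list(lvot_diameter = 40, annulus_diameter = 40,
                     sinus_diameter = 40, stj_diameter = 40,
                     ascending_diameter = 40),
      device = "EvolutPRO-23"))
  res <- suppressMessages(cli_simulate(cfgp, out_json = NULL))
  expect_equal(res$cpi, 0)
  expect_equal(res$cpmax, 0)
})

test_that("config schema violations are reported with field paths", {
  bad <- write_config(mesh = list(n_theta = 4),
                      patient = list(anatomy = list(annulus_diameter = -3)))
  err <- tryCatch(validate_config(yaml::read_yaml(bad)), error = identity)
  expect_match(conditionMessage(err), "mesh.n_theta")
  expect_match(conditionMessage(err), "patient.anatomy.annulus_diameter")

  expect_error(suppressMessages(
    cli_cohort(write_config(seed = 1, cohort = list(n_patients = 0)))), "cohort.n_patients")
})

test_that("cohort entry point writes the cohort and an analysis ledger", {
  cfgp <- write_config(seed = 7, cohort = list(mode = "statistical", n_patients = 3000))
  csv <- withr::local_tempfile(fileext = ".csv")
  led <- withr::local_tempfile(fileext = ".csv")
  res <- suppressMessages(cli_cohort(cfgp, out_csv = csv, out_ledger = led))
  expect_true(file.exists(csv) && file.exists(led))
  ledger <- utils::read.csv(led)
  expect_true(all(c("analysis", "estimate", "ci_low", "ci_high", "p")
                  %in% names(ledger)))
  expect_true(all(c("auc_cpi_mcd", "auc_cpmax_mcd") %in% ledger$analysis))
  auc_cpi <- ledger$estimate[ledger$analysis == "auc_cpi_mcd"]
  expect_gt(auc_cpi, 0.6)

  # physics mode carries the per-patient solver status column
  cfg2 <- write_config(seed = 3, mesh = list(n_theta = 36, dz = 1),
                       cohort = list(mode = "physics", n_patients = 5))
  res2 <- suppressMessages(cli_cohort(cfg2, out_csv = csv, out_ledger = led))
  expect_true("solver_status" %in% names(res2$cohort))
})

test_that("plan entry point writes the scan and prints a recommendation", {
  cfgp <- write_config(
    seed = 1, mesh = list(n_theta = 36, dz = 1),
    patient = list(device = "EvolutPRO-29"),
    plan = list(depth_grid = c(2, 6)))
  csv <- withr::local_tempfile(fileext = ".csv")
  expect_output(scan <- cli_plan(cfgp, out_csv = csv), "Recommended")
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 2)
  expect_equal(scan$recommended_depth, 2)

  # grid of one depth recommends it
  cfg1 <- write_config(seed = 1, mesh = list(n_theta = 36, dz = 1),
                       plan = list(depth_grid = 5))
  expect_output(s1 <- cli_plan(cfg1, out_csv = csv), "Recommended")
  expect_equal(s1$recommended_depth, 5)
})

test_that("exports produce readable STL/VTK/CSV artifacts and configs round-trip", {
  m <- generate_root(cylinder_params(25), n_theta = 18, dz = 2.5)
  dep <- deploy(m, get_device("EvolutPRO-23"))
  stl <- withr::local_tempfile(fileext = ".stl")
  vtk <- withr::local_tempfile(fileext = ".vtk")
  fcsv <- withr::local_tempfile(fileext = ".csv")
  lcsv <- withr::local_tempfile(fileext = ".csv")
  write_stl(m, stl)
  write_vtk(m, vtk, cell_scalars = list(pressure = dep$field$pressure))
  write_field_csv(dep$field, m, fcsv)
  write_landmarks_csv(m, lcsv)
  expect_equal(readLines(stl, n = 1), "solid aortic_root")
  expect_match(readLines(vtk, n = 1), "vtk DataFile")
  expect_equal(nrow(utils::read.csv(fcsv)), nrow(m$elements))
  expect_true("ms_mid" %in% utils::read.csv(lcsv)$name)

  # root-parameter YAML round-trip drives identical meshes
  vols <- zero_calcium(); vols["leaflet", "NCC"] <- 120
  p0 <- root_params(annulus_diameter = 24.2, ms_depth_rcc = 2.2,
                    calcium_volumes = vols)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_root_params(p0, yml)
  p1 <- read_root_params(yml)
  expect_equal(p1$diameters, p0$diameters)
  expect_equal(p1$calcium_volumes, p0$calcium_volumes)
  m0 <- generate_root(p0, n_theta = 18, dz = 2.5)
  m1 <- generate_root(p1, n_theta = 18, dz = 2.5)
  expect_identical(m0$radius, m1$radius)
})

test_that("run manifests record seeds, outputs and the version", {
  man <- run_manifest(list(seed = 5), 5, c("a.json"), 0.1)
  expect_s3_class(man, "run_manifest")
  expect_equal(man$seeds, 5)
  expect_equal(man$outputs, "a.json")
  expect_equal(man$version, as.character(utils::packageVersion("thvcpi")))
})
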