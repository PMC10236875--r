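# Configuration, pipeline entry points and run manifests. A YAML config
# drives each entry point; all units are fixed (mm, MPa, N, degrees, days,
# years) and never configurable. The `cli_*` functions are the programmatic
# surface behind the `thvcpi` command-line script (inst/cli/thvcpi); each
# writes its outputs to files and returns the result invisibly. Logs go to
# stderr, results to files/stdout only.

#' Validate a run configuration
#'
#' Checks structural expectations of a parsed YAML config and reports
#' violations with their field paths.
#'
#' @param config A named list (parsed YAML).
#' @return The config, invisibly, or an error listing offending fields.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  req_num <- function(x, path, lower = -Inf) {
    if (is.null(x)) return(invisible(NULL))
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower) {
      problems <<- c(problems, sprintf("%s: must be a finite number >= %g",
                                       path, lower))
    }
  }
  if (!is.list(config)) {
    stop("config: top level must be a mapping", call. = FALSE)
  }
  req_num(config$seed, "seed")
  if (!is.null(config$patient)) {
    an <- config$patient$anatomy
    for (f in c("lvot_diameter", "annulus_diameter", "sinus_diameter",
                "stj_diameter", "ascending_diameter")) {
      req_num(an[[f]], paste0("patient.anatomy.", f), lower = 1e-6)
    }
    for (f in c("ms_depth_ncc", "ms_depth_mid", "ms_depth_rcc")) {
      req_num(an[[f]], paste0("patient.anatomy.", f), lower = 0)
    }
    if (!is.null(config$patient$device) &&
        !is.character(config$patient$device)) {
      problems <- c(problems, "patient.device: must be a device name string")
    }
    dp <- config$patient$deployment
    req_num(dp$implantation_depth_target,
            "patient.deployment.implantation_depth_target", lower = 0)
    req_num(dp$n_retraction_steps, "patient.deployment.n_retraction_steps",
            lower = 1)
    req_num(dp$convergence_tol, "patient.deployment.convergence_tol",
            lower = 1e-12)
  }
  req_num(config$mesh$n_theta, "mesh.n_theta", lower = 16)
  req_num(config$mesh$dz, "mesh.dz", lower = 1e-6)
  if (!is.null(config$cohort)) {
    req_num(config$cohort$n_patients, "cohort.n_patients", lower = 1)
    if (!is.null(config$cohort$mode) &&
        !config$cohort$mode %in% c("statistical", "physics")) {
      problems <- c(problems,
                    "cohort.mode: must be 'statistical' or 'physics'")
    }
  }
  if (!is.null(config$plan$depth_grid)) {
    dg <- config$plan$depth_grid
    if (!is.numeric(unlist(dg)) || any(unlist(dg) < 0)) {
      problems <- c(problems, "plan.depth_grid: must be numeric depths >= 0")
    }
  }
  if (length(problems) > 0) {
    stop("config schema violations:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(config)
}

config_root_params <- function(config) {
  an <- config$patient$anatomy
  if (is.null(an)) return(root_params())
  args <- an[names(an) %in% names(formals(root_params))]
  vols <- zero_calcium()
  if (!is.null(an$calcium_volumes)) {
    for (region in names(an$calcium_volumes)) {
      for (cusp in names(an$calcium_volumes[[region]])) {
        vols[region, cusp] <- an$calcium_volumes[[region]][[cusp]]
      }
    }
  }
  args$calcium_volumes <- vols
  do.call(root_params, args)
}

config_deployment <- function(config) {
  dp <- config$patient$deployment
  if (is.null(dp)) return(deployment_config())
  do.call(deployment_config, dp[names(dp) %in% names(formals(deployment_config))])
}

config_mesh <- function(config) {
  list(n_theta = if (is.null(config$mesh$n_theta)) 72 else config$mesh$n_theta,
       dz = if (is.null(config$mesh$dz)) 0.5 else config$mesh$dz)
}

log_msg <- function(...) message(sprintf(...))

#' Single-patient simulation entry point
#'
#' Runs anatomy -> calcium -> deployment -> conduction scoring for one
#' configured patient; writes the metrics as JSON and, optionally, the
#' pressure field as VTK and CSV.
#'
#' @param config_path Path to the YAML run configuration.
#' @param out_json Output path for the metrics JSON (default
#'   `metrics.json` beside the config; `NULL` suppresses writing).
#' @param out_vtk,out_csv Optional geometry/field export paths.
#' @return The metrics list (invisibly).
#' @export
cli_simulate <- function(config_path, out_json = "metrics.json",
                         out_vtk = NULL, out_csv = NULL) {
  t0 <- proc.time()[["elapsed"]]
  config <- validate_config(yaml::read_yaml(config_path))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mesh <- config_mesh(config)
  pars <- config_root_params(config)
  model <- generate_root(pars, n_theta = mesh$n_theta, dz = mesh$dz, seed = seed)
  model <- place_calcium(model, seed = seed)
  dev_name <- if (is.null(config$patient$device)) "EvolutPRO-29" else config$patient$device
  device <- get_device(dev_name)
  dcfg <- config_deployment(config)
  dep <- deploy(model, device, dcfg)
  m <- conduction_metrics(dep, model)
  out <- list(device = dev_name, seed = seed,
              cpi = m$cpi, cpmax = m$cpmax,
              depth_ncc = m$depth_ncc, depth_lcc = m$depth_lcc,
              depth_mean = m$depth_mean,
              cpi_ge_20 = m$flags$cpi_ge_20,
              cpmax_ge_040 = m$flags$cpmax_ge_040,
              depth_ge_5 = m$flags$depth_ge_5)
  files <- character(0)
  if (!is.null(out_json)) {
    jsonlite::write_json(out, out_json, auto_unbox = TRUE, digits = NA)
    files <- c(files, out_json)
  }
  if (!is.null(out_vtk)) {
    write_vtk(model, out_vtk, cell_scalars = list(pressure = dep$field$pressure))
    files <- c(files, out_vtk)
  }
  if (!is.null(out_csv)) {
    write_field_csv(dep$field, model, out_csv)
    files <- c(files, out_csv)
  }
  out$manifest <- run_manifest(config, seed, files,
                               proc.time()[["elapsed"]] - t0)
  log_msg("simulate: CPI %.1f%%, CPMax %.3f MPa, depth %.1f mm", out$cpi,
          out$cpmax, out$depth_mean)
  invisible(out)
}

#' Cohort generation + analysis entry point
#'
#' Generates a cohort (statistical or physics mode), attaches secondary
#' outcomes, runs the validation battery (group AUCs, 2x2 diagnostics at
#' the clinical cutoffs, univariate and multivariate logistic odds ratios,
#' CPMax-stratum survival), and writes the cohort CSV and a flat results
#' ledger CSV.
#'
#' @param config_path Path to the YAML run configuration (section `cohort`:
#'   `n_patients`, `mode`).
#' @param out_csv Cohort CSV path.
#' @param out_ledger Results-ledger CSV path.
#' @return List with the cohort and ledger (invisibly).
#' @export
cli_cohort <- function(config_path, out_csv = "cohort.csv",
                       out_ledger = "ledger.csv") {
  t0 <- proc.time()[["elapsed"]]
  config <- validate_config(yaml::read_yaml(config_path))
  if (is.null(config$cohort$n_patients) || config$cohort$n_patients < 1) {
    stop("config: cohort.n_patients must be >= 1", call. = FALSE)
  }
  n <- as.integer(config$cohort$n_patients)
  mode <- if (is.null(config$cohort$mode)) "statistical" else config$cohort$mode
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  ocfg <- outcome_model_config(mode = mode)
  cohort <- if (mode == "physics") {
    mesh <- config_mesh(config)
    generate_physics_cohort(n, outcome_config = ocfg, seed = seed,
                            n_theta = mesh$n_theta, dz = mesh$dz)
  } else {
    generate_statistical_cohort(n, ocfg, seed = seed)
  }
  cohort <- attach_secondary_outcomes(cohort, ocfg, seed = seed + 1L)
  ledger <- cohort_analysis_ledger(cohort)
  write_cohort_csv(cohort, out_csv)
  utils::write.csv(ledger, out_ledger, row.names = FALSE)
  log_msg("cohort: %d patients (%s mode), %d ledger rows", n, mode,
          nrow(ledger))
  invisible(list(cohort = cohort, ledger = ledger,
                 manifest = run_manifest(config, seed, c(out_csv, out_ledger),
                                         proc.time()[["elapsed"]] - t0)))
}

#' Validation battery over a cohort
#'
#' @param cohort Cohort data.frame with scores and outcomes.
#' @return A flat ledger data.frame `(analysis, estimate, ci_low, ci_high,
#'   p)`.
#' @export
cohort_analysis_ledger <- function(cohort) {
  ok <- stats::complete.cases(cohort[, c("cpi", "cpmax", "outcome_mcd")])
  d <- cohort[ok, ]
  rows <- list()
  if (length(unique(d$outcome_mcd)) == 2) {
    r1 <- roc_auc(d$cpi, d$outcome_mcd)
    r2 <- roc_auc(d$cpmax, d$outcome_mcd)
    rows <- c(rows, list(
      ledger_row("auc_cpi_mcd", r1$auc, r1$ci_low, r1$ci_high, r1$p_value),
      ledger_row("auc_cpmax_mcd", r2$auc, r2$ci_low, r2$ci_high, r2$p_value)))
    flag2x2 <- function(flag, label) {
      tp <- sum(flag & d$outcome_mcd); fp <- sum(flag & !d$outcome_mcd)
      fn <- sum(!flag & d$outcome_mcd); tn <- sum(!flag & !d$outcome_mcd)
      if (min(tp + fn, tn + fp) == 0) return(NULL)
      m <- two_by_two_metrics(tp, fp, fn, tn)
      ledger_row(label, m$odds_ratio, m$ci_low, m$ci_high, m$fisher_p)
    }
    rows <- c(rows, list(flag2x2(d$cpi >= 20, "or_cpi_ge20_mcd"),
                         flag2x2(d$cpmax >= 0.40, "or_cpmax_ge040_mcd"),
                         flag2x2(d$implantation_depth >= 5, "or_depth_ge5_mcd")))
    preds <- data.frame(cpi_ge_20 = d$cpi >= 20,
                        cpmax_ge_040 = d$cpmax >= 0.40,
                        depth_ge_5 = d$implantation_depth >= 5)
    multi <- tryCatch(logistic_fit(d$outcome_mcd, preds), error = function(e) NULL)
    if (!is.null(multi)) {
      for (i in seq_len(nrow(multi))) {
        rows <- c(rows, list(ledger_row(
          paste0("or_multi_", multi$predictor[i]),
          multi$or[i], multi$ci_low[i], multi$ci_high[i], multi$p[i])))
      }
    }
  }
  if (all(c("survival_time", "death_event") %in% names(cohort))) {
    grp <- d$cpmax >= 0.40
    if (length(unique(grp)) == 2 && sum(d$death_event) > 0) {
      sv <- survival_analysis(d$survival_time, d$death_event, grp)
      rows <- c(rows, list(ledger_row("hr_death_cpmax_ge040", sv$hr,
                                      sv$ci_low, sv$ci_high, sv$logrank_p)))
    }
  }
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Depth-planning entry point
#'
#' Runs the implantation-depth scan for a configured patient and writes the
#' scan table; prints a one-line recommendation (and a residual-risk warning
#' when CPMax stays at or above 0.40 MPa even at the best depth).
#'
#' @param config_path Path to the YAML run configuration (optional section
#'   `plan.depth_grid`).
#' @param out_csv Scan-table CSV path.
#' @return The `depth_scan` result (invisibly).
#' @export
cli_plan <- function(config_path, out_csv = "depth_scan.csv") {
  config <- validate_config(yaml::read_yaml(config_path))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  mesh <- config_mesh(config)
  pars <- config_root_params(config)
  model <- generate_root(pars, n_theta = mesh$n_theta, dz = mesh$dz, seed = seed)
  model <- place_calcium(model, seed = seed)
  dev_name <- if (is.null(config$patient$device)) "EvolutPRO-29" else config$patient$device
  grid <- if (is.null(config$plan$depth_grid)) seq(0, 10, by = 1) else
    as.numeric(unlist(config$plan$depth_grid))
  scan <- depth_scan(model, get_device(dev_name), config_deployment(config),
                     depth_grid = grid)
  utils::write.csv(scan$grid, out_csv, row.names = FALSE)
  cat(sprintf("Recommended implantation depth: %.1f mm (CPI %.1f%%, CPMax %.3f MPa)\n",
              scan$recommended_depth, scan$recommended_cpi,
              scan$recommended_cpmax))
  if (isTRUE(scan$predicted_residual_risk)) {
    cat("WARNING: residual conduction-disturbance risk (CPMax >= 0.40 MPa at best depth).\n")
  }
  invisible(scan)
}

#' Mesh sensitivity entry point
#'
#' Runs the default-versus-doubled-resolution study on the configured
#' patient and reports the relative metric changes.
#'
#' @param config_path Path to the YAML run configuration.
#' @param out_csv Output CSV path for the sensitivity table.
#' @return The sensitivity table (invisibly).
#' @export
cli_sensitivity <- function(config_path, out_csv = "mesh_sensitivity.csv") {
  config <- validate_config(yaml::read_yaml(config_path))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  pars <- config_root_params(config)
  dev_name <- if (is.null(config$patient$device)) "EvolutPRO-29" else config$patient$device
  gen <- function(n_theta, dz) {
    place_calcium(generate_root(pars, n_theta = n_theta, dz = dz, seed = seed),
                  seed = seed)
  }
  tab <- mesh_sensitivity(gen, get_device(dev_name), config_deployment(config),
                          levels = list(c(n_theta = 72, dz = 0.5),
                                        c(n_theta = 144, dz = 0.25)))
  utils::write.csv(tab, out_csv, row.names = FALSE)
  cat(sprintf("Mesh sensitivity: final CPI change %.2f%%, CPMax change %.2f%% (pass: %s)\n",
              100 * tab$cpi_rel_change[nrow(tab)],
              100 * tab$cpmax_rel_change[nrow(tab)], attr(tab, "pass")))
  invisible(tab)
}

#' Build a run manifest
#'
#' Records the configuration snapshot, seed(s), package version, wall time
#' and the output file registry of a run.
#'
#' @param config Parsed configuration list.
#' @param seeds Seed(s) used.
#' @param files Character vector of output files written.
#' @param elapsed Elapsed wall time, seconds.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, files, elapsed) {
  structure(list(config = config, seeds = seeds,
                 version = as.character(utils::packageVersion("thvcpi")),
                 elapsed_s = elapsed, outputs = files,
                 timestamp = format(Sys.time(), tz = "UTC")),
            class = "run_manifest")
}
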