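# Synthetic cohort generation, in two modes.
#
# Statistical mode draws CPI/CPMax directly from group-conditional Gaussian
# distributions given the major-conduction-disturbance (MCD) label, coupling
# the two scores by a Gaussian copula. Physics mode runs the full anatomy ->
# deployment -> scoring pipeline per patient and draws outcomes from a
# logistic model on the computed scores. Secondary outcomes (permanent
# pacemaker, length of stay, LVEF change, survival) attach to either mode.

#' Outcome model configuration
#'
#' Defaults reproduce the outcome structure of an 80-patient self-expanding
#' TAVR cohort: MCD prevalence 33.8%; CPI 28.3 +/- 15.8 (events) vs
#' 15.6 +/- 11.2% (non-events); CPMax 0.51 +/- 0.20 vs 0.36 +/- 0.24 MPa;
#' pacemaker incidence 40.5% / 14.0% by CPI stratum; length of stay
#' log-normal with median 4.0 days and IQR 2.0-6.0; 30-day LVEF change
#' +3.8% (non-MCD) vs -1.3% (MCD); exponential survival with a hazard ratio
#' on the CPMax >= 0.40 MPa flag and administrative censoring at 3 years.
#'
#' @param mode `"statistical"` or `"physics"`.
#' @param prevalence_mcd MCD prevalence (statistical mode).
#' @param cpi_mcd,cpi_no_mcd,cpmax_mcd,cpmax_no_mcd `c(mean, sd)` of the
#'   group-conditional score distributions.
#' @param score_correlation Gaussian-copula correlation between CPI and
#'   CPMax within a group.
#' @param clip_scores Clip scores to their physical domains (off by default;
#'   clipping creates ties that bias rank statistics).
#' @param logistic_coef Physics-mode outcome model: named vector
#'   `(intercept, cpi, cpmax, depth)` on the linear predictor scale
#'   (per %, per MPa, per mm).
#' @param ppm_given_cpi_ge20,ppm_given_cpi_lt20 Pacemaker probabilities by
#'   CPI stratum.
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters.
#' @param lvef_change_no_mcd,lvef_change_mcd,lvef_change_sd,lvef_baseline_mean,lvef_baseline_sd
#'   LVEF model (percent points).
#' @param survival_base_rate Baseline (CPMax < 0.40) death hazard per year.
#' @param survival_hr_cpmax Hazard ratio for the CPMax >= 0.40 MPa flag.
#' @param followup_years Administrative censoring horizon, years.
#' @return An object of class `outcome_model_config`.
#' @export
outcome_model_config <- function(mode = c("statistical", "physics"),
                                 prevalence_mcd = 27 / 80,
                                 cpi_mcd = c(mean = 28.3, sd = 15.8),
                                 cpi_no_mcd = c(mean = 15.6, sd = 11.2),
                                 cpmax_mcd = c(mean = 0.51, sd = 0.20),
                                 cpmax_no_mcd = c(mean = 0.36, sd = 0.24),
                                 score_correlation = 0.5,
                                 clip_scores = FALSE,
                                 logistic_coef = c(intercept = -4.2, cpi = 0.03,
                                                   cpmax = 80, depth = 0.15),
                                 ppm_given_cpi_ge20 = 0.405,
                                 ppm_given_cpi_lt20 = 0.140,
                                 los_meanlog = log(4.0),
                                 los_sdlog = log(3) / (2 * stats::qnorm(0.75)),
                                 lvef_change_no_mcd = 3.8,
                                 lvef_change_mcd = -1.3,
                                 lvef_change_sd = 9.0,
                                 lvef_baseline_mean = 55,
                                 lvef_baseline_sd = 10,
                                 survival_base_rate = -log(1 - 0.133) / 3,
                                 survival_hr_cpmax = 5.63,
                                 followup_years = 3) {
  mode <- match.arg(mode)
  probs <- c(prevalence_mcd, ppm_given_cpi_ge20, ppm_given_cpi_lt20)
  if (any(probs < 0 | probs > 1)) {
    stop("invalid-parameter: probabilities must lie in [0, 1]", call. = FALSE)
  }
  sds <- c(cpi_mcd["sd"], cpi_no_mcd["sd"], cpmax_mcd["sd"], cpmax_no_mcd["sd"],
           lvef_change_sd)
  if (any(sds < 0)) stop("invalid-parameter: sds must be >= 0", call. = FALSE)
  if (abs(score_correlation) > 1) {
    stop("invalid-parameter: |score_correlation| must be <= 1", call. = FALSE)
  }
  structure(as.list(environment()), class = "outcome_model_config")
}

#' Default device mix of the cohort
#'
#' Sampling probabilities of the four frames; the 29-mm Evolut PRO (43.8%)
#' and 34-mm Evolut R (33.8%) dominate.
#'
#' @return Named probability vector summing to 1.
#' @export
default_device_mix <- function() {
  c("EvolutPRO-23" = 0.050, "EvolutPRO-26" = 0.174,
    "EvolutPRO-29" = 0.438, "EvolutR-34" = 0.338)
}

#' Implantation-depth sampling distribution
#'
#' @param mean,sd Normal parameters, mm (cohort: 6.2 +/- 2.3 mm), truncated
#'   at 0.
#' @return A list with `mean` and `sd`.
#' @export
default_depth_distribution <- function(mean = 6.2, sd = 2.3) {
  list(mean = mean, sd = sd)
}

# correlated standard-normal pair via the Gaussian copula
copula_pair <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

#' Generate a cohort in statistical mode
#'
#' Draws MCD labels at the configured prevalence, then CPI and CPMax from
#' the group-conditional Gaussians (coupled by the copula correlation), plus
#' implantation depth, membranous-septum depth and device labels from their
#' cohort distributions. Deterministic for a fixed seed.
#'
#' @param n Number of patients (>= 1).
#' @param config An [outcome_model_config()].
#' @param seed Integer seed.
#' @param device_mix Device sampling probabilities.
#' @param depth_distribution See [default_depth_distribution()].
#' @return A data.frame with one row per patient (see [cohort_dictionary()]).
#' @export
generate_statistical_cohort <- function(n, config = outcome_model_config(),
                                        seed = 1L,
                                        device_mix = default_device_mix(),
                                        depth_distribution = default_depth_distribution()) {
  stopifnot(n >= 1, inherits(config, "outcome_model_config"))
  set.seed(as.integer(seed))
  mcd <- stats::runif(n) < config$prevalence_mcd
  z <- copula_pair(n, config$score_correlation)
  cpi <- ifelse(mcd,
                config$cpi_mcd[["mean"]] + config$cpi_mcd[["sd"]] * z[, 1],
                config$cpi_no_mcd[["mean"]] + config$cpi_no_mcd[["sd"]] * z[, 1])
  cpmax <- ifelse(mcd,
                  config$cpmax_mcd[["mean"]] + config$cpmax_mcd[["sd"]] * z[, 2],
                  config$cpmax_no_mcd[["mean"]] + config$cpmax_no_mcd[["sd"]] * z[, 2])
  if (isTRUE(config$clip_scores)) {
    cpi <- pmin(pmax(cpi, 0), 100)
    cpmax <- pmax(cpmax, 0)
  }
  depth <- pmax(stats::rnorm(n, depth_distribution$mean, depth_distribution$sd), 0)
  ms <- (pmax(stats::rnorm(n, 5.1, 3.0), 0) + pmax(stats::rnorm(n, 3.5, 2.3), 0) +
         pmax(stats::rnorm(n, 1.7, 2.2), 0)) / 3
  dev <- sample(names(device_mix), n, replace = TRUE, prob = device_mix)
  data.frame(patient_id = seq_len(n), device = dev,
             implantation_depth = depth, cpi = cpi, cpmax = cpmax,
             ms_depth = ms, outcome_mcd = mcd,
             solver_status = "statistical",
             stringsAsFactors = FALSE)
}

#' Generate a cohort in physics mode
#'
#' For each patient: sample anatomy parameters, generate the root mesh,
#' deposit calcium, sample a device and implantation depth, run the
#' deployment solve, score CPI/CPMax over the membranous-septum region, and
#' draw the MCD outcome from a logistic model on (CPI, CPMax, depth).
#' Solver failures are resampled up to `retry_cap` times per slot, then
#' surfaced in the `solver_status` column.
#'
#' @param n Number of patients (>= 1).
#' @param table1_config Anatomy distributions, see
#'   [default_anatomy_distribution()].
#' @param device_mix Device sampling probabilities (must sum to 1).
#' @param depth_distribution See [default_depth_distribution()].
#' @param outcome_config An [outcome_model_config()] (its `logistic_coef` is
#'   used).
#' @param seed Integer seed.
#' @param n_theta,dz Mesh resolution per patient.
#' @param retry_cap Resampling attempts per patient slot on solver failure.
#' @return A data.frame with one row per patient.
#' @export
generate_physics_cohort <- function(n,
                                    table1_config = default_anatomy_distribution(),
                                    device_mix = default_device_mix(),
                                    depth_distribution = default_depth_distribution(),
                                    outcome_config = outcome_model_config(mode = "physics"),
                                    seed = 1L, n_theta = 72, dz = 0.5,
                                    retry_cap = 3L) {
  stopifnot(n >= 1)
  if (abs(sum(device_mix) - 1) > 1e-8) {
    stop("invalid-parameter: device mix must sum to 1", call. = FALSE)
  }
  set.seed(as.integer(seed))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    status <- "failed"
    for (attempt in seq_len(retry_cap)) {
      sub_seed <- (as.integer(seed) + i * 131L + attempt * 7919L) %% .Machine$integer.max
      pars <- sample_root_params(1, table1_config, seed = sub_seed)[[1]]
      dev_name <- sample(names(device_mix), 1, prob = device_mix)
      depth <- max(stats::rnorm(1, depth_distribution$mean, depth_distribution$sd), 0)
      res <- tryCatch({
        model <- generate_root(pars, n_theta = n_theta, dz = dz, seed = sub_seed)
        model <- place_calcium(model, seed = sub_seed)
        dep <- deploy(model, get_device(dev_name),
                      deployment_config(implantation_depth_target = depth))
        m <- conduction_metrics(dep, model)
        list(metrics = m, pars = pars)
      }, thvcpi_nonconvergence = identity, error = identity)
      if (!inherits(res, c("condition", "error"))) { status <- "converged"; break }
    }
    if (status == "failed") {
      rows[[i]] <- data.frame(patient_id = i, device = dev_name,
                              implantation_depth = depth, cpi = NA_real_,
                              cpmax = NA_real_, ms_depth = NA_real_,
                              outcome_mcd = NA, solver_status = "failed",
                              stringsAsFactors = FALSE)
      next
    }
    m <- res$metrics
    lp <- outcome_config$logistic_coef[["intercept"]] +
      outcome_config$logistic_coef[["cpi"]] * m$cpi +
      outcome_config$logistic_coef[["cpmax"]] * m$cpmax +
      outcome_config$logistic_coef[["depth"]] * m$depth_mean
    mcd <- stats::runif(1) < stats::plogis(lp)
    rows[[i]] <- data.frame(patient_id = i, device = dev_name,
                            implantation_depth = m$depth_mean,
                            cpi = m$cpi, cpmax = m$cpmax,
                            ms_depth = mean(res$pars$ms_depths),
                            outcome_mcd = mcd, solver_status = status,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Attach secondary clinical outcomes to a cohort
#'
#' Adds permanent-pacemaker implantation (stratum probabilities by the
#' CPI >= 20% flag), postprocedural length of stay (log-normal), baseline
#' and 30-day LVEF (Gaussian change by MCD group), and survival (exponential
#' with a hazard ratio on the CPMax >= 0.40 MPa flag, administratively
#' censored at the follow-up horizon).
#'
#' @param records Cohort data.frame carrying `cpi`, `cpmax`, `outcome_mcd`.
#' @param config An [outcome_model_config()].
#' @param seed Integer seed.
#' @return The cohort with columns `outcome_ppm`, `length_of_stay`,
#'   `lvef_baseline`, `lvef_30d`, `survival_time`, `death_event` appended.
#' @export
attach_secondary_outcomes <- function(records, config = outcome_model_config(),
                                      seed = 1L) {
  stopifnot(all(c("cpi", "cpmax", "outcome_mcd") %in% names(records)))
  set.seed(as.integer(seed))
  n <- nrow(records)
  cpi_hi <- !is.na(records$cpi) & records$cpi >= 20
  cpmax_hi <- !is.na(records$cpmax) & records$cpmax >= 0.40

  p_ppm <- ifelse(cpi_hi, config$ppm_given_cpi_ge20, config$ppm_given_cpi_lt20)
  records$outcome_ppm <- stats::runif(n) < p_ppm
  records$length_of_stay <- stats::rlnorm(n, config$los_meanlog, config$los_sdlog)
  records$lvef_baseline <- stats::rnorm(n, config$lvef_baseline_mean,
                                        config$lvef_baseline_sd)
  d_lvef <- ifelse(isTRUE_vec(records$outcome_mcd),
                   config$lvef_change_mcd, config$lvef_change_no_mcd)
  records$lvef_30d <- records$lvef_baseline +
    stats::rnorm(n, d_lvef, config$lvef_change_sd)
  rate <- config$survival_base_rate *
    ifelse(cpmax_hi, config$survival_hr_cpmax, 1)
  t_death <- stats::rexp(n, rate)
  records$death_event <- t_death <= config$followup_years
  records$survival_time <- pmin(t_death, config$followup_years)
  records
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Cohort column dictionary
#'
#' @return A data.frame documenting each cohort column and its units.
#' @export
cohort_dictionary <- function() {
  data.frame(
    column = c("patient_id", "device", "implantation_depth", "cpi", "cpmax",
               "ms_depth", "outcome_mcd", "solver_status", "outcome_ppm",
               "length_of_stay", "lvef_baseline", "lvef_30d",
               "survival_time", "death_event"),
    units = c("", "", "mm", "%", "MPa", "mm", "boolean", "", "boolean",
              "days", "%", "%", "years", "boolean"),
    description = c(
      "Sequential patient identifier",
      "THV model label",
      "Implantation depth below the annulus plane",
      "Contact pressure index over the membranous-septum region",
      "Maximum contact pressure over the region",
      "Mean membranous-septum depth over the three landmarks",
      "Major conduction disturbance (persistent LBBB or high-degree AV block)",
      "Per-patient solver status (physics mode)",
      "Permanent pacemaker implantation",
      "Postprocedural length of stay",
      "Baseline LV ejection fraction",
      "30-day LV ejection fraction",
      "Time to death or censoring",
      "Death observed within follow-up"),
    stringsAsFactors = FALSE)
}

#' Write / read a cohort as CSV
#'
#' @param records Cohort data.frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the cohort data.frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
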