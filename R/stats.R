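# Validation statistics: diagnostic 2x2 metrics, ROC/AUC with DeLong
# confidence intervals, Youden-optimal cutoffs, logistic regression odds
# ratios, survival analysis, and explicit group comparison tests.

#' Diagnostic metrics of a 2x2 table
#'
#' Computes sensitivity, specificity, positive and negative predictive
#' values, accuracy, the odds ratio with a Wald 95% confidence interval on
#' the log scale, and a two-sided Fisher exact p-value. A zero cell triggers
#' the Haldane-Anscombe 0.5 continuity correction for the odds ratio (all
#' four cells incremented), flagged in the result.
#'
#' @param tp,fp,fn,tn Cell counts: true/false positives, false/true
#'   negatives (test = risk flag, condition = outcome).
#' @return A list of class `two_by_two` with rates in percent, the odds
#'   ratio and its CI, `fisher_p`, and `continuity_corrected`.
#' @export
two_by_two_metrics <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || sum(cells) == 0) {
    stop("invalid-parameter: cell counts must be >= 0 with a positive total",
         call. = FALSE)
  }
  corrected <- any(cells == 0)
  h <- if (corrected) 0.5 else 0
  or <- ((tp + h) * (tn + h)) / ((fp + h) * (fn + h))
  se_log <- sqrt(sum(1 / (cells + h)))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  tab <- matrix(c(tp, fn, fp, tn), nrow = 2)
  structure(list(
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    ppv = 100 * tp / (tp + fp),
    npv = 100 * tn / (tn + fn),
    accuracy = 100 * (tp + tn) / sum(cells),
    odds_ratio = or, ci_low = ci[1], ci_high = ci[2],
    fisher_p = stats::fisher.test(tab)$p.value,
    continuity_corrected = corrected,
    cells = cells
  ), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("2x2 diagnostics: sens %.1f%%, spec %.1f%%, PPV %.1f%%, NPV %.1f%%, accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$accuracy))
  cat(sprintf("  OR %.2f (95%% CI %.2f-%.2f), Fisher p = %.3g%s\n",
              x$odds_ratio, x$ci_low, x$ci_high, x$fisher_p,
              if (x$continuity_corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Empirical ROC area with DeLong confidence interval
#'
#' AUC is the midrank (Mann-Whitney) estimator; the 95% CI and the p-value
#' against AUC = 0.5 use DeLong's placement-based variance.
#'
#' @param scores Numeric score per subject (higher = more likely event).
#' @param labels Logical (or 0/1) event indicator per subject.
#' @param conf_level Confidence level for the CI.
#' @return A list of class `roc_result` with `auc`, `ci_low`, `ci_high`,
#'   `p_value`, `se`, and the class sizes.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n1 <- as.numeric(sum(labels)); n0 <- as.numeric(sum(!labels))
  if (n1 == 0 || n0 == 0) {
    stop("degenerate-input: both classes must be present", call. = FALSE)
  }
  r_all <- rank(scores)
  auc <- (sum(r_all[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements via midranks within each class
  r_pos <- rank(scores[labels])
  r_neg <- rank(scores[!labels])
  v10 <- (r_all[labels] - r_pos) / n0        # P(score_neg < x_i)
  v01 <- 1 - (r_all[!labels] - r_neg) / n1   # P(score_pos > y_j)
  s10 <- if (n1 > 1) stats::var(v10) else 0
  s01 <- if (n0 > 1) stats::var(v01) else 0
  se <- sqrt(s10 / n1 + s01 / n0)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (!is.finite(se) || se == 0) NA_real_ else
    2 * stats::pnorm(-abs((auc - 0.5) / se))
  structure(list(auc = auc, ci_low = auc - zq * se, ci_high = auc + zq * se,
                 se = se, p_value = p, n_events = n1, n_nonevents = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), p = %.3g vs 0.5 [%d events / %d non-events]\n",
              x$auc, x$ci_low, x$ci_high, x$p_value, x$n_events, x$n_nonevents))
  invisible(x)
}

#' Closed-form binormal ROC area
#'
#' For Gaussian score distributions N(mu1, sd1) in events and N(mu0, sd0)
#' in non-events, AUC = Phi((mu1 - mu0) / sqrt(sd1^2 + sd0^2)).
#'
#' @param mu1,sd1 Event-group mean and SD.
#' @param mu0,sd0 Non-event-group mean and SD.
#' @return The binormal AUC.
#' @export
binormal_auc <- function(mu1, sd1, mu0, sd0) {
  v <- sd1^2 + sd0^2
  if (v <= 0) {
    stop("undefined: both sds are zero", call. = FALSE)
  }
  stats::pnorm((mu1 - mu0) / sqrt(v))
}

#' Youden-optimal operating point of a score
#'
#' Evaluates every observed threshold (rule: score >= threshold is
#' test-positive) and returns the one maximizing Youden's
#' J = sensitivity + specificity - 1, ties broken toward the lowest
#' threshold.
#'
#' @param scores,labels As in [roc_auc()].
#' @return A list with `threshold`, `sensitivity`, `specificity` (percent)
#'   and `youden_j`.
#' @export
optimal_cutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("degenerate-input: both classes must be present", call. = FALSE)
  }
  thr <- sort(unique(scores))
  bin <- match(scores, thr)
  pos_counts <- tabulate(bin[labels], nbins = length(thr))
  neg_counts <- tabulate(bin[!labels], nbins = length(thr))
  below_pos <- c(0, cumsum(pos_counts))[seq_along(thr)]  # events with score < t
  below_neg <- c(0, cumsum(neg_counts))[seq_along(thr)]
  sens <- (n1 - below_pos) / n1
  spec <- below_neg / n0
  j <- sens + spec - 1
  best <- which(j == max(j))[1]   # thresholds sorted ascending: lowest wins
  list(threshold = thr[best],
       sensitivity = 100 * sens[best],
       specificity = 100 * spec[best],
       youden_j = unname(j[best]))
}

#' Logistic regression odds ratios
#'
#' Maximum-likelihood binary logistic fit; per-predictor odds ratios with
#' Wald 95% confidence intervals and p-values. With a single binary
#' predictor the odds ratio equals the 2x2 cross-product ratio. Complete or
#' quasi-complete separation is detected (non-convergence, fitted
#' probabilities at the boundary, or extreme coefficients) and flagged; the
#' unpenalized estimates are still returned and should be read as unstable.
#'
#' @param outcome Logical event indicator.
#' @param predictors data.frame (or named list) of predictor columns.
#' @return A data.frame of class `logistic_fit` with one row per predictor:
#'   `or`, `ci_low`, `ci_high`, `p`; attribute `separation`.
#' @export
logistic_fit <- function(outcome, predictors) {
  outcome <- as.logical(outcome)
  if (length(unique(outcome)) < 2) {
    stop("degenerate-input: outcome must have both classes", call. = FALSE)
  }
  df <- as.data.frame(predictors)
  df$..y <- outcome
  fit <- suppressWarnings(stats::glm(..y ~ ., data = df,
                                     family = stats::binomial()))
  co <- summary(fit)$coefficients
  sep <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  rows <- rownames(co)[-1]
  zq <- stats::qnorm(0.975)
  out <- data.frame(predictor = rows,
                    or = exp(co[-1, 1]),
                    ci_low = exp(co[-1, 1] - zq * co[-1, 2]),
                    ci_high = exp(co[-1, 1] + zq * co[-1, 2]),
                    p = co[-1, 4],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "separation") <- sep
  class(out) <- c("logistic_fit", class(out))
  out
}

#' Two-group survival analysis
#'
#' Kaplan-Meier curves per group, the two-group log-rank test, and a
#' single-covariate Cox proportional-hazards fit with a Wald 95% CI on the
#' hazard ratio.
#'
#' @param time Follow-up times (> 0).
#' @param event Logical event indicator.
#' @param group Two-level grouping (logical or factor); the hazard ratio is
#'   for the second level (or `TRUE`) versus the first.
#' @return A list with `km` (a `survfit`), `logrank_p`, `hr`, `ci_low`,
#'   `ci_high`, `cox` (the `coxph` fit).
#' @export
survival_analysis <- function(time, event, group) {
  if (any(time <= 0)) stop("invalid-parameter: times must be > 0", call. = FALSE)
  group <- as.factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0)) {
    stop("degenerate-input: exactly two non-empty groups required", call. = FALSE)
  }
  if (sum(event) == 0) {
    stop("undefined: no events observed; hazard ratio undefined", call. = FALSE)
  }
  s <- survival::Surv(time, as.integer(event))
  km <- survival::survfit(s ~ group)
  lr <- survival::survdiff(s ~ group)
  logrank_p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  cox <- survival::coxph(s ~ group)
  hr <- unname(exp(stats::coef(cox)))
  se <- sqrt(unname(stats::vcov(cox)[1, 1]))
  zq <- stats::qnorm(0.975)
  list(km = km, logrank_p = logrank_p, hr = hr,
       ci_low = hr * exp(-zq * se), ci_high = hr * exp(zq * se), cox = cox)
}

#' Explicit group comparison tests
#'
#' Dispatches to the named classical test; the choice is always
#' caller-explicit. `"t"` is Welch's two-sample t-test, `"mannwhitney"` the
#' two-group Wilcoxon rank-sum, `"anova"` a one-way ANOVA over 2+ groups,
#' `"chisq"` the chi-squared test on a contingency of categories by group,
#' and `"fisher"` the exact test on a 2x2.
#'
#' @param values Numeric values (or categories for `"chisq"`/`"fisher"`).
#' @param groups Grouping vector.
#' @param test One of `"t"`, `"mannwhitney"`, `"anova"`, `"chisq"`,
#'   `"fisher"`.
#' @return A list with `test`, `statistic`, `p_value` and the underlying
#'   fit object.
#' @export
group_tests <- function(values, groups, test = c("t", "mannwhitney", "anova",
                                                 "chisq", "fisher")) {
  test <- match.arg(test)
  g <- as.factor(groups)
  two_groups <- function() {
    if (nlevels(g) != 2) stop("degenerate-input: exactly 2 groups required",
                              call. = FALSE)
  }
  res <- switch(test,
    t = { two_groups()
      ht <- stats::t.test(values ~ g)
      list(statistic = unname(ht$statistic), p_value = ht$p.value, fit = ht) },
    mannwhitney = { two_groups()
      ht <- stats::wilcox.test(values ~ g, exact = FALSE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value, fit = ht) },
    anova = {
      if (nlevels(g) < 2) stop("degenerate-input: >= 2 groups required",
                               call. = FALSE)
      fit <- stats::aov(values ~ g)
      sm <- summary(fit)[[1]]
      list(statistic = sm[["F value"]][1], p_value = sm[["Pr(>F)"]][1],
           fit = fit) },
    chisq = {
      ht <- stats::chisq.test(table(values, g))
      list(statistic = unname(ht$statistic), p_value = ht$p.value, fit = ht) },
    fisher = {
      tab <- table(values, g)
      if (!all(dim(tab) == c(2, 2))) {
        stop("degenerate-input: fisher requires a 2x2 contingency", call. = FALSE)
      }
      ht <- stats::fisher.test(tab)
      list(statistic = unname(ht$estimate), p_value = ht$p.value, fit = ht) })
  c(list(test = test), res)
}

#' Flat results ledger row
#'
#' @param analysis Label of the analysis.
#' @param estimate,ci_low,ci_high,p Numeric results (NA where not
#'   applicable).
#' @return A one-row data.frame with the ledger schema.
#' @export
ledger_row <- function(analysis, estimate, ci_low = NA, ci_high = NA, p = NA) {
  data.frame(analysis = analysis, estimate = estimate, ci_low = ci_low,
             ci_high = ci_high, p = p, stringsAsFactors = FALSE)
}
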