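#' Derived volume variables
#'
#' Adds \code{delta_wmh} (follow-up minus baseline WMH volume, ml) and
#' \code{icv_mean} (average of baseline and follow-up intracranial volume,
#' taken to improve precision) to a cohort table. Records missing either
#' WMH time point get \code{delta_wmh = NA} and are excluded case-wise from
#' linear models.
#'
#' @param cohort Cohort data frame (see \code{\link{simulate_cohort}}).
#' @return The cohort with \code{delta_wmh} and \code{icv_mean} columns.
#' @export
derive_volumes <- function(cohort) {
  cohort$delta_wmh <- cohort$wmh_volume_followup - cohort$wmh_volume_baseline
  cohort$icv_mean <- (cohort$icv_baseline + cohort$icv_followup) / 2
  cohort
}

pvc_markers <- c("solidity", "convexity", "concavity_index", "fd_pvc")
deep_markers <- c("eccentricity", "fd_deep")
log_scaled_predictors <- c("solidity", "wmh_volume_baseline")
invertible_predictors <- c("solidity", "convexity", "eccentricity")

#' Standardize predictors for the association models
#'
#' Per predictor: (1) solidity and baseline WMH volume are multiplied by 100
#' and natural-log transformed (they are right-skewed); (2) every predictor
#' is z-scored over the analysis sample; (3) when \code{invert} is TRUE,
#' the z-scores of solidity, convexity and eccentricity are sign-flipped so
#' that a higher value always means "more irregular / less elongated",
#' aligning the direction of effect across markers. Inversion applies to
#' logistic models by default; see \code{\link{run_association}}.
#'
#' @param cohort Cohort data frame.
#' @param predictors Character vector of predictor column names.
#' @param invert Logical: sign-flip solidity, convexity, eccentricity.
#' @return The cohort with added \code{z_<predictor>} columns.
#' @export
transform_predictors <- function(cohort, predictors, invert = FALSE) {
  for (p in predictors) {
    x <- cohort[[p]]
    if (is.null(x)) stop("predictor column not found: ", p)
    if (p %in% log_scaled_predictors) {
      if (any(x <= 0, na.rm = TRUE))
        stop("non-positive values in ", p, " cannot be log transformed")
      x <- log(100 * x)
    }
    mu <- mean(x, na.rm = TRUE)
    sdx <- sd(x, na.rm = TRUE)
    if (!is.finite(sdx) || sdx == 0)
      stop("predictor has zero variance: ", p)
    z <- (x - mu) / sdx
    if (invert && p %in% invertible_predictors) z <- -z
    cohort[[paste0("z_", p)]] <- z
  }
  cohort
}

regression_result <- function(marker, outcome, model, estimate, ci_low,
                              ci_high, p_value, n_used, flagged = FALSE) {
  data.frame(marker = marker, outcome = outcome, model = model,
             estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             p_value = p_value, n_used = n_used, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Linear model of WMH-volume change on one standardized marker
#'
#' Ordinary least squares of the outcome (default: WMH-volume change) on the
#' z-scored predictor, controlled for age, sex and mean intracranial volume.
#' B is the predictor coefficient (ml per 1-SD); the 95\% CI uses the exact
#' t quantile.
#'
#' @param cohort Cohort with derived volumes and a \code{z_<predictor>}
#'   column (see \code{\link{transform_predictors}}).
#' @param predictor Raw predictor name (e.g. \code{"concavity_index"}).
#' @param outcome Outcome column (default \code{"delta_wmh"}).
#' @param covariates Covariate columns.
#' @return One-row \code{RegressionResult} data frame.
#' @export
fit_linear <- function(cohort, predictor, outcome = "delta_wmh",
                       covariates = c("age", "sex", "icv_mean")) {
  zcol <- paste0("z_", predictor)
  if (is.null(cohort[[zcol]])) stop("missing standardized column ", zcol,
                                    "; run transform_predictors() first")
  cols <- c(outcome, zcol, covariates)
  dat <- cohort[stats::complete.cases(cohort[cols]), cols]
  if (nrow(dat) < length(cols) + 1)
    stop("too few complete cases for the linear model")
  fml <- stats::reformulate(c(zcol, covariates), response = outcome)
  fit <- lm(fml, data = dat)
  b <- coef(fit)[[zcol]]
  se <- sqrt(diag(vcov(fit))[[zcol]])
  df <- fit$df.residual
  tq <- qt(0.975, df)
  p <- 2 * stats::pt(abs(b / se), df, lower.tail = FALSE)
  regression_result(predictor, outcome, "linear", b, b - tq * se,
                    b + tq * se, p, nrow(dat))
}

#' Logistic model of a new-lesion outcome on one standardized marker
#'
#' Maximum-likelihood logistic regression (IRLS, convergence tolerance
#' 1e-8, max 50 iterations) of a new-lesion flag on the z-scored predictor,
#' controlled for age and sex. Returns the odds ratio per 1-SD with a Wald
#' 95\% CI, \code{exp(coef +/- 1.96 SE)}, and a two-sided Wald p. With
#' \code{at_risk_only} (default), participants already positive for the
#' lesion type at baseline are excluded, so the OR refers to the population
#' at risk of a first new lesion. Apparent separation is flagged, not
#' silently returned.
#'
#' @param cohort Cohort with \code{z_<predictor>} columns.
#' @param predictor Raw predictor name.
#' @param outcome New-lesion flag column (e.g. \code{"microbleed_new"}).
#' @param covariates Covariate columns.
#' @param at_risk_only Exclude baseline-prevalent cases using
#'   \code{baseline_col}.
#' @param baseline_col Baseline flag column; default replaces the
#'   \code{_new} suffix with \code{_baseline}.
#' @return One-row \code{RegressionResult} data frame (estimate is the OR).
#' @export
fit_logistic <- function(cohort, predictor, outcome,
                         covariates = c("age", "sex"),
                         at_risk_only = TRUE, baseline_col = NULL) {
  zcol <- paste0("z_", predictor)
  if (is.null(cohort[[zcol]])) stop("missing standardized column ", zcol,
                                    "; run transform_predictors() first")
  if (at_risk_only) {
    if (is.null(baseline_col))
      baseline_col <- sub("_new$", "_baseline", outcome)
    if (!is.null(cohort[[baseline_col]]))
      cohort <- cohort[!is.na(cohort[[baseline_col]]) &
                         cohort[[baseline_col]] == 0, ]
  }
  cols <- c(outcome, zcol, covariates)
  dat <- cohort[stats::complete.cases(cohort[cols]), cols]
  y <- dat[[outcome]]
  if (length(unique(y)) < 2)
    stop("outcome ", outcome, " has a single class in the analysis sample")
  fml <- stats::reformulate(c(zcol, covariates), response = outcome)
  fit <- suppressWarnings(glm(fml, data = dat, family = binomial(),
                              control = stats::glm.control(epsilon = 1e-8,
                                                           maxit = 50)))
  b <- coef(fit)[[zcol]]
  se <- sqrt(diag(vcov(fit))[[zcol]])
  flagged <- !fit$converged || abs(b) > 15 || se > 1e3
  p <- 2 * pnorm(abs(b / se), lower.tail = FALSE)
  regression_result(predictor, outcome, "logistic", exp(b),
                    exp(b - 1.96 * se), exp(b + 1.96 * se), p, nrow(dat),
                    flagged)
}

#' Run the full marker-by-outcome association analysis
#'
#' Fits, for each of the four periventricular/confluent markers, the two
#' deep markers and baseline WMH volume: one linear model of WMH-volume
#' change (age/sex/ICV-adjusted) and one logistic model per new-lesion
#' outcome (age/sex-adjusted). Solidity, convexity and eccentricity are
#' inverted for the logistic models (configurable), so their ORs read
#' "per 1-SD more irregular / less elongated". Participants missing a
#' marker (no lesions of that type) are dropped case-wise from that
#' marker's models, so n can differ between marker families. No
#' multiple-testing adjustment is applied; p < 0.05 is the significance
#' convention of the report.
#'
#' @param cohort Cohort data frame.
#' @param outcomes Character vector of outcome stems (default the five
#'   lesion types).
#' @param at_risk_only Passed to \code{\link{fit_logistic}}.
#' @param invert_scope \code{"logistic"} (default), \code{"both"} or
#'   \code{"none"}: which model families use inverted predictors.
#' @return Data frame of \code{RegressionResult} rows.
#' @export
run_association <- function(cohort,
                            outcomes = c("subcortical_infarct", "microbleed",
                                         "epvs", "cerebellar_infarct",
                                         "cortical_infarct"),
                            at_risk_only = TRUE,
                            invert_scope = c("logistic", "both", "none")) {
  invert_scope <- match.arg(invert_scope)
  cohort <- derive_volumes(cohort)
  predictors <- c(pvc_markers, deep_markers, "wmh_volume_baseline")
  lin <- transform_predictors(cohort, predictors,
                              invert = invert_scope == "both")
  log_ <- transform_predictors(cohort, predictors,
                               invert = invert_scope != "none")
  res <- list()
  for (p in predictors) {
    res[[length(res) + 1L]] <- fit_linear(lin, p)
    for (oc in outcomes)
      res[[length(res) + 1L]] <-
        fit_logistic(log_, p, paste0(oc, "_new"),
                     at_risk_only = at_risk_only)
  }
  do.call(rbind, res)
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Marker-by-outcome results table
#'
#' Formats the association results as a grid of markers (rows) by outcomes
#' (columns) with "estimate (95\% CI)" cells and significance stars
#' (* p < 0.05, ** p < 0.01, *** p < 0.001). Missing cells render as empty
#' strings, never fabricated values. The per-marker-family n is appended as
#' an attribute and printed in the header.
#'
#' @param results Data frame from \code{\link{run_association}}.
#' @param digits Decimal places of the estimates.
#' @return Character matrix (markers x outcomes) with attributes
#'   \code{n_used} (named vector per marker) and \code{direction_note}.
#' @export
build_results_table <- function(results, digits = 2) {
  markers <- unique(results$marker)
  outcomes <- unique(results$outcome)
  fmt <- function(r) {
    if (nrow(r) == 0) return("")
    sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)%s"),
            r$estimate, r$ci_low, r$ci_high, significance_stars(r$p_value))
  }
  tab <- matrix("", nrow = length(markers), ncol = length(outcomes),
                dimnames = list(markers, outcomes))
  for (m in markers) for (oc in outcomes)
    tab[m, oc] <- fmt(results[results$marker == m & results$outcome == oc, ])
  n_used <- vapply(markers, function(m)
    max(results$n_used[results$marker == m]), numeric(1))
  attr(tab, "n_used") <- n_used
  attr(tab, "direction_note") <- paste(
    "Linear cells: B (95% CI) per 1-SD of the raw marker.",
    "Logistic cells: OR (95% CI) per 1-SD with solidity, convexity and",
    "eccentricity inverted, so every OR reads 'per 1-SD more irregular",
    "(or less elongated)'. * p<0.05 ** p<0.01 *** p<0.001.")
  tab
}
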