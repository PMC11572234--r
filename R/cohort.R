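#' Cohort simulation configuration
#'
#' Defaults reproduce the published summary of the source cohort
#' (\code{\link{reference_summary}}): n = 2297 participants aged
#' 74.5 +/- 4.7 years, 61\% female, marker distributions matching the
#' reported means/SDs, log-normal baseline WMH volume matching the reported
#' mean 16.56 / SD 17.21 ml, outcome incidences matching the reported
#' change-over-time column (e.g. new microbleeds 13\%), and true effects in
#' the direction "more irregular at baseline, more progression".
#'
#' Each binary outcome is generated from a logistic model on the z-score of
#' one linked marker (default: concavity index) plus age and sex terms; the
#' WMH-volume change is linear in every marker z-score plus covariates and
#' Gaussian noise.
#'
#' @param n Number of participants (>= 10).
#' @param age_mean,age_sd Age distribution (years).
#' @param prop_female Proportion female, in (0, 1).
#' @param marker_means,marker_sds Named vectors over the six markers
#'   (solidity, convexity, concavity_index, fd_pvc, eccentricity, fd_deep).
#' @param wmh_meanlog,wmh_sdlog Log-normal parameters of baseline WMH volume
#'   (ml); defaults are solved from the reported mean/SD.
#' @param linear_slopes Named vector: true change in WMH-volume growth (ml)
#'   per 1-SD increase of each raw marker.
#' @param linear_intercept Mean WMH-volume change (ml) at covariate means.
#' @param linear_noise_sd Residual SD of the volume change (ml).
#' @param outcome_prevalence Named vector of target new-lesion incidences,
#'   each in (0, 1).
#' @param baseline_prevalence Named vector of baseline prevalences.
#' @param outcome_or Named vector of true odds ratios per 1-SD of the linked
#'   marker (on the raw marker direction).
#' @param outcome_marker Named character vector linking each outcome to the
#'   marker driving it.
#' @param age_or Odds ratio per 1-SD of age for every outcome.
#' @param missing_deep_rate Fraction of participants with no deep lesion
#'   (their deep markers are missing, mirroring case-wise exclusion).
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(
    n = 2297,
    age_mean = 74.5, age_sd = 4.7,
    prop_female = 0.61,
    marker_means = NULL, marker_sds = NULL,
    wmh_meanlog = NULL, wmh_sdlog = NULL,
    linear_slopes = c(solidity = -0.91, convexity = -1.94,
                      concavity_index = 2.28, fd_pvc = 2.62,
                      eccentricity = -2.02, fd_deep = 2.09),
    linear_intercept = 5.76,
    linear_noise_sd = 7.0,
    outcome_prevalence = c(subcortical_infarct = 0.03, microbleed = 0.13,
                           epvs = 0.02, cerebellar_infarct = 0.07,
                           cortical_infarct = 0.05),
    baseline_prevalence = c(subcortical_infarct = 0.07, microbleed = 0.17,
                            epvs = 0.16, cerebellar_infarct = 0.19,
                            cortical_infarct = 0.08),
    outcome_or = c(subcortical_infarct = 1.58, microbleed = 1.24,
                   epvs = 1.34, cerebellar_infarct = 1.16,
                   cortical_infarct = 1.09),
    outcome_marker = c(subcortical_infarct = "concavity_index",
                       microbleed = "concavity_index",
                       epvs = "concavity_index",
                       cerebellar_infarct = "concavity_index",
                       cortical_infarct = "concavity_index"),
    age_or = 1.25,
    missing_deep_rate = 4 / 2297) {
  ref <- reference_summary()
  markers <- c("solidity", "convexity", "concavity_index", "fd_pvc",
               "eccentricity", "fd_deep")
  if (is.null(marker_means))
    marker_means <- setNames(ref[paste0(markers, "_mean")], markers)
  if (is.null(marker_sds))
    marker_sds <- setNames(ref[paste0(markers, "_sd")], markers)
  if (is.null(wmh_sdlog) || is.null(wmh_meanlog)) {
    m <- ref[["wmh_volume_ml_baseline_mean"]]
    s <- ref[["wmh_volume_ml_baseline_sd"]]
    sdl <- sqrt(log(1 + (s / m)^2))
    if (is.null(wmh_sdlog)) wmh_sdlog <- sdl
    if (is.null(wmh_meanlog)) wmh_meanlog <- log(m) - sdl^2 / 2
  }
  cfg <- structure(list(
    n = as.integer(n), age_mean = age_mean, age_sd = age_sd,
    prop_female = prop_female,
    marker_means = marker_means, marker_sds = marker_sds,
    wmh_meanlog = wmh_meanlog, wmh_sdlog = wmh_sdlog,
    linear_slopes = linear_slopes, linear_intercept = linear_intercept,
    linear_noise_sd = linear_noise_sd,
    outcome_prevalence = outcome_prevalence,
    baseline_prevalence = baseline_prevalence,
    outcome_or = outcome_or, outcome_marker = outcome_marker,
    age_or = age_or, missing_deep_rate = missing_deep_rate
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n) || cfg$n < 10L)
    stop("cohort size n must be at least 10")
  if (cfg$age_sd <= 0 || cfg$linear_noise_sd <= 0 || any(cfg$marker_sds <= 0))
    stop("all standard deviations must be > 0")
  prev <- c(cfg$outcome_prevalence, cfg$baseline_prevalence, cfg$prop_female)
  if (any(prev <= 0) || any(prev >= 1))
    stop("prevalences and prop_female must lie strictly in (0, 1)")
  if (any(cfg$outcome_or <= 0)) stop("odds ratios must be > 0")
  invisible(cfg)
}

# choose the logistic intercept giving the target marginal prevalence for a
# fixed linear predictor sample
calibrate_intercept <- function(lp, target) {
  f <- function(a) mean(plogis(a + lp)) - target
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Simulate a participant cohort table
#'
#' Draws covariates, shape markers, WMH volumes and binary outcomes from the
#' configured generative model. Fully reproducible: the same config and seed
#' give an identical table.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Integer seed.
#' @return Data frame with one row per participant: id, age, sex
#'   (1 = female), the six markers (deep markers NA for participants with no
#'   deep lesions), wmh_volume_baseline/followup, icv_baseline/followup (ml),
#'   and per outcome \code{<outcome>_baseline} and \code{<outcome>_new}
#'   flags.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  cfg <- config
  with_seed(seed, {
    n <- cfg$n
    age <- rnorm(n, cfg$age_mean, cfg$age_sd)
    sex <- rbinom(n, 1, cfg$prop_female)
    markers <- names(cfg$marker_means)
    mk <- sapply(markers, function(m)
      rnorm(n, cfg$marker_means[[m]], cfg$marker_sds[[m]]))
    # physical ranges: solidity in (0,1], eccentricity in [0,1)
    mk[, "solidity"] <- pmin(pmax(mk[, "solidity"], 0.01), 1)
    mk[, "eccentricity"] <- pmin(pmax(mk[, "eccentricity"], 0.01), 0.99)
    zmk <- scale(mk)
    wmh0 <- exp(rnorm(n, cfg$wmh_meanlog, cfg$wmh_sdlog))
    icv0 <- rnorm(n, 1500, 140)
    icv1 <- icv0 + rnorm(n, -5, 8)
    zage <- (age - cfg$age_mean) / cfg$age_sd

    delta <- cfg$linear_intercept +
      as.vector(zmk[, names(cfg$linear_slopes)] %*% cfg$linear_slopes) +
      0.4 * zage - 0.3 * sex +
      rnorm(n, 0, cfg$linear_noise_sd)
    # follow-up volume is exactly baseline + delta so that the observed
    # change keeps the configured Gaussian model (no censoring; rare
    # negative follow-up volumes are accepted as model artifacts)
    wmh1 <- wmh0 + delta

    out <- data.frame(id = sprintf("P%04d", seq_len(n)), age = age,
                      sex = sex, mk, wmh_volume_baseline = wmh0,
                      wmh_volume_followup = wmh1,
                      icv_baseline = icv0, icv_followup = icv1,
                      stringsAsFactors = FALSE)
    for (oc in names(cfg$outcome_prevalence)) {
      out[[paste0(oc, "_baseline")]] <-
        rbinom(n, 1, cfg$baseline_prevalence[[oc]])
      lp <- log(cfg$outcome_or[[oc]]) * zmk[, cfg$outcome_marker[[oc]]] +
        log(cfg$age_or) * zage + 0.1 * sex
      alpha <- calibrate_intercept(lp, cfg$outcome_prevalence[[oc]])
      out[[paste0(oc, "_new")]] <- rbinom(n, 1, plogis(alpha + lp))
    }
    # participants without deep lesions carry missing deep markers
    n_missing <- rbinom(1, n, cfg$missing_deep_rate)
    if (n_missing > 0) {
      miss <- sample.int(n, n_missing)
      out$eccentricity[miss] <- NA_real_
      out$fd_deep[miss] <- NA_real_
    }
    out
  })
}
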