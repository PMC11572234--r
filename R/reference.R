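#' Published reference summary of the source cohort
#'
#' Summary statistics of the community-dwelling older-adult cohort
#' (n = 2297, 5.2-year MRI follow-up) that the simulator defaults emulate:
#' marker means/SDs, WMH volumes, outcome prevalences and the
#' missing-follow-up exclusion counts. These are published aggregate
#' numbers shipped as plain data; no participant-level data is involved.
#'
#' @return Named numeric vector of reference quantities.
#' @export
reference_summary <- function() {
  path <- system.file("extdata", "cohort_reference.csv", package = "wmhshape",
                      mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  setNames(df$value, df$quantity)
}

#' Derived quantities from the reference summary
#'
#' Recomputes, from the shipped aggregate numbers, the arithmetic facts the
#' pipeline relies on: mean WMH-volume change (follow-up minus baseline
#' means), the total excluded for missing follow-up (sum of the per-reason
#' counts), and the incidence / prevalence percentages of each outcome.
#'
#' @param ref Output of \code{\link{reference_summary}}.
#' @return Named list with \code{delta_wmh_ml},
#'   \code{missing_followup_total}, and per-outcome \code{*_new_pct} /
#'   \code{*_followup_pct} percentages (on the 0-100 scale).
#' @export
summarize_reference <- function(ref = reference_summary()) {
  n <- ref[["n_included"]]
  outcomes <- c("subcortical_infarct", "microbleed", "epvs",
                "cerebellar_infarct", "cortical_infarct")
  out <- list(
    delta_wmh_ml = ref[["wmh_volume_ml_followup_mean"]] -
      ref[["wmh_volume_ml_baseline_mean"]],
    missing_followup_total = sum(ref[grep("^excluded_", names(ref))])
  )
  for (oc in outcomes) {
    out[[paste0(oc, "_new_pct")]] <- 100 * ref[[paste0(oc, "_new_n")]] / n
    out[[paste0(oc, "_followup_pct")]] <-
      100 * ref[[paste0(oc, "_followup_n")]] / n
    out[[paste0(oc, "_baseline_pct")]] <-
      100 * ref[[paste0(oc, "_baseline_n")]] / n
  }
  out
}
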