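#' Generate a synthetic age-sex lookup curve
#'
#' The lifetime model needs a value for every integer age, but published
#' parameter tables typically print only an example value at a single anchor
#' age (here age 65). This generator extends an anchor into a full curve:
#' `"exponential"` grows log-linearly with age (a Gompertz-like shape, the
#' usual approximation for adult mortality and chronic-disease incidence),
#' `"flat"` holds the anchor constant (used for cost curves). Probability
#' curves are clipped to \[0, 1\]; the anchor is always reproduced exactly.
#'
#' These curves are anchored fixtures for testing and demonstration, not
#' estimates of any national life table or disease registry.
#'
#' @param family `"exponential"` or `"flat"`.
#' @param anchor_age Age (years) at which `anchor_value` applies.
#' @param anchor_value Curve value at `anchor_age`.
#' @param log_slope Log-scale slope per year of age (exponential family only).
#' @param sex `"male"` or `"female"` label for the output rows.
#' @param kind `"probability"` (values clipped to \[0, 1\]; anchor must lie in
#'   \[0, 1\]) or `"cost"` (values must be non-negative).
#' @param ages Integer ages to tabulate (default 0:100).
#' @return A tibble with columns `age`, `sex`, `value`.
#' @export
#' @examples
#' gen_age_curve("exponential", 65, 0.01071, 0.09, sex = "male")
gen_age_curve <- function(family = c("exponential", "flat"), anchor_age,
                          anchor_value, log_slope = 0, sex = "male",
                          kind = c("probability", "cost"), ages = 0:100) {
  family <- match.arg(family)
  kind <- match.arg(kind)
  if (kind == "probability" && (anchor_value < 0 || anchor_value > 1)) {
    stop("probability curve anchor must be in [0, 1] (got ", anchor_value, ")",
         call. = FALSE)
  }
  if (kind == "cost" && anchor_value < 0) {
    stop("cost curve anchor must be >= 0", call. = FALSE)
  }
  value <- switch(family,
    flat = rep(anchor_value, length(ages)),
    exponential = anchor_value * exp(log_slope * (ages - anchor_age))
  )
  if (kind == "probability") value <- pmin(pmax(value, 0), 1)
  tibble::tibble(age = as.integer(ages), sex = sex, value = value)
}

#' Generate an individual-level synthetic trial cohort
#'
#' Simulates per-participant records of a two-arm cessation trial matching
#' given arm-level summaries: quit status at 24 weeks drawn Bernoulli at the
#' arm's point-prevalence rate, and EQ-5D utilities at baseline and 24 weeks
#' drawn from beta distributions on \[0, 1\] matched by method of moments to
#' the arm's mean and individual-level standard deviation (`se * sqrt(n)`,
#' with `n` the reported arm size, independent of how many records are
#' simulated).
#' Baseline and follow-up utilities are drawn independently, as are quitting
#' and utility; adherence is defined for the intervention arm only.
#'
#' @param n_per_arm Participants per arm.
#' @param arm_summaries Data frame with one row per arm and columns `arm`
#'   (`"intervention"`/`"control"`), `n` (reported arm size, used to scale
#'   standard errors to individual-level spread), `quit_rate`, `eq5d_baseline_mean`,
#'   `eq5d_baseline_se`, `eq5d_24wk_mean`, `eq5d_24wk_se`, plus optional
#'   `prop_adherent` and `prop_female`. Defaults to
#'   [default_arm_summaries()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A tibble with columns `id`, `arm`, `adherent`, `sex`, `quit_24wk`,
#'   `eq5d_baseline`, `eq5d_24wk`.
#' @export
#' @examples
#' gen_trial_cohort(100, seed = 1)
gen_trial_cohort <- function(n_per_arm, arm_summaries = default_arm_summaries(),
                             seed) {
  stopifnot(n_per_arm >= 1)
  if (missing(seed)) stop("a seed must be supplied", call. = FALSE)
  if (any(arm_summaries$quit_rate < 0 | arm_summaries$quit_rate > 1)) {
    stop("quit rates must be in [0, 1]", call. = FALSE)
  }
  old <- globalenv()$.Random.seed
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  rows <- purrr::pmap(arm_summaries, function(arm, n, quit_rate,
                                              eq5d_baseline_mean,
                                              eq5d_baseline_se,
                                              eq5d_24wk_mean, eq5d_24wk_se,
                                              prop_adherent = NA,
                                              prop_female = 0.54, ...) {
    n_sd <- sqrt(n)
    tibble::tibble(
      arm = arm,
      adherent = if (arm == "intervention" && !is.na(prop_adherent)) {
        stats::runif(n_per_arm) < prop_adherent
      } else {
        rep(NA, n_per_arm)
      },
      sex = ifelse(stats::runif(n_per_arm) < prop_female, "female", "male"),
      quit_24wk = stats::runif(n_per_arm) < quit_rate,
      eq5d_baseline = rbeta_moments(n_per_arm, eq5d_baseline_mean,
                                    eq5d_baseline_se * n_sd),
      eq5d_24wk = rbeta_moments(n_per_arm, eq5d_24wk_mean,
                                eq5d_24wk_se * n_sd)
    )
  })
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, id = dplyr::row_number(), .before = 1)
}

# beta draws matched to (mean, sd) by method of moments on [0, 1]
rbeta_moments <- function(n, mean, sd) {
  fit <- fit_distribution(uncertain_value(mean, sd, "beta"))
  stats::rbeta(n, fit$shape1, fit$shape2)
}

#' Default trial arm summaries
#'
#' Arm-level 24-week outcomes of the cessation trial (intention-to-treat):
#' point-prevalence quit rates and EQ-5D means with standard errors, the
#' adherent share of the intervention arm, and the female share of
#' participants.
#'
#' @return A tibble with one row per arm.
#' @export
default_arm_summaries <- function() {
  tibble::tibble(
    arm = c("intervention", "control"),
    n = c(455L, 451L),
    quit_rate = c(0.231, 0.217),
    eq5d_baseline_mean = c(0.792, 0.800),
    eq5d_baseline_se = c(0.01, 0.01),
    eq5d_24wk_mean = c(0.800, 0.803),
    eq5d_24wk_se = c(0.01, 0.01),
    prop_adherent = c(236 / 455, NA),
    prop_female = c(0.54, 0.54)
  )
}

#' Write the default parameter bundle to disk
#'
#' Convenience wrapper: loads the packaged defaults and serialises them as
#' `params.yaml` plus per-curve CSV files under `dir/curves/`, the layout
#' [load_parameters()] consumes.
#'
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_default_inputs <- function(dir) {
  write_parameters(default_parameters(), dir)
}

#' Write a synthetic trial-record file
#'
#' Generates a cohort with [gen_trial_cohort()] and writes it as a CSV with
#' header `id,arm,adherent,sex,quit_24wk,eq5d_baseline,eq5d_24wk`.
#'
#' @inheritParams gen_trial_cohort
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_records <- function(path, n_per_arm = 455,
                                arm_summaries = default_arm_summaries(),
                                seed = 1L) {
  cohort <- gen_trial_cohort(n_per_arm, arm_summaries, seed)
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
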