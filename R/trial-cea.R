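#' Amortise a total cost over participants
#'
#' Spreads a one-off programme cost (e.g. facilitator training) evenly over
#' the participants of an arm, rounded to the cent for reporting.
#'
#' @param total_cost Total cost (NZ$), non-negative.
#' @param n_participants Number of participants, at least 1.
#' @return Per-participant cost in NZ$, rounded to 2 decimal places.
#' @export
#' @examples
#' amortise(1125, 455) # 2.47
amortise <- function(total_cost, n_participants) {
  stopifnot(total_cost >= 0)
  if (n_participants < 1) {
    stop("cannot amortise over ", n_participants, " participants",
         call. = FALSE)
  }
  round(total_cost / n_participants, 2)
}

#' Per-arm programme cost summary
#'
#' @param arm Arm label.
#' @param components Named numeric vector of per-participant cost components
#'   (NZ$), all non-negative.
#' @return An `arm_cost_summary` object: a list with `arm`, a `components`
#'   tibble and `total` (the exact sum, to the cent).
#' @export
#' @examples
#' arm_cost_summary("usual_care", c(quitline = 195.33))
arm_cost_summary <- function(arm, components = numeric()) {
  components <- unlist(components)
  if (any(components < 0)) {
    stop("cost components must be non-negative", call. = FALSE)
  }
  total <- round(sum(components), 2)
  structure(
    list(arm = arm,
         components = tibble::tibble(
           item = names(components) %||% character(),
           cost = unname(components)),
         total = total),
    class = "arm_cost_summary"
  )
}

#' @export
print.arm_cost_summary <- function(x, ...) {
  cat(sprintf("<arm_cost_summary> %s: NZ$%.2f per participant\n",
              x$arm, x$total))
  if (nrow(x$components)) {
    for (i in seq_len(nrow(x$components))) {
      cat(sprintf("  %-28s %10.2f\n", x$components$item[i],
                  x$components$cost[i]))
    }
  }
  invisible(x)
}

#' Incremental programme cost per participant
#'
#' @param intervention,control `arm_cost_summary` objects.
#' @return Difference in per-participant totals (intervention minus control),
#'   NZ$; negative values are preserved.
#' @export
#' @examples
#' p <- default_parameters()
#' incremental_cost(p$costs$intervention, p$costs$usual_care) # 427.58
incremental_cost <- function(intervention, control) {
  stopifnot(inherits(intervention, "arm_cost_summary"),
            inherits(control, "arm_cost_summary"))
  round(intervention$total - control$total, 2)
}

new_ce_result <- function(delta_cost, delta_effect, effect_units,
                          extra = list()) {
  if (delta_effect > 0 && delta_cost >= 0) {
    classification <- "cost_per_unit"
    icer <- delta_cost / delta_effect
  } else if (delta_effect > 0 && delta_cost < 0) {
    classification <- "dominant"
    icer <- NA_real_
  } else if (delta_effect < 0 && delta_cost > 0) {
    classification <- "dominated"
    icer <- NA_real_
  } else if (delta_effect < 0 && delta_cost <= 0) {
    # south-west quadrant: less effect for less cost; ratio still meaningful
    classification <- "southwest"
    icer <- delta_cost / delta_effect
  } else {
    classification <- "undefined"
    icer <- NA_real_
  }
  structure(
    c(list(delta_cost = delta_cost, delta_effect = delta_effect,
           effect_units = effect_units, icer = icer,
           classification = classification), extra),
    class = "ce_result"
  )
}

#' Incremental cost-effectiveness ratio
#'
#' Computes the incremental cost per unit of health effect of switching from
#' the control to the intervention strategy. When the effect difference is
#' positive and the cost difference non-negative the ICER is the ratio;
#' otherwise a dominance classification is returned: `"dominant"` (cheaper
#' and more effective), `"dominated"` (costlier and less effective),
#' `"southwest"` (cheaper and less effective; the ratio is reported with that
#' interpretation flag) or `"undefined"` (zero effect difference).
#'
#' @param delta_cost Incremental cost (NZ$ per participant).
#' @param effect_intervention,effect_control Effects on a common scale
#'   (e.g. quit proportion, QALYs).
#' @param effect_units Label for the effect scale.
#' @return A `ce_result` object; see [tidy.ce_result()].
#' @export
#' @examples
#' icer(427.58, 0.231, 0.217, "quitters") # ~NZ$30,541 per quitter
icer <- function(delta_cost, effect_intervention, effect_control,
                 effect_units = "effect") {
  new_ce_result(delta_cost, effect_intervention - effect_control,
                effect_units)
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  cat(sprintf("  incremental cost:   NZ$%.2f\n", x$delta_cost))
  cat(sprintf("  incremental effect: %.6g %s\n", x$delta_effect,
              x$effect_units))
  if (x$classification %in% c("cost_per_unit", "southwest")) {
    cat(sprintf("  ICER: NZ$%s per %s%s\n",
                format(round(x$icer), big.mark = ","),
                sub("s$", "", x$effect_units),
                if (x$classification == "southwest") " (south-west quadrant)" else ""))
  } else {
    cat(sprintf("  ICER: %s\n", x$classification))
  }
  invisible(x)
}

#' QALYs accrued over an interval (trapezoid rule)
#'
#' Health-state utility multiplied by time spent at that utility gives
#' quality-adjusted life-years; for a utility moving linearly from `u_start`
#' to `u_end` the accrual is the trapezoid area under the utility-time line.
#'
#' @param u_start,u_end Utilities at the interval endpoints (EQ-5D scale,
#'   \[-0.59, 1\]).
#' @param duration_years Interval length in years, non-negative.
#' @return QALYs accrued.
#' @export
#' @examples
#' qaly_accrual(0.56, 0.56, 0.5) # 0.28
qaly_accrual <- function(u_start, u_end, duration_years) {
  stopifnot(all(u_start >= -0.59 & u_start <= 1),
            all(u_end >= -0.59 & u_end <= 1))
  if (any(duration_years < 0)) {
    stop("duration must be non-negative", call. = FALSE)
  }
  (u_start + u_end) / 2 * duration_years
}

#' Baseline-adjusted between-arm QALY difference
#'
#' Computes each participant's within-trial QALYs by the trapezoid rule
#' between baseline and follow-up EQ-5D utilities, then estimates the
#' between-arm difference with baseline utility as a linear covariate
#' (ANCOVA), which removes chance baseline imbalance. Records missing either
#' utility are excluded listwise.
#'
#' @param trial_records Data frame with columns `arm`, `eq5d_baseline`,
#'   `eq5d_24wk` (as produced by [gen_trial_cohort()]).
#' @param duration_years Trial follow-up length in years (default 24 weeks).
#' @param conf_level Confidence level for the normal-approximation interval.
#' @return A tibble with columns `delta_qaly`, `conf_low`, `conf_high`,
#'   `n_intervention`, `n_control`.
#' @export
adjusted_qaly_difference <- function(trial_records,
                                     duration_years = 24 / 52,
                                     conf_level = 0.95) {
  d <- dplyr::filter(trial_records,
                     !is.na(.data$eq5d_baseline), !is.na(.data$eq5d_24wk))
  counts <- table(d$arm)
  if (any(!c("intervention", "control") %in% names(counts)) ||
      any(counts[c("intervention", "control")] < 2)) {
    stop("need at least 2 complete records per arm", call. = FALSE)
  }
  d <- dplyr::mutate(
    d,
    qaly = qaly_accrual(.data$eq5d_baseline, .data$eq5d_24wk, duration_years),
    arm = factor(.data$arm, levels = c("control", "intervention"))
  )
  fit <- stats::lm(qaly ~ arm + eq5d_baseline, data = d)
  est <- stats::coef(fit)[["armintervention"]]
  se <- sqrt(stats::vcov(fit)["armintervention", "armintervention"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    delta_qaly = est,
    conf_low = est - z * se,
    conf_high = est + z * se,
    n_intervention = as.integer(counts[["intervention"]]),
    n_control = as.integer(counts[["control"]])
  )
}

#' Within-trial cost-effectiveness analysis
#'
#' Assembles the 24-week economic evaluation: per-arm programme costs, the
#' incremental cost per participant, the ICER per additional quitter
#' (intention-to-treat and, if an adherent quit rate is supplied, for the
#' adherent subgroup), and — when individual records are supplied — the
#' baseline-adjusted QALY difference and ICER per QALY. Programme costs only
#' enter: no other health-sector costs are assumed to accrue over 24 weeks.
#'
#' @param params A `model_parameters` object (for programme costs); defaults
#'   to [default_parameters()].
#' @param quit_rate_intervention,quit_rate_control 24-week point-prevalence
#'   quit proportions.
#' @param quit_rate_adherent Optional quit proportion in the adherent
#'   intervention subgroup.
#' @param trial_records Optional individual-level records for the QALY
#'   analysis (see [adjusted_qaly_difference()]).
#' @return A list of class `trial_cea` with elements `costs` (per-arm
#'   summaries), `incremental_cost`, `icer_per_quitter`,
#'   `icer_per_quitter_adherent`, `qaly` and `icer_per_qaly`.
#' @export
#' @examples
#' trial_cea()
trial_cea <- function(params = default_parameters(),
                      quit_rate_intervention = 0.231,
                      quit_rate_control = 0.217,
                      quit_rate_adherent = 0.322,
                      trial_records = NULL) {
  dc <- incremental_cost(params$costs$intervention, params$costs$usual_care)
  res <- list(
    costs = params$costs,
    incremental_cost = dc,
    icer_per_quitter = icer(dc, quit_rate_intervention, quit_rate_control,
                            "quitters"),
    icer_per_quitter_adherent = if (!is.null(quit_rate_adherent)) {
      icer(dc, quit_rate_adherent, quit_rate_control, "quitters")
    },
    qaly = NULL, icer_per_qaly = NULL
  )
  if (!is.null(trial_records)) {
    res$qaly <- adjusted_qaly_difference(trial_records)
    res$icer_per_qaly <- new_ce_result(dc, res$qaly$delta_qaly, "QALYs")
  }
  structure(res, class = "trial_cea")
}

#' @export
print.trial_cea <- function(x, ...) {
  cat("Within-trial cost-effectiveness (24 weeks, 2012 NZ$)\n")
  cat(sprintf("  intervention cost/participant: NZ$%.2f\n",
              x$costs$intervention$total))
  cat(sprintf("  usual-care cost/participant:   NZ$%.2f\n",
              x$costs$usual_care$total))
  cat(sprintf("  incremental cost:              NZ$%.2f (NZ$%d rounded)\n",
              x$incremental_cost, round(x$incremental_cost)))
  cat(sprintf("  ICER per quitter (ITT):        NZ$%s\n",
              format(round(x$icer_per_quitter$icer), big.mark = ",")))
  if (!is.null(x$icer_per_quitter_adherent)) {
    cat(sprintf("  ICER per quitter (adherent):   NZ$%s\n",
                format(round(x$icer_per_quitter_adherent$icer),
                       big.mark = ",")))
  }
  if (!is.null(x$qaly)) {
    cat(sprintf("  adjusted QALY gain: %.4f (%.4f to %.4f)\n",
                x$qaly$delta_qaly, x$qaly$conf_low, x$qaly$conf_high))
    cat(sprintf("  ICER per QALY: %s\n",
                if (is.na(x$icer_per_qaly$icer)) x$icer_per_qaly$classification
                else paste0("NZ$", format(round(x$icer_per_qaly$icer),
                                          big.mark = ","))))
  }
  invisible(x)
}
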