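#' Convert a 2012 NZ$ amount for display
#'
#' All quantities are stored internally in 2012 NZ$; purchasing-power-parity
#' conversion is a display-layer operation using the configured rates
#' (NZ$1 = US$0.68 = EUR 0.53 by default).
#'
#' @param nzd_amount Amount in 2012 NZ$.
#' @param target `"USD"` or `"EUR"` (or `"NZD"`, a no-op).
#' @param params `model_parameters` carrying the PPP rates.
#' @param round_units Round to whole currency units for display.
#' @return Converted amount.
#' @export
#' @examples
#' convert_currency(100, "USD") # 68
convert_currency <- function(nzd_amount, target = c("NZD", "USD", "EUR"),
                             params = default_parameters(),
                             round_units = TRUE) {
  target <- match.arg(target)
  stopifnot(all(is.finite(nzd_amount)))
  out <- if (target == "NZD") {
    nzd_amount
  } else {
    rate <- params$settings$ppp[[target]]
    if (is.null(rate)) stop("no PPP rate configured for ", target,
                            call. = FALSE)
    nzd_amount * rate
  }
  if (round_units) round(out) else out
}

fmt_money <- function(x) {
  ifelse(is.na(x), "-", format(round(x), big.mark = ",", trim = TRUE))
}

fmt_icer <- function(icer, classification) {
  dplyr::case_when(
    classification == "dominant" ~ "Dominant",
    classification == "dominated" ~ "Dominated",
    classification == "undefined" ~ "-",
    TRUE ~ fmt_money(icer)
  )
}

#' Render a lifetime cost-effectiveness report
#'
#' Formats base-case and scenario results in the conventional layout of a
#' lifetime cost-effectiveness table: per-strategy mean cost and QALYs with
#' their difference for the base case, then one row per scenario with
#' incremental cost, incremental QALYs, ICER (with "Dominant"/"Dominated"
#' labelling) and, where available, the probability of cost-effectiveness at
#' the configured threshold. Missing cells render as "-" rather than erroring.
#'
#' @param base_case Named list of `ce_result` objects keyed by sex (as from
#'   [compare_strategies()]); may be empty.
#' @param scenarios Optional scenario tibble from [run_scenarios()].
#' @param currency Display currency (see [convert_currency()]).
#' @param params `model_parameters` for PPP rates.
#' @return A character vector of report lines (class `cea_report`), printed
#'   with `cat`-style formatting. All amounts are 2012 NZ$ unless converted.
#' @export
render_cea_table <- function(base_case = list(), scenarios = NULL,
                             currency = "NZD",
                             params = default_parameters()) {
  cv <- function(x) {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x)
    out[ok] <- convert_currency(x[ok], currency, params, round_units = FALSE)
    out
  }
  lines <- character()
  lines <- c(lines, sprintf(
    "Lifetime cost-effectiveness, adherent group (2012 NZ$%s)",
    if (currency != "NZD") paste0(", shown in ", currency) else ""))
  if (length(base_case) == 0L && is.null(scenarios)) {
    warning("no results supplied; rendering an empty report", call. = FALSE)
  }
  if (length(base_case) > 0L) {
    lines <- c(lines, "", "Base case:")
    lines <- c(lines, sprintf("  %-8s %14s %14s %12s %12s %10s",
                              "sex", "cost (int.)", "cost (UC)",
                              "dQALYs", "dcost", "ICER"))
    for (sex in names(base_case)) {
      r <- base_case[[sex]]
      if (is.null(r)) {
        lines <- c(lines, sprintf("  %-8s %14s %14s %12s %12s %10s",
                                  sex, "-", "-", "-", "-", "-"))
        next
      }
      by <- r$by_strategy
      lines <- c(lines, sprintf(
        "  %-8s %14s %14s %12.3f %12s %10s",
        sex, fmt_money(cv(by$cost[by$strategy == "intervention"])),
        fmt_money(cv(by$cost[by$strategy == "usual_care"])),
        r$delta_effect, fmt_money(cv(r$delta_cost)),
        fmt_icer(cv(r$icer), r$classification)))
    }
  }
  if (!is.null(scenarios) && nrow(scenarios) > 0L) {
    has_psa <- "prob_cost_effective" %in% names(scenarios)
    lines <- c(lines, "", "Scenarios:")
    lines <- c(lines, sprintf("  %-24s %-8s %10s %10s %10s%s",
                              "scenario", "sex", "dcost", "dQALYs", "ICER",
                              if (has_psa) "   P(CE)" else ""))
    for (i in seq_len(nrow(scenarios))) {
      s <- scenarios[i, ]
      lines <- c(lines, sprintf(
        "  %-24s %-8s %10s %10.3f %10s%s",
        s$scenario, s$sex, fmt_money(cv(s$delta_cost)), s$delta_qaly,
        fmt_icer(cv(s$icer), s$classification),
        if (has_psa) sprintf("   %5.3f", s$prob_cost_effective) else ""))
    }
  }
  structure(lines, class = "cea_report")
}

#' @export
print.cea_report <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}

#' Run manifest
#'
#' Records what produced a set of outputs: the analysis name, configuration
#' paths, seed, timestamp, package version and a checksum of the parameter
#' set, so a run can be reproduced exactly.
#'
#' @param analysis Short analysis label (e.g. `"psa"`).
#' @param params The `model_parameters` used.
#' @param seed Seed used (NA for deterministic stages).
#' @param config Configuration path(s), if any.
#' @return A one-row tibble.
#' @export
run_manifest <- function(analysis, params, seed = NA_integer_,
                         config = character()) {
  tibble::tibble(
    analysis = analysis,
    config = paste(config, collapse = ";"),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("quitcea")),
    parameter_checksum = rlang::hash(params)
  )
}

# --- broom-style tidiers -----------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cost-effectiveness result
#'
#' @param x A `ce_result`.
#' @param ... Unused.
#' @return One-row tibble with `delta_cost`, `delta_effect`, `effect_units`,
#'   `icer`, `classification` (plus `sex`/`start_age` for lifetime results).
#' @export
tidy.ce_result <- function(x, ...) {
  out <- tibble::tibble(
    delta_cost = x$delta_cost, delta_effect = x$delta_effect,
    effect_units = x$effect_units, icer = x$icer,
    classification = x$classification
  )
  if (!is.null(x$sex)) {
    out$sex <- x$sex
    out$start_age <- x$start_age
    out$discount_rate <- x$discount_rate
  }
  out
}

#' @rdname tidy.ce_result
#' @export
glance.ce_result <- function(x, ...) tidy(x, ...)

#' Tidy a PSA result into its per-draw incrementals
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Tibble with columns `rep`, `delta_cost`, `delta_qaly`.
#' @export
tidy.psa_result <- function(x, ...) x$draws

#' One-row PSA summary
#'
#' @param x A `psa_result`.
#' @param ... Unused.
#' @return Tibble with the PSA means, the probability of cost-effectiveness
#'   at the configured threshold, draw/exclusion counts and the seed.
#' @export
glance.psa_result <- function(x, ...) {
  tibble::tibble(
    sex = x$sex, start_age = x$start_age,
    n_draws = x$n_draws, n_excluded = x$n_excluded, seed = x$seed,
    mean_delta_cost = x$mean_delta_cost,
    mean_delta_qaly = x$mean_delta_qaly,
    wtp_threshold = x$wtp_threshold,
    prob_cost_effective = x$prob_cost_effective
  )
}

#' Tidy a within-trial CEA
#'
#' @param x A `trial_cea` object.
#' @param ... Unused.
#' @return Tibble with one row per reported quantity (`quantity`, `value`,
#'   `units`).
#' @export
tidy.trial_cea <- function(x, ...) {
  rows <- list(
    tibble::tibble(quantity = "cost_per_participant_intervention",
                   value = x$costs$intervention$total, units = "NZD"),
    tibble::tibble(quantity = "cost_per_participant_usual_care",
                   value = x$costs$usual_care$total, units = "NZD"),
    tibble::tibble(quantity = "incremental_cost",
                   value = x$incremental_cost, units = "NZD"),
    tibble::tibble(quantity = "icer_per_quitter_itt",
                   value = x$icer_per_quitter$icer, units = "NZD/quitter")
  )
  if (!is.null(x$icer_per_quitter_adherent)) {
    rows <- c(rows, list(tibble::tibble(
      quantity = "icer_per_quitter_adherent",
      value = x$icer_per_quitter_adherent$icer, units = "NZD/quitter")))
  }
  if (!is.null(x$qaly)) {
    rows <- c(rows, list(
      tibble::tibble(quantity = "adjusted_delta_qaly",
                     value = x$qaly$delta_qaly, units = "QALY"),
      tibble::tibble(quantity = "icer_per_qaly",
                     value = x$icer_per_qaly$icer, units = "NZD/QALY")))
  }
  dplyr::bind_rows(rows)
}

# --- plots -------------------------------------------------------------------

#' Cost-effectiveness plane of PSA draws
#'
#' Scatter of per-draw incremental QALYs against incremental costs, with the
#' willingness-to-pay threshold drawn as a line through the origin; draws
#' below the line are cost-effective at that threshold.
#'
#' @param object A `psa_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_abline(slope = object$wtp_threshold, intercept = 0,
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "Incremental QALYs per person",
      y = "Incremental cost per person (2012 NZ$)",
      title = sprintf("Cost-effectiveness plane (%s, start age %d)",
                      object$sex, object$start_age),
      subtitle = sprintf("dashed line: NZ$%s per QALY",
                         format(object$wtp_threshold, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param x A `psa_result` or a CEAC tibble from [ceac()].
#' @param wtp Optional willingness-to-pay threshold to mark.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, wtp = NULL) {
  if (inherits(x, "psa_result")) {
    wtp <- wtp %||% x$wtp_threshold
    x <- x$ceac
  }
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$threshold,
                                       y = .data$prob_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (NZ$ per QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot cohort state occupancy over time
#'
#' @param object A `cohort_trace`.
#' @param collapse Aggregate tunnel and quit-duration sub-states into their
#'   parent states (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_trace <- function(object, collapse = TRUE, ...) {
  df <- tidy(object)
  if (collapse) {
    df <- dplyr::mutate(df, state = dplyr::case_when(
      startsWith(.data$state, "quit_") ~ "well_quit",
      startsWith(.data$state, "lc_early") ~ "lc_early",
      startsWith(.data$state, "lc_adv") ~ "lc_adv",
      startsWith(.data$state, "dead") ~ "dead",
      TRUE ~ .data$state
    ))
    df <- dplyr::summarise(df, occupancy = sum(.data$occupancy),
                           .by = c("age", "state"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$occupancy,
                                   fill = .data$state)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "Age (years)", y = "Cohort occupancy",
                  title = sprintf("Cohort trace: %s, %s", object$strategy,
                                  object$sex)) +
    ggplot2::theme_minimal()
}

#' Tornado plot of one-way sensitivity results
#'
#' @param one_way_tbl Output of [one_way_all()].
#' @param top_n Number of parameters to show (widest ICER ranges first).
#' @return A ggplot object.
#' @export
plot_tornado <- function(one_way_tbl, top_n = 10) {
  df <- dplyr::slice_head(one_way_tbl, n = top_n)
  df <- dplyr::mutate(df, id = stats::reorder(.data$id, .data$range))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$icer_low,
                                       xend = .data$icer_high,
                                       y = .data$id, yend = .data$id),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$icer_base),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (NZ$ per QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER") +
    ggplot2::theme_minimal()
}
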