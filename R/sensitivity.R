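#' Draw a random parameter set for probabilistic sensitivity analysis
#'
#' Every uncertain scalar parameter (positive standard error) is drawn
#' independently from its method-of-moments distribution (beta for
#' probabilities, lognormal for relative risks, gamma for costs); fixed
#' parameters are left unchanged. Drawn probabilities are clipped to \[0, 1\]
#' with a warning if clipping occurs, keeping the number of draws exact.
#' Age-sex curves are not sampled by default; with `sample_curves = TRUE`
#' each curve is perturbed by a single multiplicative factor with mean 1 and
#' coefficient of variation `curve_cv` (lognormal for probability curves,
#' values re-clipped to \[0, 1\]; gamma for cost curves).
#'
#' @param params Base `model_parameters`.
#' @param sample_curves Also perturb the age-sex curves by a common factor.
#' @param curve_cv Coefficient of variation of the curve factor.
#' @return A `model_parameters` object with drawn means.
#' @export
draw_parameters <- function(params, sample_curves = FALSE, curve_cv = 0.1) {
  clipped <- 0L
  for (id in scalar_param_ids()) {
    uv <- param_get(params, id)
    if (uv$family == "fixed" || uv$se == 0) next
    x <- draw_uncertain(uv, 1L)
    if (uv$family == "beta" && (x < 0 || x > 1)) {
      x <- min(max(x, 0), 1)
      clipped <- clipped + 1L
    }
    params <- param_set(params, id, x)
  }
  if (sample_curves) {
    sdlog <- sqrt(log(1 + curve_cv^2))
    for (nm in names(params$curves)) {
      is_cost <- startsWith(nm, "cost_")
      f <- if (is_cost) {
        stats::rgamma(1L, shape = 1 / curve_cv^2, scale = curve_cv^2)
      } else {
        stats::rlnorm(1L, -sdlog^2 / 2, sdlog)
      }
      params$curves[[nm]]$value <- params$curves[[nm]]$value * f
      if (!is_cost) {
        params$curves[[nm]]$value <- pmin(pmax(params$curves[[nm]]$value, 0), 1)
      }
    }
  }
  if (clipped > 0L) {
    warning(clipped, " drawn probability value(s) clipped to [0, 1]",
            call. = FALSE)
  }
  params
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective: the fraction of PSA draws with positive
#' net monetary benefit `threshold * delta_qaly - delta_cost > 0`.
#'
#' @param draws Data frame with columns `delta_cost` and `delta_qaly`, one
#'   row per PSA draw.
#' @param thresholds Willingness-to-pay thresholds (NZ$ per QALY).
#' @return A tibble with columns `threshold`, `prob_cost_effective`.
#' @export
#' @examples
#' d <- data.frame(delta_cost = c(100, -50, 200, 10),
#'                 delta_qaly = c(0.01, 0.02, -0.01, 0.005))
#' ceac(d, 20000) # 0.75: three of four draws have positive net benefit
ceac <- function(draws, thresholds = seq(0, 50000, by = 1000)) {
  if (nrow(draws) == 0L) stop("no PSA draws supplied", call. = FALSE)
  tibble::tibble(
    threshold = thresholds,
    prob_cost_effective = purrr::map_dbl(
      thresholds,
      function(l) mean(l * draws$delta_qaly - draws$delta_cost > 0))
  )
}

#' Probabilistic sensitivity analysis
#'
#' Repeatedly draws a parameter set with [draw_parameters()] and re-runs the
#' strategy comparison, yielding the joint distribution of incremental costs
#' and QALYs and the cost-effectiveness acceptability curve. Each repetition
#' uses its own child seed derived from the root seed, so increasing `n_reps`
#' extends rather than reshuffles the draw sequence. Draws that fail model
#' preconditions are excluded with a count reported.
#'
#' @param params Base `model_parameters`.
#' @param sex `"male"` or `"female"`.
#' @param start_age Cohort starting age (default from settings).
#' @param n_reps Number of Monte Carlo repetitions.
#' @param seed Root seed (required for reproducibility).
#' @param thresholds CEAC thresholds; the configured willingness-to-pay
#'   threshold is always included.
#' @param discount_rate Optional discount-rate override.
#' @param sample_curves,curve_cv Passed to [draw_parameters()].
#' @return A `psa_result`: per-draw incrementals, CEAC, means, the seed and
#'   exclusion count. See [tidy.psa_result()], [glance.psa_result()] and
#'   [autoplot.psa_result()].
#' @export
run_psa <- function(params, sex = c("male", "female"), start_age = NULL,
                    n_reps = 1000L, seed, thresholds = seq(0, 50000, 1000),
                    discount_rate = NULL, sample_curves = FALSE,
                    curve_cv = 0.1) {
  sex <- match.arg(sex)
  stopifnot(n_reps >= 1L)
  if (missing(seed)) stop("a root seed must be supplied", call. = FALSE)
  wtp <- params$settings$wtp_threshold
  thresholds <- sort(unique(c(thresholds, wtp)))

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  rows <- vector("list", n_reps)
  n_excluded <- 0L
  for (i in seq_len(n_reps)) {
    set.seed(rep_seeds[i])
    rows[[i]] <- tryCatch({
      drawn <- suppressWarnings(draw_parameters(params, sample_curves,
                                                curve_cv))
      cs <- compare_strategies(drawn, sex, start_age,
                               discount_rate = discount_rate)
      tibble::tibble(rep = i, delta_cost = cs$delta_cost,
                     delta_qaly = cs$delta_effect)
    }, error = function(e) {
      n_excluded <<- n_excluded + 1L
      NULL
    })
  }
  draws <- dplyr::bind_rows(rows)
  if (nrow(draws) == 0L) stop("all PSA draws failed", call. = FALSE)
  if (n_excluded > 0L) {
    warning(n_excluded, " PSA draw(s) excluded after model errors",
            call. = FALSE)
  }
  curve <- ceac(draws, thresholds)
  structure(list(
    draws = draws,
    ceac = curve,
    n_draws = nrow(draws),
    n_excluded = n_excluded,
    seed = seed,
    sex = sex,
    start_age = start_age %||% params$settings$start_age,
    wtp_threshold = wtp,
    mean_delta_cost = mean(draws$delta_cost),
    mean_delta_qaly = mean(draws$delta_qaly),
    prob_cost_effective =
      curve$prob_cost_effective[curve$threshold == wtp]
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s, start age %d, %d draws (seed %d, %d excluded)\n",
              x$sex, x$start_age, x$n_draws, x$seed, x$n_excluded))
  cat(sprintf("  mean incremental cost:  NZ$%.0f\n", x$mean_delta_cost))
  cat(sprintf("  mean incremental QALYs: %.4f\n", x$mean_delta_qaly))
  cat(sprintf("  P(cost-effective at NZ$%s/QALY): %.3f\n",
              format(x$wtp_threshold, big.mark = ","),
              x$prob_cost_effective))
  invisible(x)
}

#' One-way sensitivity analysis of a single parameter
#'
#' Re-runs the deterministic strategy comparison with one parameter set to its
#' low and high inputs — mean plus or minus two standard errors when a
#' standard error is available, otherwise mean times 0.8 and 1.2 — holding
#' every other parameter at its base value. Probability parameters are
#' clamped to \[0, 1\].
#'
#' @param params Base `model_parameters`.
#' @param parameter_id Dotted identifier from [param_table()].
#' @param sex,start_age Cohort selectors as in [compare_strategies()].
#' @return A one-row tibble: `id`, `low_input`, `high_input`, `icer_low`,
#'   `icer_high`, `classification_low`, `classification_high`.
#' @export
one_way <- function(params, parameter_id, sex = c("male", "female"),
                    start_age = NULL) {
  sex <- match.arg(sex)
  uv <- param_get(params, parameter_id)
  bounds <- if (uv$se > 0) {
    c(uv$mean - 2 * uv$se, uv$mean + 2 * uv$se)
  } else {
    c(uv$mean * 0.8, uv$mean * 1.2)
  }
  if (uv$family == "beta" || grepl("^(quit_rate|relapse|utility)\\.", parameter_id) ||
      grepl("fatality", parameter_id)) {
    bounds <- pmin(pmax(bounds, 0), 1)
  }
  res <- purrr::map(bounds, function(v) {
    compare_strategies(param_set(params, parameter_id, v), sex, start_age)
  })
  tibble::tibble(
    id = parameter_id,
    low_input = bounds[1L], high_input = bounds[2L],
    icer_low = res[[1L]]$icer, icer_high = res[[2L]]$icer,
    classification_low = res[[1L]]$classification,
    classification_high = res[[2L]]$classification
  )
}

#' One-way sensitivity analysis over many parameters (tornado table)
#'
#' @param params Base `model_parameters`.
#' @param ids Parameter identifiers (default: every scalar parameter).
#' @param sex,start_age Cohort selectors.
#' @return A tibble with one [one_way()] row per parameter, plus `icer_base`
#'   and `range` (the absolute ICER spread, for tornado ordering), sorted by
#'   decreasing range.
#' @export
one_way_all <- function(params, ids = param_table(params)$id,
                        sex = c("male", "female"), start_age = NULL) {
  sex <- match.arg(sex)
  base <- compare_strategies(params, sex, start_age)
  out <- dplyr::bind_rows(purrr::map(ids, one_way, params = params, sex = sex,
                                     start_age = start_age))
  out$icer_base <- base$icer
  out$range <- abs(out$icer_high - out$icer_low)
  dplyr::arrange(out, dplyr::desc(.data$range))
}

#' Scenario analysis grid
#'
#' Re-runs the deterministic comparison for each sex under the base case and
#' the standard scenario set: alternative discount rates (0 and 5% for both
#' costs and QALYs) and alternative cohort starting ages (30, 50, 60). With
#' `psa_reps > 0`, the probability of cost-effectiveness at the configured
#' threshold is estimated per cell by PSA.
#'
#' @param params Base `model_parameters`.
#' @param sexes Sexes to include.
#' @param discount_rates Scenario discount rates (base rate reported as the
#'   base case).
#' @param start_ages Scenario starting ages (base age reported as the base
#'   case).
#' @param psa_reps PSA repetitions per cell (0 skips the PSA column).
#' @param seed Root seed, required when `psa_reps > 0`.
#' @return A tibble with one row per (sex, scenario): `scenario`, `sex`,
#'   `delta_cost`, `delta_qaly`, `icer`, `classification`, and
#'   `prob_cost_effective` when requested.
#' @export
run_scenarios <- function(params, sexes = c("male", "female"),
                          discount_rates = c(0, 0.05),
                          start_ages = c(30, 50, 60),
                          psa_reps = 0L, seed = NULL) {
  st <- params$settings
  grid <- dplyr::bind_rows(
    tibble::tibble(scenario = "base case", discount = st$discount_rate,
                   start_age = st$start_age),
    tibble::tibble(
      scenario = sprintf("%g%% discount rate", 100 * discount_rates),
      discount = discount_rates, start_age = st$start_age),
    tibble::tibble(
      scenario = sprintf("%d-year-old cohort", start_ages),
      discount = st$discount_rate, start_age = start_ages)
  )
  grid <- tidyr::crossing(sex = sexes, grid)
  if (psa_reps > 0L && is.null(seed)) {
    stop("a seed is required when psa_reps > 0", call. = FALSE)
  }
  rows <- purrr::pmap(grid, function(sex, scenario, discount, start_age) {
    cs <- compare_strategies(params, sex, start_age,
                             discount_rate = discount)
    row <- tibble::tibble(
      scenario = scenario, sex = sex, discount_rate = discount,
      start_age = start_age,
      delta_cost = cs$delta_cost, delta_qaly = cs$delta_effect,
      icer = cs$icer, classification = cs$classification
    )
    if (psa_reps > 0L) {
      psa <- run_psa(params, sex, start_age, n_reps = psa_reps, seed = seed,
                     discount_rate = discount)
      row$prob_cost_effective <- psa$prob_cost_effective
    }
    row
  })
  dplyr::bind_rows(rows)
}
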