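#' Build the Markov state space
#'
#' The lifetime model tracks a cohort through annual cycles across the states:
#' well and smoking; well and quit (expanded into one sub-state per year since
#' quitting, so that lung-cancer risk can decay and relapse can be confined to
#' the first years after a quit attempt); a single CVD living state (entered
#' after a non-fatal cardiovascular event, with permanently reduced utility);
#' early- and advanced-stage lung cancer, each expanded into tunnel sub-states
#' so that progression and death risk depend on years since diagnosis; and
#' death, disaggregated by cause (other, CVD, lung cancer) for bookkeeping.
#' The final quit and tunnel sub-states self-loop.
#'
#' @param tunnel_years Tunnel depth (years since diagnosis) per lung-cancer
#'   stage, at least 1.
#' @param quit_memory_years Years of time-since-quit tracking, at least 15 so
#'   the ex-smoker lung-cancer relative risk can decay fully.
#' @return A `state_space` object: state names plus index helpers.
#' @export
#' @examples
#' build_state_space(5, 15)
build_state_space <- function(tunnel_years = 5, quit_memory_years = 15) {
  if (tunnel_years < 1) stop("tunnel_years must be >= 1", call. = FALSE)
  if (quit_memory_years < 15) {
    stop("quit_memory_years must be >= 15 (risk-decay horizon)", call. = FALSE)
  }
  states <- c(
    "well_smoking",
    paste0("quit_", seq_len(quit_memory_years)),
    "cvd",
    paste0("lc_early_", seq_len(tunnel_years)),
    paste0("lc_adv_", seq_len(tunnel_years)),
    "dead_other", "dead_cvd", "dead_lc"
  )
  idx <- rlang::set_names(seq_along(states), states)
  structure(list(
    states = states,
    tunnel_years = tunnel_years,
    quit_memory_years = quit_memory_years,
    i_smoke = idx[["well_smoking"]],
    i_quit = unname(idx[paste0("quit_", seq_len(quit_memory_years))]),
    i_cvd = idx[["cvd"]],
    i_lc_early = unname(idx[paste0("lc_early_", seq_len(tunnel_years))]),
    i_lc_adv = unname(idx[paste0("lc_adv_", seq_len(tunnel_years))]),
    i_dead = unname(idx[c("dead_other", "dead_cvd", "dead_lc")]),
    i_dead_other = idx[["dead_other"]],
    i_dead_cvd = idx[["dead_cvd"]],
    i_dead_lc = idx[["dead_lc"]]
  ), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d states (%d quit-duration, 2 x %d lung-cancer tunnel)\n",
              length(x$states), x$quit_memory_years, x$tunnel_years))
  invisible(x)
}

#' Annual relapse hazard from a cumulative relapse proportion
#'
#' Converts a cumulative relapse proportion over several years into the
#' constant annual hazard with the same cumulative effect:
#' `h = 1 - (1 - cumulative)^(1/years)`.
#'
#' @param cumulative Cumulative relapse proportion over the period.
#' @param years Number of years the proportion accumulates over.
#' @return Annual relapse probability.
#' @export
#' @examples
#' relapse_hazard_annual(0.30, 3) # ~0.1121
relapse_hazard_annual <- function(cumulative, years) {
  stopifnot(cumulative >= 0, cumulative < 1, years >= 1)
  1 - (1 - cumulative)^(1 / years)
}

#' Quit and relapse flows for a model cycle
#'
#' Cycle 0 is the trial year: the arm's quit probability is applied to current
#' smokers and 21% of the new quitters relapse before 12 months. Over the next
#' three cycles, quitters relapse at the constant annual hazard whose
#' cumulative effect is 30%; from the fourth post-quit year on, relapse is
#' zero.
#'
#' @param cycle_index Years since the quit attempt (0 = trial year).
#' @param quitters Number (or share) of quitters entering the cycle.
#' @param params A `model_parameters` object.
#' @return A list with `relapse_flow` and `remaining`.
#' @export
#' @examples
#' annual_quit_dynamics(0, 1000, default_parameters()) # 210 relapse
annual_quit_dynamics <- function(cycle_index, quitters,
                                 params = default_parameters()) {
  stopifnot(cycle_index >= 0)
  rel <- params$relapse
  rate <- if (cycle_index == 0) {
    rel$to_12mo$mean
  } else if (cycle_index <= rel$years_after_12mo) {
    relapse_hazard_annual(rel$after_12mo_cumulative$mean,
                          rel$years_after_12mo)
  } else {
    0
  }
  list(relapse_flow = quitters * rate, remaining = quitters * (1 - rate))
}

#' Ex-smoker lung-cancer relative risk by time since quitting
#'
#' At the moment of quitting an ex-smoker carries the smoker-level lung-cancer
#' relative risk versus the general population; the excess decays linearly to
#' 1.0 over the decay horizon (15 years by default), after which risk equals
#' the general population's.
#'
#' @param years_since_quit Years since the quit attempt, non-negative.
#' @param rr_smoker Smoker relative risk versus the general population.
#' @param decay_years Years over which the excess risk decays to zero.
#' @return Relative risk (vectorised over `years_since_quit`).
#' @export
#' @examples
#' lc_rr_exsmoker(7.5, 1.771) # 1.3855
lc_rr_exsmoker <- function(years_since_quit, rr_smoker, decay_years = 15) {
  stopifnot(all(years_since_quit >= 0), rr_smoker >= 1)
  frac <- pmin(years_since_quit, decay_years) / decay_years
  rr_smoker - (rr_smoker - 1) * frac
}

#' Outcome split of a cardiovascular event
#'
#' Of those experiencing a CVD event, a share dies before reaching hospital;
#' of the hospitalised remainder, a further share dies within 28 days; the
#' survivors enter the CVD living state with permanently reduced utility.
#'
#' @param event_probability Probability (or share of the cohort) experiencing
#'   an event this cycle.
#' @param prehospital_fatality Probability of pre-hospital death given an
#'   event.
#' @param fatality_28day Probability of death within 28 days given
#'   hospitalisation.
#' @return A list with `instant_death_share`, `early_death_share`,
#'   `survivor_share`, `hospitalised_share` and `total_fatality` (all scaled
#'   by `event_probability`, except `total_fatality` which is per event).
#' @export
#' @examples
#' cvd_event_outcome(1)$total_fatality # ~0.2392
cvd_event_outcome <- function(event_probability,
                              prehospital_fatality = 0.181,
                              fatality_28day = 0.071) {
  stopifnot(all(event_probability >= 0), all(event_probability <= 1))
  hosp <- 1 - prehospital_fatality
  fatality <- prehospital_fatality + hosp * fatality_28day
  list(
    instant_death_share = event_probability * prehospital_fatality,
    early_death_share = event_probability * hosp * fatality_28day,
    survivor_share = event_probability * (1 - fatality),
    hospitalised_share = event_probability * hosp,
    total_fatality = fatality
  )
}

flow_names <- function() {
  c("quit_flow", "relapse_flow", "lc_incident", "cvd_events",
    "cvd_hospitalised", "cvd_deaths", "lc_deaths")
}

#' Run the lifetime Markov cohort model for one strategy
#'
#' Tracks a sex-specific cohort of smokers from the start age to the horizon
#' age in annual cycles. Within each cycle, events apply in a fixed order:
#' mortality (background for all living states, plus stage-specific
#' lung-cancer death and progression within the tunnels), then disease
#' incidence from the well states (CVD and lung cancer are mutually
#' exclusive), then smoking-status flows (the quit attempt with its
#' within-year relapse in the first cycle, annual relapse hazards in
#' post-quit years 1-3, and advancement of the time-since-quit clock).
#' Smokers face the smoker relative risks for both diseases; quitters' CVD
#' risk falls immediately by the ex-smoker relative risk while their
#' lung-cancer risk decays linearly over the decay horizon (see
#' [lc_rr_exsmoker()]). Relapsers return to the full smoker risk profile.
#'
#' @param params A `model_parameters` object.
#' @param strategy `"intervention"` (adherent exercise-counselling add-on) or
#'   `"usual_care"`; the strategies differ only in quit probability and
#'   programme cost.
#' @param sex `"male"` or `"female"`.
#' @param start_age Cohort starting age (default from `params$settings`).
#' @return A `cohort_trace` object: the occupancy matrix (one row per cycle,
#'   row 0 = initial distribution), per-cycle event flows used for costing,
#'   and run metadata. See [tidy.cohort_trace()] and [accumulate()].
#' @export
#' @examples
#' tr <- run_cohort(default_parameters(), "usual_care", "male")
#' tr
run_cohort <- function(params, strategy = c("intervention", "usual_care"),
                       sex = c("male", "female"), start_age = NULL) {
  strategy <- match.arg(strategy)
  sex <- match.arg(sex)
  st <- params$settings
  if (is.null(start_age)) start_age <- st$start_age
  if (start_age >= st$horizon_age) {
    stop("start_age must be below horizon_age", call. = FALSE)
  }
  ss <- build_state_space(st$tunnel_years, st$quit_memory_years)
  n_cycles <- st$horizon_age - start_age
  n_states <- length(ss$states)
  ages <- start_age + seq_len(n_cycles) - 1L

  # pre-computed per-cycle inputs
  m_bg <- curve_value(params$curves$background_mortality, ages, sex)
  p_lc_base <- curve_value(params$curves$lc_incidence, ages, sex)
  p_cvd_base <- curve_value(params$curves$cvd_incidence, ages, sex)

  rr_lc_smoker <- params$lc$rr_smoker$mean
  rr_cvd_smoker <- params$cvd$rr_smoker$mean
  rr_cvd_ex <- rr_cvd_smoker * params$cvd$rr_exsmoker_vs_smoker$mean
  rr_lc_quit <- lc_rr_exsmoker(seq_len(ss$quit_memory_years), rr_lc_smoker,
                               params$lc$rr_decay_years)
  quit_prob <- params$quit_rate[[strategy]][[sex]]$mean
  relapse0 <- params$relapse$to_12mo$mean
  h_relapse <- relapse_hazard_annual(params$relapse$after_12mo_cumulative$mean,
                                     params$relapse$years_after_12mo)
  relapse_years <- params$relapse$years_after_12mo
  evt <- cvd_event_outcome(1, params$cvd$prehospital_fatality$mean,
                           params$cvd$fatality_28day$mean)
  d_early <- params$lc$death_prob_early
  d_adv <- params$lc$death_prob_adv
  p_prog <- params$lc$progression_early_to_adv
  Tn <- ss$tunnel_years
  Q <- ss$quit_memory_years

  occ <- matrix(0, nrow = n_cycles + 1L, ncol = n_states,
                dimnames = list(NULL, ss$states))
  occ[1L, ss$i_smoke] <- 1
  flows <- matrix(0, nrow = n_cycles, ncol = length(flow_names()),
                  dimnames = list(NULL, flow_names()))
  clipped <- FALSE

  for (t in seq_len(n_cycles)) {
    v <- occ[t, ]
    nxt <- numeric(n_states)
    nxt[ss$i_dead] <- v[ss$i_dead]

    # 1) mortality
    m <- m_bg[t]
    living <- setdiff(seq_len(n_states), ss$i_dead)
    nxt[ss$i_dead_other] <- nxt[ss$i_dead_other] + sum(v[living]) * m
    surv <- v
    surv[living] <- v[living] * (1 - m)

    # lung-cancer tunnel: stage-specific death, progression, advancement
    lc_deaths <- 0
    adv_in <- numeric(Tn)   # arrivals into advanced tunnel positions
    early_in <- numeric(Tn)
    for (y in seq_len(Tn)) {
      e <- surv[ss$i_lc_early[y]]
      lc_deaths <- lc_deaths + e * d_early
      stay <- e * (1 - d_early)
      adv_in[1L] <- adv_in[1L] + stay * p_prog
      early_in[min(y + 1L, Tn)] <- early_in[min(y + 1L, Tn)] +
        stay * (1 - p_prog)
      a <- surv[ss$i_lc_adv[y]]
      lc_deaths <- lc_deaths + a * d_adv
      adv_in[min(y + 1L, Tn)] <- adv_in[min(y + 1L, Tn)] + a * (1 - d_adv)
    }
    nxt[ss$i_dead_lc] <- nxt[ss$i_dead_lc] + lc_deaths

    # 2) disease incidence from the well states (mutually exclusive risks)
    p_lc_s <- p_lc_base[t] * rr_lc_smoker
    p_cvd_s <- p_cvd_base[t] * rr_cvd_smoker
    p_lc_q <- p_lc_base[t] * rr_lc_quit
    p_cvd_q <- p_cvd_base[t] * rr_cvd_ex
    tot_s <- p_lc_s + p_cvd_s
    if (tot_s > 1) {
      p_lc_s <- p_lc_s / tot_s; p_cvd_s <- p_cvd_s / tot_s; clipped <- TRUE
    }
    tot_q <- p_lc_q + p_cvd_q
    over <- tot_q > 1
    if (any(over)) {
      p_lc_q[over] <- p_lc_q[over] / tot_q[over]
      p_cvd_q[over] <- p_cvd_q[over] / tot_q[over]
      clipped <- TRUE
    }

    smoker <- surv[ss$i_smoke]
    quit_v <- surv[ss$i_quit]
    lc_new <- smoker * p_lc_s + sum(quit_v * p_lc_q)
    cvd_new <- smoker * p_cvd_s + sum(quit_v * p_cvd_q)

    early_in[1L] <- early_in[1L] + lc_new * params$lc$early_prop
    adv_in[1L] <- adv_in[1L] + lc_new * params$lc$adv_prop
    nxt[ss$i_lc_early] <- early_in
    nxt[ss$i_lc_adv] <- adv_in

    nxt[ss$i_dead_cvd] <- nxt[ss$i_dead_cvd] + cvd_new * evt$total_fatality
    nxt[ss$i_cvd] <- surv[ss$i_cvd] + cvd_new * (1 - evt$total_fatality)

    # 3) smoking-status flows among disease-free well states
    smoker_left <- smoker * (1 - p_lc_s - p_cvd_s)
    quit_left <- quit_v * (1 - p_lc_q - p_cvd_q)

    quit_flow <- 0
    relapse_flow <- 0
    quit_next <- numeric(Q)
    if (t == 1L) {
      quit_flow <- smoker_left * quit_prob
      relapse_flow <- quit_flow * relapse0
      quit_next[1L] <- quit_flow - relapse_flow
      smoker_left <- smoker_left - quit_flow + relapse_flow
    }
    for (d in seq_len(Q)) {
      x <- quit_left[d]
      if (x == 0) next
      if (d <= relapse_years) {
        rel <- x * h_relapse
        relapse_flow <- relapse_flow + rel
        smoker_left <- smoker_left + rel
        x <- x - rel
      }
      dn <- min(d + 1L, Q)
      quit_next[dn] <- quit_next[dn] + x
    }
    nxt[ss$i_smoke] <- smoker_left
    nxt[ss$i_quit] <- nxt[ss$i_quit] + quit_next

    occ[t + 1L, ] <- nxt
    flows[t, ] <- c(quit_flow, relapse_flow, lc_new, cvd_new,
                    cvd_new * evt$hospitalised_share,
                    cvd_new * evt$total_fatality, lc_deaths)
  }
  if (clipped) {
    warning("disease incidence probabilities exceeded 1 and were rescaled",
            call. = FALSE)
  }

  structure(list(
    occupancy = occ, flows = flows, states = ss$states, state_space = ss,
    strategy = strategy, sex = sex, start_age = start_age,
    ages = c(start_age, ages + 1L)
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1L
  final_dead <- sum(x$occupancy[n + 1L, x$state_space$i_dead])
  cat(sprintf("<cohort_trace> %s, %s, ages %d-%d (%d cycles)\n",
              x$strategy, x$sex, x$start_age, x$start_age + n, n))
  cat(sprintf("  final dead occupancy: %.4f\n", final_dead))
  invisible(x)
}

#' Tidy a cohort trace into long format
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A tibble with columns `cycle`, `age`, `state`, `occupancy`
#'   (cycle 0 is the initial distribution).
#' @export
tidy.cohort_trace <- function(x, ...) {
  df <- tibble::as_tibble(x$occupancy)
  df$cycle <- seq_len(nrow(df)) - 1L
  df$age <- x$start_age + df$cycle
  tidyr::pivot_longer(df, cols = -c("cycle", "age"), names_to = "state",
                      values_to = "occupancy")
}

state_utilities <- function(ss, params) {
  u <- numeric(length(ss$states))
  u[ss$i_smoke] <- params$utility$well_smoking$mean
  u[ss$i_quit] <- params$utility$well_quit$mean
  u[ss$i_cvd] <- params$utility$cvd$mean
  u[ss$i_lc_early] <- params$utility$lc_early$mean
  u[ss$i_lc_adv] <- params$utility$lc_adv$mean
  u
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' Per cycle, QALYs are the occupancy-weighted sum of state utilities and
#' costs comprise: the programme cost in the first cycle; lung-cancer
#' first-year costs for incident cases; lung-cancer subsequent annual costs
#' for tunnel occupants beyond their first year; CVD first-year costs for
#' hospitalised events; and terminal six-month costs charged as a lump sum in
#' the cycle of cause-specific death. Costs and QALYs for cycle t are
#' discounted by `1/(1+r)^(t-1)` (the first cycle is undiscounted). State
#' occupancy at the end of each cycle is used; with `half_cycle = TRUE`,
#' QALYs and life-years use the mean of start- and end-of-cycle occupancy.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param params The `model_parameters` used to produce it.
#' @param discount_rate Annual discount rate; defaults to the configured one.
#' @param half_cycle Apply a half-cycle correction to QALYs and life-years.
#' @return A `cohort_result` tibble with columns `strategy`, `sex`,
#'   `start_age`, `cost`, `qalys`, `life_years` (cost and QALYs discounted,
#'   life-years undiscounted).
#' @export
accumulate <- function(trace, params, discount_rate = NULL,
                       half_cycle = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"))
  r <- discount_rate %||% params$settings$discount_rate
  ss <- trace$state_space
  n_cycles <- nrow(trace$flows)
  ages <- trace$start_age + seq_len(n_cycles) - 1L
  sex <- trace$sex
  disc <- (1 + r)^-(seq_len(n_cycles) - 1L)

  u <- state_utilities(ss, params)
  occ_end <- trace$occupancy[-1L, , drop = FALSE]
  occ_use <- if (half_cycle) {
    (occ_end + trace$occupancy[-(n_cycles + 1L), , drop = FALSE]) / 2
  } else {
    occ_end
  }
  qaly_cycle <- as.numeric(occ_use %*% u)
  living <- setdiff(seq_along(ss$states), ss$i_dead)
  ly_cycle <- rowSums(occ_use[, living, drop = FALSE])

  c_lc_first <- curve_value(params$curves$cost_lc_first_year, ages, sex)
  c_lc_sub <- curve_value(params$curves$cost_lc_subsequent, ages, sex)
  c_lc_term <- curve_value(params$curves$cost_lc_terminal, ages, sex)
  c_cvd_first <- curve_value(params$curves$cost_cvd_first_year, ages, sex)
  c_cvd_term <- curve_value(params$curves$cost_cvd_terminal, ages, sex)

  lc_later <- c(ss$i_lc_early[-1L], ss$i_lc_adv[-1L])
  lc_sub_occ <- if (length(lc_later)) {
    rowSums(occ_end[, lc_later, drop = FALSE])
  } else {
    numeric(n_cycles)
  }

  cost_cycle <-
    c_lc_first * trace$flows[, "lc_incident"] +
    c_lc_sub * lc_sub_occ +
    c_lc_term * trace$flows[, "lc_deaths"] +
    c_cvd_first * trace$flows[, "cvd_hospitalised"] +
    c_cvd_term * trace$flows[, "cvd_deaths"]
  cost_cycle[1L] <- cost_cycle[1L] + params$costs[[trace$strategy]]$total

  tibble::new_tibble(tibble::tibble(
    strategy = trace$strategy, sex = sex, start_age = trace$start_age,
    cost = sum(disc * cost_cycle),
    qalys = sum(disc * qaly_cycle),
    life_years = sum(ly_cycle)
  ), class = "cohort_result")
}

#' Compare the two strategies over a lifetime
#'
#' Runs the Markov cohort model under the intervention and under usual care —
#' identical in everything except quit probability and programme cost — and
#' returns incremental discounted costs, incremental discounted QALYs and the
#' ICER (or dominance classification).
#'
#' @inheritParams run_cohort
#' @param discount_rate Optional override of the configured discount rate.
#' @param half_cycle Passed to [accumulate()].
#' @return A `ce_result` with extra fields `by_strategy` (per-strategy
#'   `cohort_result` rows), `sex`, `start_age`, `discount_rate`.
#' @export
#' @examples
#' compare_strategies(default_parameters(), sex = "male")
compare_strategies <- function(params, sex = c("male", "female"),
                               start_age = NULL, discount_rate = NULL,
                               half_cycle = FALSE) {
  sex <- match.arg(sex)
  res <- dplyr::bind_rows(purrr::map(
    c("intervention", "usual_care"),
    function(s) accumulate(run_cohort(params, s, sex, start_age), params,
                           discount_rate = discount_rate,
                           half_cycle = half_cycle)
  ))
  dc <- res$cost[1L] - res$cost[2L]
  dq <- res$qalys[1L] - res$qalys[2L]
  new_ce_result(dc, dq, "QALYs", extra = list(
    by_strategy = res, sex = sex,
    start_age = start_age %||% params$settings$start_age,
    discount_rate = discount_rate %||% params$settings$discount_rate
  ))
}
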