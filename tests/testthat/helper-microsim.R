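# Independent per-individual microsimulation oracle.
#
# Re-implements the annual rules of the cohort model by simulating n
# individuals with explicit random draws, sharing no code with run_cohort().
# Event order per cycle mirrors the model contract: background mortality,
# lung-cancer tunnel death/progression, disease incidence from the well
# states, then quit/relapse flows and clock advancement. Returns collapsed
# end-of-cycle occupancy proportions (well_smoking, well_quit, cvd, lc, dead)
# per cycle, including cycle 0.
microsim_occupancy <- function(params, strategy, sex, start_age, horizon_age,
                               n = 1e5, seed = 1L) {
  set.seed(seed)
  n_cycles <- horizon_age - start_age
  ages <- start_age + seq_len(n_cycles) - 1L

  m_bg <- curve_value(params$curves$background_mortality, ages, sex)
  p_lc_base <- curve_value(params$curves$lc_incidence, ages, sex)
  p_cvd_base <- curve_value(params$curves$cvd_incidence, ages, sex)

  rr_lc_s <- params$lc$rr_smoker$mean
  rr_cvd_s <- params$cvd$rr_smoker$mean
  rr_cvd_q <- rr_cvd_s * params$cvd$rr_exsmoker_vs_smoker$mean
  q_prob <- params$quit_rate[[strategy]][[sex]]$mean
  rel0 <- params$relapse$to_12mo$mean
  rel_years <- params$relapse$years_after_12mo
  h_rel <- 1 - (1 - params$relapse$after_12mo_cumulative$mean)^(1 / rel_years)
  fat_pre <- params$cvd$prehospital_fatality$mean
  fat_28 <- params$cvd$fatality_28day$mean
  p_fatal <- fat_pre + (1 - fat_pre) * fat_28
  d_early <- params$lc$death_prob_early
  d_adv <- params$lc$death_prob_adv
  p_prog <- params$lc$progression_early_to_adv
  decay <- params$lc$rr_decay_years
  Q <- params$settings$quit_memory_years

  # states: 1 smoker, 2 quit, 3 cvd, 4 lc_early, 5 lc_adv, 6 dead
  state <- rep(1L, n)
  tsq <- rep(0L, n) # years since quit

  snap <- function() {
    c(well_smoking = mean(state == 1L), well_quit = mean(state == 2L),
      cvd = mean(state == 3L), lc = mean(state %in% 4:5),
      dead = mean(state == 6L))
  }
  out <- matrix(NA_real_, nrow = n_cycles + 1L, ncol = 5L,
                dimnames = list(NULL, names(snap())))
  out[1L, ] <- snap()

  for (t in seq_len(n_cycles)) {
    alive <- state != 6L
    die <- alive & stats::runif(n) < m_bg[t]
    state[die] <- 6L

    # lung-cancer tunnel
    in_lc <- state %in% 4:5
    u <- stats::runif(n)
    lc_die <- in_lc & u < ifelse(state == 4L, d_early, d_adv)
    prog <- state == 4L & !lc_die & stats::runif(n) < p_prog
    state[lc_die] <- 6L
    state[prog] <- 5L

    # disease incidence from the well states
    well <- state %in% 1:2
    rr_lc <- ifelse(state == 1L, rr_lc_s,
                    rr_lc_s - (rr_lc_s - 1) * pmin(tsq, decay) / decay)
    p_lc <- p_lc_base[t] * rr_lc
    p_cvd <- p_cvd_base[t] * ifelse(state == 1L, rr_cvd_s, rr_cvd_q)
    u <- stats::runif(n)
    got_lc <- well & u < p_lc
    got_cvd <- well & !got_lc & u < p_lc + p_cvd
    adv <- got_lc & stats::runif(n) < params$lc$adv_prop
    state[got_lc] <- ifelse(adv[got_lc], 5L, 4L)
    cvd_fatal <- got_cvd & stats::runif(n) < p_fatal
    state[got_cvd] <- 3L
    state[cvd_fatal] <- 6L

    # quit / relapse flows among the disease-free well states
    if (t == 1L) {
      quits <- state == 1L & stats::runif(n) < q_prob
      stay_quit <- quits & stats::runif(n) >= rel0
      state[stay_quit] <- 2L
      tsq[stay_quit] <- 0L # advanced to 1 below
    }
    relapse <- state == 2L & tsq >= 1L & tsq <= rel_years &
      stats::runif(n) < h_rel
    state[relapse] <- 1L
    tsq[relapse] <- 0L
    isq <- state == 2L
    tsq[isq] <- pmin(tsq[isq] + 1L, Q)

    out[t + 1L, ] <- snap()
  }
  out
}

# collapse a cohort_trace occupancy matrix to the microsim's 5 groups
collapse_trace <- function(trace) {
  ss <- trace$state_space
  occ <- trace$occupancy
  cbind(
    well_smoking = occ[, ss$i_smoke],
    well_quit = rowSums(occ[, ss$i_quit, drop = FALSE]),
    cvd = occ[, ss$i_cvd],
    lc = rowSums(occ[, c(ss$i_lc_early, ss$i_lc_adv), drop = FALSE]),
    dead = rowSums(occ[, ss$i_dead, drop = FALSE])
  )
}
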