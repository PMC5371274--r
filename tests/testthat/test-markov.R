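test_that("state space enumerates tunnels, quit memory and cause-split death", {
  ss <- build_state_space(5, 15)
  expect_length(ss$i_lc_early, 5)
  expect_length(ss$i_lc_adv, 5)
  expect_length(c(ss$i_lc_early, ss$i_lc_adv), 10)
  expect_length(ss$i_quit, 15)
  expect_equal(sum(ss$states == "cvd"), 1) # exactly one CVD living state
  expect_length(ss$i_dead, 3)
  expect_length(ss$states, 1 + 15 + 1 + 10 + 3)
  ss1 <- build_state_space(1, 15)
  expect_length(c(ss1$i_lc_early, ss1$i_lc_adv), 2)
  expect_error(build_state_space(0, 15), "tunnel")
  expect_error(build_state_space(5, 10), "quit_memory")
})

test_that("quit/relapse dynamics follow the published relapse schedule", {
  p <- default_parameters()
  # trial year: 21% of new quitters relapse before 12 months
  expect_equal(annual_quit_dynamics(0, 1000, p)$relapse_flow, 210)
  # years 1-3: constant annual hazard with cumulative effect 30%
  h <- relapse_hazard_annual(0.30, 3)
  expect_equal((1 - h)^3, 0.70)
  expect_equal(annual_quit_dynamics(1, 1000, p)$remaining, 1000 * 0.7^(1 / 3))
  expect_equal(annual_quit_dynamics(3, 500, p)$relapse_flow, 500 * h)
  # beyond the third post-quit year relapse is zero
  expect_equal(annual_quit_dynamics(4, 1000, p)$relapse_flow, 0)
  expect_equal(annual_quit_dynamics(5, 1000, p)$relapse_flow, 0)
})

test_that("ex-smoker lung-cancer risk decays linearly to baseline", {
  expect_equal(lc_rr_exsmoker(0, 1.771), 1.771)
  expect_equal(lc_rr_exsmoker(7.5, 1.771), 1.3855)
  expect_equal(lc_rr_exsmoker(15, 1.771), 1)
  expect_equal(lc_rr_exsmoker(40, 1.771), 1) # no overshoot past the horizon
  expect_true(all(diff(lc_rr_exsmoker(0:20, 1.771)) <= 0))
})

test_that("CVD event outcomes compose the two fatality stages", {
  o <- cvd_event_outcome(1)
  expect_equal(o$total_fatality, 0.181 + (1 - 0.181) * 0.071)
  expect_equal(o$instant_death_share + o$early_death_share + o$survivor_share,
               1)
  z <- cvd_event_outcome(0)
  expect_equal(z$instant_death_share, 0)
  expect_equal(z$survivor_share, 0)
  half <- cvd_event_outcome(0.5)
  expect_equal(half$hospitalised_share, 0.5 * (1 - 0.181))
})

test_that("cohort traces conserve probability and death is absorbing", {
  p <- default_parameters()
  for (strategy in c("intervention", "usual_care")) {
    for (sex in c("male", "female")) {
      tr <- run_cohort(p, strategy, sex)
      expect_lt(max(abs(rowSums(tr$occupancy) - 1)), 1e-9)
      dead <- rowSums(tr$occupancy[, tr$state_space$i_dead, drop = FALSE])
      expect_true(all(diff(dead) >= -1e-12))
      expect_true(all(tr$occupancy >= -1e-15 & tr$occupancy <= 1 + 1e-12))
    }
  }
})

test_that("closed system keeps all occupancy in the well states", {
  p <- params_closed()
  tr <- run_cohort(p, "intervention", "male")
  ss <- tr$state_space
  well <- rowSums(tr$occupancy[, c(ss$i_smoke, ss$i_quit), drop = FALSE])
  expect_equal(well, rep(1, nrow(tr$occupancy)), tolerance = 1e-12)
})

test_that("certain mortality flushes the whole cohort in one cycle", {
  p <- params_no_disease()
  p <- set_flat_mortality(p, 1)
  tr <- run_cohort(p, "usual_care", "male")
  expect_equal(unname(tr$occupancy[2, "dead_other"]), 1)
  expect_equal(sum(tr$occupancy[nrow(tr$occupancy),
                                tr$state_space$i_dead]), 1)
})

test_that("well occupancy matches the geometric closed form exactly", {
  m <- 0.0173
  p <- params_no_disease()
  p <- set_flat_mortality(p, m)
  p$quit_rate$usual_care$male <- uncertain_value(0) # no flows at all
  tr <- run_cohort(p, "usual_care", "male")
  t_idx <- 0:(nrow(tr$occupancy) - 1)
  expect_equal(unname(tr$occupancy[, "well_smoking"]), (1 - m)^t_idx,
               tolerance = 1e-12)
})

test_that("QALY accumulation reproduces geometric discounting sums", {
  p <- params_closed()
  p$quit_rate$usual_care$male <- uncertain_value(0)
  p$utility$well_smoking <- uncertain_value(1)
  p$settings$start_age <- 90 # 10 cycles to age 100
  tr <- run_cohort(p, "usual_care", "male")
  r0 <- accumulate(tr, p, discount_rate = 0)
  expect_equal(r0$qalys, 10, tolerance = 1e-12)
  expect_equal(r0$life_years, 10, tolerance = 1e-12)
  r <- accumulate(tr, p, discount_rate = 0.035)
  expect_equal(r$qalys, sum(1.035^-(0:9)), tolerance = 1e-12)
  # cost side: programme cost only, charged undiscounted in the first cycle
  expect_equal(r$cost, p$costs$usual_care$total)
})

test_that("a no-risk toy model matches the hand closed form for dQALY", {
  # no disease, no mortality, no relapse, utility gain g for quitters:
  # dQALY over T undiscounted cycles = (q_i - q_u) * g * T
  p <- params_closed()
  g <- p$utility$well_quit$mean - p$utility$well_smoking$mean
  q_i <- p$quit_rate$intervention$male$mean
  q_u <- p$quit_rate$usual_care$male$mean
  cs <- compare_strategies(p, "male", discount_rate = 0)
  T_cycles <- p$settings$horizon_age - p$settings$start_age
  expect_equal(cs$delta_effect, (q_i - q_u) * g * T_cycles,
               tolerance = 1e-12)
  expect_equal(cs$delta_cost,
               p$costs$intervention$total - p$costs$usual_care$total)
})

test_that("the cohort model agrees with an independent microsimulation", {
  p <- default_parameters()
  start_age <- 60
  horizon <- 80
  n <- 1e5
  p$settings$horizon_age <- horizon
  tr <- run_cohort(p, "intervention", "male", start_age)
  expected <- collapse_trace(tr)
  got <- microsim_occupancy(p, "intervention", "male", start_age, horizon,
                            n = n, seed = 2024)
  for (col in colnames(expected)) {
    se <- sqrt(expected[, col] * (1 - expected[, col]) / n)
    expect_true(all(abs(got[, col] - expected[, col]) <= 4 * se + 1e-12),
                label = paste("microsim occupancy agreement:", col))
  }
})

test_that("monotonicity: quit rate raises dQALYs, discounting lowers QALYs", {
  p <- default_parameters()
  base <- compare_strategies(p, "male")
  up <- compare_strategies(param_set(p, "quit_rate.intervention.male", 0.45),
                           "male")
  expect_gt(up$delta_effect, base$delta_effect)
  hi_disc <- compare_strategies(p, "male", discount_rate = 0.07)
  expect_lt(hi_disc$by_strategy$qalys[1], base$by_strategy$qalys[1])
  no_disc <- compare_strategies(p, "male", discount_rate = 0)
  expect_gt(no_disc$delta_effect, base$delta_effect)
})

test_that("trace tidiers and accumulation metadata are coherent", {
  p <- default_parameters()
  tr <- run_cohort(p, "usual_care", "female", 55)
  td <- tidy(tr)
  expect_equal(nrow(td), nrow(tr$occupancy) * length(tr$states))
  expect_equal(sort(unique(td$age)), 55:100)
  res <- accumulate(tr, p)
  expect_s3_class(res, "cohort_result")
  expect_equal(res$strategy, "usual_care")
  expect_gt(res$life_years, res$qalys) # utilities below 1
  # half-cycle correction raises QALYs (occupancy declines over a cycle)
  res_hc <- accumulate(tr, p, half_cycle = TRUE)
  expect_gt(res_hc$qalys, res$qalys)
})
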