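test_that("degenerate PSA draws reproduce the base parameters exactly", {
  p <- params_all_fixed()
  set.seed(1)
  drawn <- draw_parameters(p)
  expect_equal(param_table(drawn), param_table(p))
})

test_that("parameter draws are seed-reproducible and recover Table means", {
  p <- default_parameters()
  set.seed(123)
  a <- draw_parameters(p)
  set.seed(123)
  b <- draw_parameters(p)
  expect_equal(param_table(a), param_table(b))

  set.seed(99)
  n <- 1e4
  rr <- draw_uncertain(p$cvd$rr_smoker, n)
  expect_lt(abs(mean(rr) - 1.42), 4 * 0.031 / sqrt(n))
  qr <- draw_uncertain(p$quit_rate$intervention$male, n)
  expect_lt(abs(mean(qr) - 0.352), 4 * 0.047 / sqrt(n))
})

test_that("curve perturbation keeps probabilities bounded and costs positive", {
  p <- default_parameters()
  set.seed(4)
  d <- draw_parameters(p, sample_curves = TRUE, curve_cv = 0.3)
  expect_true(all(d$curves$background_mortality$value >= 0 &
                  d$curves$background_mortality$value <= 1))
  expect_true(all(d$curves$cost_lc_first_year$value >= 0))
  expect_false(identical(d$curves$cvd_incidence$value,
                         p$curves$cvd_incidence$value))
})

test_that("the CEAC is the fraction of draws with positive net benefit", {
  draws <- tibble::tibble(delta_cost = c(100, -50, 200, 10),
                          delta_qaly = c(0.01, 0.02, -0.01, 0.005))
  # enumerate NMB signs at 20k: 100, 450, -400, 90 -> 3/4 positive
  expect_equal(ceac(draws, 20000)$prob_cost_effective, 0.75)
  # threshold-zero limit: fraction of cost-saving draws
  expect_equal(ceac(draws, 0)$prob_cost_effective,
               mean(draws$delta_cost < 0))
  pos <- dplyr::filter(draws, delta_qaly > 0)
  expect_equal(ceac(pos, 1e9)$prob_cost_effective, 1)
  # non-decreasing in the threshold when all dQALY >= 0
  curve <- ceac(pos, seq(0, 50000, 1000))
  expect_true(all(diff(curve$prob_cost_effective) >= 0))
  expect_error(ceac(draws[0, ], 20000), "draws")
})

test_that("a single all-fixed PSA repetition equals the deterministic base case", {
  p <- params_all_fixed()
  det <- compare_strategies(p, "male")
  psa <- run_psa(p, "male", n_reps = 1, seed = 42)
  expect_equal(psa$mean_delta_cost, det$delta_cost)
  expect_equal(psa$mean_delta_qaly, det$delta_effect)
  expect_equal(psa$n_excluded, 0)
})

test_that("PSA is reproducible and extending reps preserves earlier draws", {
  p <- default_parameters()
  a <- run_psa(p, "female", n_reps = 8, seed = 7)
  b <- run_psa(p, "female", n_reps = 8, seed = 7)
  expect_identical(a$draws, b$draws)
  expect_equal(a$seed, 7) # the seed is part of the result
  longer <- run_psa(p, "female", n_reps = 12, seed = 7)
  expect_equal(dplyr::slice_head(longer$draws, n = 8), a$draws)
  # CEAC at the configured threshold equals the headline probability
  at_wtp <- a$ceac$prob_cost_effective[a$ceac$threshold == a$wtp_threshold]
  expect_equal(a$prob_cost_effective, at_wtp)
  expect_true(all(a$ceac$prob_cost_effective >= 0 &
                  a$ceac$prob_cost_effective <= 1))
})

test_that("one-way analysis brackets the mean and touches nothing else", {
  p <- default_parameters()
  ow <- one_way(p, "cvd.rr_smoker", "male")
  expect_equal(ow$low_input, 1.42 - 2 * 0.031)
  expect_equal(ow$high_input, 1.42 + 2 * 0.031)
  expect_true(ow$low_input < 1.42 && ow$high_input > 1.42)
  # parameter without se: +-20% of the mean
  ow2 <- one_way(p, "lc.rr_smoker", "male")
  expect_equal(ow2$low_input, 1.771 * 0.8)
  expect_equal(ow2$high_input, 1.771 * 1.2)
  expect_error(one_way(p, "not.a.param", "male"), "unknown parameter")

  # the perturbed copy differs from base only in the target parameter
  p_low <- param_set(p, "cvd.rr_smoker", ow$low_input)
  tab_base <- param_table(p)
  tab_low <- param_table(p_low)
  other <- tab_base$id != "cvd.rr_smoker"
  expect_identical(tab_low[other, ], tab_base[other, ])
  expect_identical(p_low$curves, p$curves)
})

test_that("the scenario grid enumerates discount rates and start ages", {
  p <- default_parameters()
  sc <- run_scenarios(p)
  # 2 sexes x (base + 2 discount + 3 ages)
  expect_equal(nrow(sc), 12)
  expect_setequal(unique(sc$scenario),
                  c("base case", "0% discount rate", "5% discount rate",
                    "30-year-old cohort", "50-year-old cohort",
                    "60-year-old cohort"))
  for (s in c("male", "female")) {
    rows <- dplyr::filter(sc, sex == s)
    base_q <- rows$delta_qaly[rows$scenario == "base case"]
    undisc <- rows$delta_qaly[rows$scenario == "0% discount rate"]
    expect_gt(undisc, base_q) # discounting monotonicity
  }
})
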