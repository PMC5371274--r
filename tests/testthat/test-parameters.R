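test_that("uncertain_value enforces family-specific domains", {
  expect_s3_class(uncertain_value(0.5, 0.1, "beta"), "uncertain_value")
  expect_error(uncertain_value(1.2, 0.1, "beta"), "beta")
  expect_error(uncertain_value(-1, 0.1, "gamma"), "gamma")
  expect_error(uncertain_value(0, 0.1, "lognormal"), "lognormal")
  # zero se collapses to a fixed value; positive se forbids 'fixed'
  expect_equal(uncertain_value(0.3, 0, "beta")$family, "fixed")
  expect_error(uncertain_value(0.3, 0.1, "fixed"), "fixed")
})

test_that("method-of-moments fits recover closed-form parameterisations", {
  b <- fit_distribution(uncertain_value(0.5, 0.1, "beta"))
  expect_equal(c(b$shape1, b$shape2), c(12, 12))
  g <- fit_distribution(uncertain_value(100, 10, "gamma"))
  expect_equal(c(g$shape, g$scale), c(100, 1))
  f <- fit_distribution(uncertain_value(0.181))
  expect_equal(f$value, 0.181)
  expect_true(all(draw_uncertain(uncertain_value(0.181), 10) == 0.181))
  # lognormal natural-scale moments invert exactly
  ln <- fit_distribution(uncertain_value(1.42, 0.031, "lognormal"))
  m <- exp(ln$meanlog + ln$sdlog^2 / 2)
  v <- (exp(ln$sdlog^2) - 1) * exp(2 * ln$meanlog + ln$sdlog^2)
  expect_equal(m, 1.42)
  expect_equal(sqrt(v), 0.031)
  expect_error(fit_distribution(uncertain_value(0.5, 0.6, "beta")),
               "infeasible")
})

test_that("draws from every family match their (mean, se) moments", {
  set.seed(42)
  cases <- list(
    uncertain_value(0.5, 0.1, "beta"),
    uncertain_value(0.231, 0.02, "beta"),
    uncertain_value(100, 10, "gamma"),
    uncertain_value(1.42, 0.031, "lognormal"),
    uncertain_value(0.71, 0.036, "lognormal")
  )
  n <- 1e5
  for (uv in cases) {
    x <- draw_uncertain(uv, n)
    mc_se <- uv$se / sqrt(n)
    expect_lt(abs(mean(x) - uv$mean), 4 * mc_se)
    # sd of the sample sd is ~ se/sqrt(2n) for near-normal families
    expect_lt(abs(stats::sd(x) - uv$se), 6 * uv$se / sqrt(2 * n))
  }
})

test_that("composite CVD utility is the incidence-weighted mean", {
  expect_equal(composite_cvd_utility(), 0.611)
  comp <- default_cvd_utility_components()
  # order invariance and convexity bounds
  expect_equal(composite_cvd_utility(comp[sample(4), ]),
               composite_cvd_utility(comp))
  expect_gte(composite_cvd_utility(comp), min(comp$utility))
  expect_lte(composite_cvd_utility(comp), max(comp$utility))
  all_one <- dplyr::mutate(comp, utility = 1)
  expect_equal(composite_cvd_utility(all_one), 1)
  single <- tibble::tibble(condition = "chf", utility = 0.493, weight = 1)
  expect_equal(composite_cvd_utility(single), 0.493)
  bad <- dplyr::mutate(comp, weight = weight * 1.1)
  expect_error(composite_cvd_utility(bad), "sum to 1")
})

test_that("default configuration reproduces the published scalar inputs", {
  p <- default_parameters()
  expect_equal(p$cvd$rr_smoker$mean, 1.42)
  expect_equal(p$cvd$rr_smoker$se, 0.031)
  expect_equal(p$cvd$rr_exsmoker_vs_smoker$mean, 0.71)
  expect_equal(p$utility$well_smoking$mean, 0.800)
  expect_equal(p$utility$well_quit$mean, 0.830)
  expect_equal(p$utility$cvd$mean, 0.611)
  expect_equal(p$quit_rate$intervention$male$mean, 0.352)
  expect_equal(p$quit_rate$intervention$female$mean, 0.298)
  expect_equal(p$quit_rate$usual_care$male$mean, 0.242)
  expect_equal(p$quit_rate$usual_care$female$mean, 0.197)
  expect_equal(p$relapse$to_12mo$mean, 0.21)
  expect_equal(p$relapse$after_12mo_cumulative$mean, 0.30)
  expect_equal(p$lc$early_prop + p$lc$adv_prop, 1)
  # age-65 anchors on the generated curves
  expect_equal(curve_value(p$curves$background_mortality, 65, "male"), 0.01071)
  expect_equal(curve_value(p$curves$lc_incidence, 65, "female"), 0.00165)
  expect_equal(curve_value(p$curves$cvd_incidence, 65, "male"), 0.03095)
  expect_equal(curve_value(p$curves$cost_lc_first_year, 65, "male"), 23970)
  expect_equal(curve_value(p$curves$cost_cvd_terminal, 65, "female"), 11048)
})

test_that("invalid configurations are rejected with named errors", {
  p <- default_parameters()
  bad <- p
  bad$lc$early_prop <- 0.3
  bad$lc$adv_prop <- 0.8
  expect_error(validate_parameters(bad), "early_prop")
  bad2 <- p
  bad2$cvd$prehospital_fatality <- uncertain_value(1.5)
  expect_error(validate_parameters(bad2), "probability")
  # missing required key in a config file
  cfg <- yaml::read_yaml(system.file("extdata", "default-params.yaml",
                                     package = "quitcea"))
  cfg$cvd$rr_smoker <- NULL
  tmp <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, tmp)
  expect_error(load_parameters(tmp), "cvd.rr_smoker")
})

test_that("parameter sets round-trip through disk serialisation", {
  p <- default_parameters()
  dir <- withr::local_tempdir()
  write_parameters(p, dir)
  p2 <- load_parameters(dir)
  expect_equal(param_table(p2), param_table(p))
  for (nm in names(p$curves)) {
    expect_equal(p2$curves[[nm]]$value, p$curves[[nm]]$value,
                 tolerance = 1e-12, label = nm)
  }
  expect_equal(p2$settings$discount_rate, p$settings$discount_rate)
  expect_equal(p2$costs$intervention$total, p$costs$intervention$total)
})

test_that("curve lookup holds boundary values constant outside the range", {
  cv <- gen_age_curve("exponential", 65, 0.01, 0.09, sex = "male",
                      ages = 40:80)
  expect_equal(curve_value(cv, 30, "male"), curve_value(cv, 40, "male"))
  expect_equal(curve_value(cv, 95, "male"), curve_value(cv, 80, "male"))
  expect_error(curve_value(cv, 50, "female"), "sex")
})

test_that("param_get/param_set address scalars by dotted id", {
  p <- default_parameters()
  expect_equal(param_get(p, "quit_rate.usual_care.female")$mean, 0.197)
  expect_error(param_get(p, "no.such.param"), "unknown parameter")
  p2 <- param_set(p, "cvd.rr_smoker", 1.5)
  expect_equal(param_get(p2, "cvd.rr_smoker")$mean, 1.5)
  # base object untouched
  expect_equal(param_get(p, "cvd.rr_smoker")$mean, 1.42)
  tab <- param_table(p)
  expect_true(all(c("id", "mean", "se", "family") %in% names(tab)))
  expect_gt(nrow(tab), 10)
})
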