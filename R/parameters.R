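#' Uncertain model parameter
#'
#' An uncertain value couples a natural-scale mean with a standard error and a
#' sampling-distribution family, the form in which health-economic model
#' inputs are usually reported (mean and se per parameter, with beta used for
#' probabilities, gamma for costs and lognormal for relative risks).
#'
#' @param mean Natural-scale mean.
#' @param se Standard error on the natural scale; `0` (or `NULL`) means the
#'   parameter is treated as fixed.
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`. When
#'   `se` is zero the family is forced to `"fixed"`.
#'
#' @return An object of class `uncertain_value`.
#' @export
#' @examples
#' uncertain_value(1.42, 0.031, "lognormal")
#' uncertain_value(0.181) # fixed point value
uncertain_value <- function(mean, se = 0, family = "fixed") {
  if (is.null(se) || is.na(se)) se <- 0
  stopifnot(is.numeric(mean), length(mean) == 1L, is.finite(mean),
            is.numeric(se), length(se) == 1L, se >= 0)
  family <- match.arg(family, c("fixed", "beta", "gamma", "lognormal"))
  if (se == 0) family <- "fixed"
  if (family != "fixed" && se == 0) {
    stop("non-fixed family requires se > 0", call. = FALSE)
  }
  if (family == "fixed" && se > 0) {
    stop("family 'fixed' requires se = 0 (got se = ", se, ")", call. = FALSE)
  }
  if (family == "beta" && (mean <= 0 || mean >= 1)) {
    stop("beta family requires 0 < mean < 1 (got ", mean, ")", call. = FALSE)
  }
  if (family %in% c("gamma", "lognormal") && mean <= 0) {
    stop(family, " family requires mean > 0 (got ", mean, ")", call. = FALSE)
  }
  structure(list(mean = mean, se = se, family = family),
            class = "uncertain_value")
}

#' @export
print.uncertain_value <- function(x, ...) {
  cat(sprintf("<uncertain_value> %s(mean = %g, se = %g)\n",
              x$family, x$mean, x$se))
  invisible(x)
}

is_uncertain_value <- function(x) inherits(x, "uncertain_value")

#' Fit a sampling distribution to an uncertain value by method of moments
#'
#' Converts a `(mean, se)` pair into the parameterisation of its distribution
#' family so that the analytic mean and standard deviation of the fitted
#' distribution equal `mean` and `se` exactly:
#' * beta: `shape1 + shape2 = mean(1 - mean)/se^2 - 1`, `shape1 = mean * (shape1 + shape2)`;
#' * gamma: `shape = mean^2/se^2`, `scale = se^2/mean`;
#' * lognormal (natural-scale moments): `sdlog^2 = log(1 + (se/mean)^2)`,
#'   `meanlog = log(mean) - sdlog^2/2`;
#' * fixed: a degenerate point mass at `mean`.
#'
#' @param uv An [uncertain_value()].
#' @return A list with element `family` plus the family's natural parameters
#'   (`shape1`/`shape2`, `shape`/`scale`, `meanlog`/`sdlog`, or `value`).
#' @export
#' @examples
#' fit_distribution(uncertain_value(0.5, 0.1, "beta")) # shape1 = shape2 = 12
fit_distribution <- function(uv) {
  stopifnot(is_uncertain_value(uv))
  m <- uv$mean
  v <- uv$se^2
  switch(uv$family,
    fixed = list(family = "fixed", value = m),
    beta = {
      if (v >= m * (1 - m)) {
        stop("infeasible beta moments: se^2 = ", v, " >= mean(1-mean) = ",
             m * (1 - m), call. = FALSE)
      }
      nu <- m * (1 - m) / v - 1
      list(family = "beta", shape1 = m * nu, shape2 = (1 - m) * nu)
    },
    gamma = list(family = "gamma", shape = m^2 / v, scale = v / m),
    lognormal = {
      sdlog2 <- log(1 + v / m^2)
      list(family = "lognormal", meanlog = log(m) - sdlog2 / 2,
           sdlog = sqrt(sdlog2))
    }
  )
}

#' Draw random variates from an uncertain value
#'
#' Samples from the method-of-moments fit of [fit_distribution()]. Fixed
#' parameters return their mean for every draw.
#'
#' @param uv An [uncertain_value()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
draw_uncertain <- function(uv, n = 1L) {
  fit <- fit_distribution(uv)
  switch(fit$family,
    fixed = rep(fit$value, n),
    beta = stats::rbeta(n, fit$shape1, fit$shape2),
    gamma = stats::rgamma(n, shape = fit$shape, scale = fit$scale),
    lognormal = stats::rlnorm(n, fit$meanlog, fit$sdlog)
  )
}

#' Composite cardiovascular-disease utility
#'
#' The model uses a single utility for the CVD health state, formed as the
#' incidence-weighted mean of condition-specific EQ-5D utilities (coronary
#' artery disease, stroke, congestive heart failure, peripheral vascular
#' disease), each weighted by its share of CVD hospital admissions.
#'
#' @param components Data frame with columns `condition`, `utility`, `weight`
#'   (weights are proportions summing to 1). Defaults to
#'   [default_cvd_utility_components()].
#' @param digits Rounding applied to the reported composite (default 3,
#'   matching how such utilities are tabulated).
#' @return A single utility value.
#' @export
#' @examples
#' composite_cvd_utility() # 0.611
composite_cvd_utility <- function(components = default_cvd_utility_components(),
                                  digits = 3) {
  stopifnot(all(c("utility", "weight") %in% names(components)))
  w <- components$weight
  if (abs(sum(w) - 1) > 1e-3) {
    stop("CVD component weights must sum to 1 (got ", sum(w), ")",
         call. = FALSE)
  }
  round(sum(components$utility * w) / sum(w), digits)
}

#' Default CVD utility components
#'
#' Condition-specific utilities with hospital-admission incidence weights used
#' to build the composite CVD utility.
#'
#' @return A tibble with columns `condition`, `utility`, `weight`.
#' @export
default_cvd_utility_components <- function() {
  tibble::tibble(
    condition = c("coronary_artery_disease", "stroke",
                  "congestive_heart_failure", "peripheral_vascular_disease"),
    utility = c(0.629, 0.649, 0.493, 0.657),
    weight = c(0.549, 0.219, 0.176, 0.056)
  )
}

uv_from_config <- function(x, key) {
  if (is.null(x)) stop("missing required parameter: ", key, call. = FALSE)
  if (is.numeric(x) && length(x) == 1L) return(uncertain_value(x))
  if (is.null(x$mean)) stop("parameter '", key, "' has no mean", call. = FALSE)
  uncertain_value(x$mean, x$se %||% 0, x$family %||% "fixed")
}

uv_to_config <- function(uv) {
  if (uv$family == "fixed") {
    list(mean = uv$mean, family = "fixed")
  } else {
    list(mean = uv$mean, se = uv$se, family = uv$family)
  }
}

required_curves <- function() {
  c("background_mortality", "lc_incidence", "cvd_incidence",
    "cost_lc_first_year", "cost_lc_subsequent", "cost_lc_terminal",
    "cost_cvd_first_year", "cost_cvd_terminal")
}

#' Load model parameters from a configuration
#'
#' Reads the full lifetime-model parameter set: scalar parameters with
#' uncertainty (YAML), and one age-sex lookup curve per epidemiological or
#' cost input, either from CSV files (`age,sex,value`, one row per integer
#' age and sex) in a `curves/` directory next to the config, or generated
#' from the `curve_specs` section via [gen_age_curve()] when no files exist.
#'
#' @param config Path to a YAML configuration file, or a directory containing
#'   `params.yaml`. `NULL` loads the packaged default configuration, which
#'   reproduces the published parameter table.
#' @return A validated `model_parameters` object (see [validate_parameters()]).
#' @export
#' @examples
#' p <- load_parameters()
#' p$cvd$rr_smoker
load_parameters <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "default-params.yaml", package = "quitcea")
  }
  curves_dir <- NULL
  if (dir.exists(config)) {
    curves_dir <- file.path(config, "curves")
    config <- file.path(config, "params.yaml")
  }
  if (!file.exists(config)) {
    stop("configuration file not found: ", config, call. = FALSE)
  }
  cfg <- yaml::read_yaml(config)

  need <- function(section, key = NULL) {
    x <- cfg[[section]]
    if (is.null(x)) stop("missing required section: ", section, call. = FALSE)
    if (is.null(key)) return(x)
    if (is.null(x[[key]])) {
      stop("missing required key: ", section, ".", key, call. = FALSE)
    }
    x[[key]]
  }

  qr <- need("quit_rate")
  quit_rate <- purrr::map(
    c(intervention = "intervention", usual_care = "usual_care"),
    function(arm) purrr::imap(qr[[arm]],
      function(x, sex) uv_from_config(x, paste("quit_rate", arm, sex, sep = ".")))
  )

  comp_cfg <- cfg$cvd_utility_components
  components <- if (is.null(comp_cfg)) {
    default_cvd_utility_components()
  } else {
    dplyr::bind_rows(purrr::map(comp_cfg, tibble::as_tibble))
  }

  curves <- load_or_generate_curves(cfg, curves_dir)

  params <- structure(list(
    quit_rate = quit_rate,
    relapse = list(
      to_12mo = uv_from_config(need("relapse", "to_12mo"), "relapse.to_12mo"),
      after_12mo_cumulative = uv_from_config(
        need("relapse", "after_12mo_cumulative"),
        "relapse.after_12mo_cumulative"),
      years_after_12mo = need("relapse", "years_after_12mo")
    ),
    lc = list(
      early_prop = need("lc", "early_prop"),
      adv_prop = need("lc", "adv_prop"),
      rr_smoker = uv_from_config(need("lc", "rr_smoker"), "lc.rr_smoker"),
      rr_decay_years = need("lc", "rr_decay_years"),
      death_prob_early = need("lc", "death_prob_early"),
      death_prob_adv = need("lc", "death_prob_adv"),
      progression_early_to_adv = need("lc", "progression_early_to_adv")
    ),
    cvd = list(
      rr_smoker = uv_from_config(need("cvd", "rr_smoker"), "cvd.rr_smoker"),
      rr_exsmoker_vs_smoker = uv_from_config(
        need("cvd", "rr_exsmoker_vs_smoker"), "cvd.rr_exsmoker_vs_smoker"),
      prehospital_fatality = uv_from_config(
        need("cvd", "prehospital_fatality"), "cvd.prehospital_fatality"),
      fatality_28day = uv_from_config(
        need("cvd", "fatality_28day"), "cvd.fatality_28day")
    ),
    utility = list(
      well_smoking = uv_from_config(need("utility", "well_smoking"),
                                    "utility.well_smoking"),
      well_quit = uv_from_config(need("utility", "well_quit"),
                                 "utility.well_quit"),
      lc_early = uv_from_config(need("utility", "lc_early"),
                                "utility.lc_early"),
      lc_adv = uv_from_config(need("utility", "lc_adv"), "utility.lc_adv"),
      cvd = uncertain_value(composite_cvd_utility(components))
    ),
    cvd_utility_components = components,
    programme = need("programme"),
    settings = need("settings"),
    curves = curves
  ), class = "model_parameters")

  params$costs <- programme_costs(params$programme)
  validate_parameters(params)
}

load_or_generate_curves <- function(cfg, curves_dir) {
  names <- required_curves()
  if (!is.null(curves_dir) && dir.exists(curves_dir)) {
    curves <- purrr::map(rlang::set_names(names), function(nm) {
      f <- file.path(curves_dir, paste0(nm, ".csv"))
      if (!file.exists(f)) stop("missing curve file: ", f, call. = FALSE)
      read_age_curve(f)
    })
    return(curves)
  }
  specs <- cfg$curve_specs
  if (is.null(specs)) {
    stop("configuration has neither curve files nor curve_specs", call. = FALSE)
  }
  purrr::map(rlang::set_names(names), function(nm) {
    sp <- specs[[nm]]
    if (is.null(sp)) stop("missing curve spec: ", nm, call. = FALSE)
    dplyr::bind_rows(purrr::map(c("male", "female"), function(sex) {
      gen_age_curve(
        family = sp$family, anchor_age = sp$anchor_age,
        anchor_value = sp$anchor[[sex]], log_slope = sp$log_slope %||% 0,
        sex = sex, kind = sp$kind %||% "probability"
      )
    }))
  })
}

#' Read an age-sex lookup curve from a CSV file
#'
#' @param path CSV file with header `age,sex,value`; ages are literal integer
#'   years, `sex` is `male`/`female`.
#' @return A tibble with columns `age`, `sex`, `value`.
#' @export
read_age_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("age", "sex", "value"))) {
    stop("curve file must have header age,sex,value: ", path, call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Look up an age-sex curve value
#'
#' Ages outside the tabulated range hold the nearest tabulated value constant.
#'
#' @param curve Tibble with columns `age`, `sex`, `value`.
#' @param age Integer age(s) in years.
#' @param sex `"male"` or `"female"`.
#' @return Numeric vector of values, one per age.
#' @export
curve_value <- function(curve, age, sex) {
  sub <- curve[curve$sex == sex, ]
  if (nrow(sub) == 0L) stop("curve has no rows for sex: ", sex, call. = FALSE)
  sub <- sub[order(sub$age), ]
  age <- pmin(pmax(age, min(sub$age)), max(sub$age))
  idx <- match(age, sub$age)
  if (anyNA(idx)) {
    stop("curve does not cover ages: ",
         paste(unique(age[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  sub$value[idx]
}

programme_costs <- function(pr) {
  training_total <- pr$trainer_hours * pr$trainer_rate
  comps <- c(
    psp_training = amortise(training_total, pr$n_intervention),
    psp_salary = amortise(pr$psp_salary_total, pr$n_intervention),
    gp_visit = pr$gp_visit,
    pedometer = pr$pedometer,
    quitline = pr$quitline_per_participant
  )
  list(
    intervention = arm_cost_summary("intervention", comps),
    usual_care = arm_cost_summary(
      "usual_care", c(quitline = pr$quitline_per_participant))
  )
}

#' Validate a model-parameters object
#'
#' Checks the structural invariants of the parameter set: probabilities in
#' \[0, 1\], relative risks positive, cost curves non-negative, lung-cancer
#' stage proportions summing to 1, CVD utility weights summing to 1, and
#' curve coverage of the modelled age range.
#'
#' @param params A `model_parameters` object.
#' @return `params`, invisibly usable, after validation; errors describe the
#'   offending field.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "model_parameters"))
  probs <- c(
    purrr::map_dbl(params$quit_rate$intervention, "mean"),
    purrr::map_dbl(params$quit_rate$usual_care, "mean"),
    params$relapse$to_12mo$mean, params$relapse$after_12mo_cumulative$mean,
    params$cvd$prehospital_fatality$mean, params$cvd$fatality_28day$mean,
    params$lc$early_prop, params$lc$adv_prop,
    params$lc$death_prob_early, params$lc$death_prob_adv,
    params$lc$progression_early_to_adv
  )
  if (any(probs < 0 | probs > 1)) {
    stop("probability parameter outside [0, 1]", call. = FALSE)
  }
  if (abs(params$lc$early_prop + params$lc$adv_prop - 1) > 1e-9) {
    stop("lc.early_prop + lc.adv_prop must equal 1 (got ",
         params$lc$early_prop + params$lc$adv_prop, ")", call. = FALSE)
  }
  rrs <- c(params$lc$rr_smoker$mean, params$cvd$rr_smoker$mean,
           params$cvd$rr_exsmoker_vs_smoker$mean)
  if (any(rrs <= 0)) stop("relative risks must be > 0", call. = FALSE)
  utils_ <- purrr::map_dbl(params$utility, "mean")
  if (any(utils_ < -0.59 | utils_ > 1)) {
    stop("utility outside the EQ-5D range [-0.59, 1]", call. = FALSE)
  }
  if (abs(sum(params$cvd_utility_components$weight) - 1) > 1e-3) {
    stop("CVD utility component weights must sum to 1", call. = FALSE)
  }
  st <- params$settings
  for (nm in required_curves()) {
    cv <- params$curves[[nm]]
    if (is.null(cv)) stop("missing curve: ", nm, call. = FALSE)
    is_prob <- !startsWith(nm, "cost_")
    if (is_prob && any(cv$value < 0 | cv$value > 1)) {
      stop("curve ", nm, " has probabilities outside [0, 1]", call. = FALSE)
    }
    if (!is_prob && any(cv$value < 0)) {
      stop("curve ", nm, " has negative costs", call. = FALSE)
    }
    for (sex in c("male", "female")) {
      ages <- sort(cv$age[cv$sex == sex])
      span <- seq(st$start_age, st$horizon_age)
      # lookup holds end values constant, so only interior gaps are fatal
      interior <- span[span >= min(ages) & span <= max(ages)]
      missing <- setdiff(interior, ages)
      if (length(missing) > 0L) {
        stop("curve ", nm, " (", sex, ") missing ages: ",
             paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
      }
    }
  }
  if (st$discount_rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  params
}

#' Write a parameter set to disk
#'
#' Serialises a `model_parameters` object as `params.yaml` plus one
#' `curves/<name>.csv` per age-sex curve, the same layout [load_parameters()]
#' reads, so that a round trip reproduces the object.
#'
#' @param params A `model_parameters` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_parameters <- function(params, dir) {
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  cfg <- list(
    settings = params$settings,
    quit_rate = purrr::map(params$quit_rate,
                           function(arm) purrr::map(arm, uv_to_config)),
    relapse = list(
      to_12mo = uv_to_config(params$relapse$to_12mo),
      after_12mo_cumulative = uv_to_config(params$relapse$after_12mo_cumulative),
      years_after_12mo = params$relapse$years_after_12mo
    ),
    lc = list(
      early_prop = params$lc$early_prop,
      adv_prop = params$lc$adv_prop,
      rr_smoker = uv_to_config(params$lc$rr_smoker),
      rr_decay_years = params$lc$rr_decay_years,
      death_prob_early = params$lc$death_prob_early,
      death_prob_adv = params$lc$death_prob_adv,
      progression_early_to_adv = params$lc$progression_early_to_adv
    ),
    cvd = purrr::map(params$cvd, uv_to_config),
    utility = purrr::map(params$utility[c("well_smoking", "well_quit",
                                          "lc_early", "lc_adv")],
                         uv_to_config),
    cvd_utility_components = purrr::pmap(params$cvd_utility_components, list),
    programme = params$programme
  )
  yaml::write_yaml(cfg, file.path(dir, "params.yaml"))
  for (nm in names(params$curves)) {
    utils::write.csv(params$curves[[nm]],
                     file.path(dir, "curves", paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Default model parameters
#'
#' Loads the packaged default configuration: scalar parameters as published
#' (quit rates per arm and sex, relapse rates, disease relative risks,
#' fatality splits, utilities, programme costs) plus synthetic age-sex curves
#' anchored at the published age-65 example values (see [gen_age_curve()]).
#'
#' @return A `model_parameters` object.
#' @export
default_parameters <- function() load_parameters(NULL)

#' @export
print.model_parameters <- function(x, ...) {
  st <- x$settings
  cat("<model_parameters>\n")
  cat(sprintf("  cohort: ages %d-%d, discount %.1f%%, WTP NZ$%s/QALY\n",
              st$start_age, st$horizon_age, 100 * st$discount_rate,
              format(st$wtp_threshold, big.mark = ",")))
  cat(sprintf("  quit rates (intervention M/F): %.3f / %.3f; (usual care): %.3f / %.3f\n",
              x$quit_rate$intervention$male$mean,
              x$quit_rate$intervention$female$mean,
              x$quit_rate$usual_care$male$mean,
              x$quit_rate$usual_care$female$mean))
  cat(sprintf("  programme cost/participant: NZ$%.2f vs NZ$%.2f\n",
              x$costs$intervention$total, x$costs$usual_care$total))
  cat(sprintf("  curves: %s\n", paste(names(x$curves), collapse = ", ")))
  invisible(x)
}

# --- parameter registry -----------------------------------------------------

scalar_param_ids <- function() {
  c(
    "quit_rate.intervention.male", "quit_rate.intervention.female",
    "quit_rate.usual_care.male", "quit_rate.usual_care.female",
    "relapse.to_12mo", "relapse.after_12mo_cumulative",
    "lc.rr_smoker", "cvd.rr_smoker", "cvd.rr_exsmoker_vs_smoker",
    "cvd.prehospital_fatality", "cvd.fatality_28day",
    "utility.well_smoking", "utility.well_quit",
    "utility.lc_early", "utility.lc_adv", "utility.cvd"
  )
}

#' Enumerate the scalar model parameters
#'
#' Lists every scalar parameter reachable by a dotted identifier, with its
#' mean, standard error and distribution family. These identifiers drive
#' one-way sensitivity analysis and parameter overrides.
#'
#' @param params A `model_parameters` object.
#' @return A tibble with columns `id`, `mean`, `se`, `family`.
#' @export
param_table <- function(params) {
  dplyr::bind_rows(purrr::map(scalar_param_ids(), function(id) {
    uv <- param_get(params, id)
    tibble::tibble(id = id, mean = uv$mean, se = uv$se, family = uv$family)
  }))
}

#' Get or set a scalar parameter by dotted identifier
#'
#' @param params A `model_parameters` object.
#' @param id Dotted path, e.g. `"cvd.rr_smoker"` or
#'   `"quit_rate.intervention.male"` (see [param_table()]).
#' @param value For `param_set()`: a number (kept as a fixed value preserving
#'   the original family label for reporting) or an [uncertain_value()].
#' @return `param_get()` returns the [uncertain_value()]; `param_set()`
#'   returns a modified copy of `params`.
#' @export
param_get <- function(params, id) {
  node <- purrr::pluck(params, !!!strsplit(id, ".", fixed = TRUE)[[1]])
  if (is.null(node) || !is_uncertain_value(node)) {
    stop("unknown parameter id: ", id, call. = FALSE)
  }
  node
}

#' @rdname param_get
#' @export
param_set <- function(params, id, value) {
  path <- strsplit(id, ".", fixed = TRUE)[[1]]
  old <- param_get(params, id)
  if (is.numeric(value)) {
    value <- structure(list(mean = value, se = old$se, family = old$family),
                       class = "uncertain_value")
  }
  stopifnot(is_uncertain_value(value))
  purrr::pluck(params, !!!path) <- value
  params
}
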