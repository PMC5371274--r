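# Parameter-set variants used across tests. All start from the packaged
# defaults and overwrite specific pieces, so tests state exactly which
# assumption they switch off.

flat_curve <- function(value, ages = 0:100) {
  dplyr::bind_rows(
    gen_age_curve("flat", 65, value, sex = "male", kind = "cost", ages = ages),
    gen_age_curve("flat", 65, value, sex = "female", kind = "cost", ages = ages)
  )
}

# no disease: zero incidence for both diseases (mortality untouched)
params_no_disease <- function(p = default_parameters()) {
  p$curves$lc_incidence$value <- 0
  p$curves$cvd_incidence$value <- 0
  p
}

# closed-system variant: no disease, no background mortality, no relapse
params_closed <- function(p = default_parameters()) {
  p <- params_no_disease(p)
  p$curves$background_mortality$value <- 0
  p$relapse$to_12mo <- uncertain_value(0)
  p$relapse$after_12mo_cumulative <- uncertain_value(0)
  p
}

# replace every uncertain scalar by its fixed mean
params_all_fixed <- function(p = default_parameters()) {
  for (id in param_table(p)$id) {
    p <- param_set(p, id, uncertain_value(param_get(p, id)$mean))
  }
  p
}

set_flat_mortality <- function(p, m) {
  p$curves$background_mortality <- flat_curve(m)
  p
}
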