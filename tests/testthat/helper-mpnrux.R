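# shared fixtures: default parameters and a couple of synthetic patients
# (built once per test run; generation is cheap, fitting is not)

default_params <- mpn_params()

fig2_state <- disease_onset_state()

# a noiseless identifiable patient (both effects active, 6 points)
make_noiseless_patient <- function(seed = 42) {
  spec <- cohort_spec(noise_sd = 0, points_range = c(6, 6),
                      window_years_range = c(2, 4), seed = seed)
  set.seed(seed)
  generate_patient(spec, default_params, "noiseless", dose = 35)
}

# a patient with no stem-cell effect: dips then relapses late
make_relapse_patient <- function(seed = 3) {
  spec <- cohort_spec(noise_sd = 0.005, prob_sy0_zero = 1,
                      points_range = c(7, 7),
                      window_years_range = c(3.5, 4), seed = seed)
  set.seed(seed)
  generate_patient(spec, default_params, "relapse", dose = 35)
}
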