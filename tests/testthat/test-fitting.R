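test_that("rmse implements the stated score", {
  expect_equal(rmse(c(0.5, 0.4), c(0.4, 0.5)), 0.1)
  expect_equal(rmse(1:5 / 10, 1:5 / 10), 0)
  # invariant under permutation of paired points
  set.seed(1)
  o <- runif(6); pr <- runif(6)
  perm <- sample(6)
  expect_equal(rmse(o, pr), rmse(o[perm], pr[perm]))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:4), "lengths")
})

test_that("patient series constructor enforces the measurement contract", {
  s <- patient_series("p1", c(0, 30, 200), c(0.8, 0.6, 0.5), 35)
  expect_equal(s$m, 3L)
  expect_error(patient_series("p", c(10, 30), c(0.5, 0.4), 35), "time 0")
  expect_error(patient_series("p", c(0, 30, 30), c(0.5, 0.4, 0.3), 35),
               "increasing")
  expect_error(patient_series("p", c(0, 30), c(0.5, 1.4), 35), "\\[0, 1\\]")
  expect_error(patient_series("p", 0, 0.5, 35))
})

test_that("baseline anchoring reproduces the requested VAF and orders anchor times", {
  p <- default_params
  st <- baseline_state(0.5, p)
  expect_equal(vaf_readout(st[["x2"]], st[["y2"]]), 0.5, tolerance = 1e-6)
  # the model VAF passes 50% around year 30 of untreated progression
  expect_equal(attr(st, "onset_time_days") / 365, 30, tolerance = 0.05)
  # monotone: a later disease stage anchors later
  t_at <- function(v) attr(baseline_state(v, p), "onset_time_days")
  expect_true(t_at(0.3) < t_at(0.5) && t_at(0.5) < t_at(0.76) &&
                t_at(0.76) < t_at(0.9))
  expect_error(baseline_state(1.5, p), "inside")
  expect_error(baseline_state(0.999, p, horizon_years = 35), "unreachable")
})

test_that("prediction is anchored at the first observation and untreated prediction never declines", {
  p <- default_params
  s <- patient_series("p1", c(0, 100, 400, 900), c(0.6, 0.5, 0.4, 0.3), 35)
  pred0 <- predict_vaf(treatment_response(0, 0, 35), s, p)
  expect_equal(pred0[1], 0.6, tolerance = 1e-5)
  expect_true(all(diff(pred0) >= 0))  # untreated progression
  # a strong progenitor-only effect dips and then rises again
  pred_d <- predict_vaf(treatment_response(0, 0.5, 35), s, p,
                        times = seq(0, 4 * 365, by = 30))
  expect_lt(min(pred_d), 0.6 - 0.05)
  expect_gt(pred_d[length(pred_d)], min(pred_d) + 0.02)
})

test_that("noiseless synthetic patients are recovered to high accuracy", {
  pat <- make_noiseless_patient()
  fit <- fit_patient(pat$series, default_params, "both")
  expect_lt(abs(fit$rho_sy0 - pat$truth$rho_sy0) / pat$truth$rho_sy0, 0.01)
  expect_lt(abs(fit$rho_dy1 - pat$truth$rho_dy1) / pat$truth$rho_dy1, 0.01)
  expect_lt(fit$rmse, 1e-3)
})

test_that("relapsing series are classified as having no stem-cell effect", {
  pat <- make_relapse_patient()
  # generated with rho_sy0 = 0; series dips then rises late
  expect_identical(pat$truth$rho_sy0, 0)
  expect_gt(pat$series$vaf[pat$series$m], min(pat$series$vaf))
  fit <- fit_patient(pat$series, default_params, "both")
  expect_lt(fit$fold_sy0, 1.05)  # boundary optimum: effectively no effect
  expect_gt(fit$fold_dy1, 1.5)
})

test_that("the joint hypothesis dominates both restricted hypotheses", {
  for (pat in list(make_noiseless_patient(8), make_relapse_patient(9))) {
    fits <- fit_patient_all_modes(pat$series, default_params)
    expect_lte(fits$both$rmse,
               min(fits$sy0_only$rmse, fits$dy1_only$rmse) + 1e-9)
    expect_identical(fits$sy0_only$rho_dy1, 0)
    expect_identical(fits$dy1_only$rho_sy0, 0)
  }
})

test_that("approximate CIs are seed-reproducible and widen with noise", {
  p <- default_params
  fits <- list()
  for (ns in c(0.03, 0)) {
    spec <- cohort_spec(noise_sd = ns, points_range = c(6, 6),
                        window_years_range = c(2, 4), seed = 42)
    set.seed(42)
    pat <- generate_patient(spec, p, "ci", dose = 35)
    fit <- fit_patient(pat$series, p, "both")
    fits[[as.character(ns)]] <-
      approximate_ci(fit, p, n_samples = 300, seed = 11)
  }
  hi <- fits[["0.03"]]; lo <- fits[["0"]]
  expect_gt(hi$band_mean_width, 5 * lo$band_mean_width)
  expect_lt(lo$band_mean_width, 0.02)
  # same seed, same intervals and band
  again <- approximate_ci(fit_patient(
    local({
      spec <- cohort_spec(noise_sd = 0.03, points_range = c(6, 6),
                          window_years_range = c(2, 4), seed = 42)
      set.seed(42)
      generate_patient(spec, p, "ci", dose = 35)$series
    }), p, "both"), p, n_samples = 300, seed = 11)
  expect_identical(again$ci, hi$ci)
  expect_identical(again$band, hi$band)
  # truncated lower bounds never negative
  expect_true(all(hi$ci_reported[, 1] >= 0))
  expect_error(approximate_ci(
    fit_patient(patient_series("tiny", c(0, 60), c(0.7, 0.6), 35),
                default_params, "both"),
    default_params), "degrees of freedom")
})

test_that("cohort summary aggregates folds with outlier exclusion", {
  fake_fit <- function(id, fsy, fdy, rmse_val) {
    structure(list(patient_id = id, fold_sy0 = fsy, fold_dy1 = fdy,
                   rmse = rmse_val), class = "mpn_fit")
  }
  fits <- list(fake_fit("a", 2, 2, 0.01), fake_fit("b", 4, 4, 0.03))
  cs <- cohort_summary(fits)
  expect_equal(cs$fold_sy0$mean, 3)
  expect_equal(cs$fold_sy0$sd, sqrt(2))
  expect_equal(cs$n_rmse_le_002, 1L)
  expect_equal(cs$n_rmse_le_004, 2L)
  # an astronomical fold is excluded from that parameter's summary only
  fits2 <- c(fits, list(fake_fit("c", 3.19e6, 3, 0.02)))
  cs2 <- cohort_summary(fits2)
  expect_equal(cs2$fold_sy0$excluded, "c")
  expect_equal(cs2$fold_sy0$mean, 3)
  expect_equal(cs2$fold_dy1$mean, 3)
  expect_equal(cs2$fold_dy1$n, 3L)
  # all-identical folds: zero dispersion
  same <- list(fake_fit("a", 5, 5, 0.01), fake_fit("b", 5, 5, 0.01))
  expect_equal(cohort_summary(same)$fold_dy1$sd, 0)
})

test_that("patient series round-trip through the delimited format", {
  sl <- list(
    p1 = patient_series("p1", c(0, 40, 300), c(0.9, 0.7, 0.5), 35),
    p2 = patient_series("p2", c(0, 90), c(0.6, 0.2), 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_patient_series(sl, path)
  back <- read_patient_series(path)
  expect_equal(names(back), c("p1", "p2"))
  for (id in names(sl)) {
    expect_equal(back[[id]]$times, sl[[id]]$times)
    expect_equal(back[[id]]$vaf, sl[[id]]$vaf)
    expect_equal(back[[id]]$dose, sl[[id]]$dose)
  }
})
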