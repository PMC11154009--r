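test_that("cohort generation is exactly reproducible under its seed", {
  spec <- cohort_spec(n_patients = 4, seed = 123)
  c1 <- generate_cohort(spec, default_params)
  c2 <- generate_cohort(spec, default_params)
  expect_identical(c1$truth, c2$truth)
  for (id in names(c1$series)) {
    expect_identical(c1$series[[id]]$vaf, c2$series[[id]]$vaf)
    expect_identical(c1$series[[id]]$times, c2$series[[id]]$times)
  }
})

test_that("generated series satisfy the measurement contract by construction", {
  spec <- cohort_spec(n_patients = 8, seed = 21)
  cohort <- generate_cohort(spec, default_params)
  for (s in cohort$series) {
    expect_s3_class(s, "mpn_patient_series")
    expect_identical(s$times[1], 0)
    expect_true(all(diff(s$times) >= spec$min_gap_days - 1e-9))
    expect_true(all(s$vaf >= 0 & s$vaf <= 1))
    expect_true(s$m >= spec$points_range[1] && s$m <= spec$points_range[2])
    expect_lte(max(s$times), spec$window_years_range[2] * 365)
  }
  expect_true(all(cohort$truth$rho_sy0 >= 0 &
                    cohort$truth$rho_sy0 <= spec$rho_sy0_max))
  expect_true(all(cohort$truth$rho_dy1 >= spec$rho_dy1_range[1] &
                    cohort$truth$rho_dy1 <= spec$rho_dy1_range[2]))
  expect_true(all(cohort$truth$baseline_vaf > spec$baseline_range[1] &
                    cohort$truth$baseline_vaf < spec$baseline_range[2]))
})

test_that("noiseless series lie exactly on the model trajectory", {
  pat <- make_noiseless_patient(5)
  s <- pat$series
  pred <- predict_vaf(
    treatment_response(pat$truth$rho_sy0, pat$truth$rho_dy1, s$dose),
    s, default_params)
  expect_equal(s$vaf, pred, tolerance = 1e-5)
})

test_that("measurement noise has the specified dispersion", {
  # pool observed-minus-noiseless residuals across patients: the noiseless
  # curve is the model prediction at the stored ground truth
  p <- default_params
  sd_target <- 0.02
  spec <- cohort_spec(n_patients = 60, points_range = c(8, 8),
                      noise_sd = sd_target, seed = 31)
  cohort <- generate_cohort(spec, p)
  pooled <- lapply(seq_len(nrow(cohort$truth)), function(i) {
    s <- cohort$series[[i]]
    tru <- cohort$truth[i, ]
    clean <- predict_vaf(
      treatment_response(tru$rho_sy0, tru$rho_dy1, tru$dose), s, p)
    clean[1] <- tru$baseline_vaf
    data.frame(resid = s$vaf - clean, clean = clean)
  })
  pooled <- do.call(rbind, pooled)
  expect_gte(nrow(pooled), 450)
  # clipping at [0,1] affects only near-boundary points; drop them
  keep <- pooled$clean > 0.06 & pooled$clean < 0.94
  expect_equal(sd(pooled$resid[keep]), sd_target, tolerance = 0.1)
})

test_that("default cohort composition mirrors the two-trial design", {
  spec <- cohort_spec(seed = 77)
  cohort <- generate_cohort(spec, default_params)
  expect_equal(nrow(cohort$truth), 24L)
  expect_equal(sum(cohort$truth$dose == 35), 18L)
  expect_equal(sum(cohort$truth$dose == 20), 6L)
  # around a fifth of patients carry no stem-cell effect; their series
  # show a late VAF increase
  zero <- cohort$truth$rho_sy0 == 0
  expect_gte(sum(zero), 1L)
  rises_late <- vapply(cohort$series[zero], function(s) {
    s$vaf[s$m] > min(s$vaf) + 1e-12
  }, logical(1))
  expect_gte(mean(rises_late), 0.5)
})

test_that("cohort files round-trip losslessly", {
  dir <- withr::local_tempdir()
  spec <- cohort_spec(n_patients = 3, seed = 9)
  cohort <- generate_cohort(spec, default_params, dir = dir)
  back <- read_patient_series(file.path(dir, "patients.csv"))
  expect_equal(names(back), names(cohort$series))
  for (id in names(back)) {
    expect_equal(back[[id]]$vaf, cohort$series[[id]]$vaf)
    expect_equal(back[[id]]$times, cohort$series[[id]]$times)
  }
  truth_back <- read.csv(file.path(dir, "truth.csv"),
                         stringsAsFactors = FALSE)
  expect_equal(truth_back$rho_dy1, cohort$truth$rho_dy1)
  expect_equal(truth_back$rho_sy0, cohort$truth$rho_sy0)
})

test_that("noise degrades parameter recovery monotonically", {
  p <- default_params
  med_err <- vapply(c(0, 0.05), function(ns) {
    spec <- cohort_spec(n_patients = 6, points_range = c(6, 8),
                        window_years_range = c(2, 4), prob_sy0_zero = 1,
                        noise_sd = ns, seed = 13)
    cohort <- generate_cohort(spec, p)
    errs <- vapply(seq_along(cohort$series), function(i) {
      fit <- fit_patient(cohort$series[[i]], p, "dy1_only",
                         start_grid = c(0.01, 0.1, 1))
      abs(fit$rho_dy1 - cohort$truth$rho_dy1[i]) / cohort$truth$rho_dy1[i]
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_lt(med_err[1] * 2, med_err[2] + 1e-9)
})
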