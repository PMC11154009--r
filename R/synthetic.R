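#' Specification of a synthetic VAF cohort
#'
#' Describes an in-silico cohort with the statistical structure of sparse
#' clinical JAK2 VAF monitoring under constant-dose ruxolitinib: a few
#' measurements per patient over a window of a few years, baseline VAF
#' centred near 0.76, and additive homoscedastic Gaussian measurement noise
#' of the order reported for qPCR VAF assays. A fraction of patients
#' carries no stem-cell level drug effect (`rho_sy0 = 0`); their series
#' relapse after an initial dip.
#'
#' @param n_patients Number of patients (default 24).
#' @param doses Daily dose per patient, mg/day (default 18 patients at 35
#'   and 6 at 20, the myelofibrosis/polycythaemia-vera trial split);
#'   recycled to `n_patients`.
#' @param baseline_mean,baseline_sd Normal distribution of the baseline
#'   VAF, truncated to `baseline_range` (defaults 0.76, 0.12).
#' @param baseline_range Allowed baseline VAF interval (default (0.3, 0.98)).
#' @param points_range Measurements per patient, drawn uniformly in this
#'   integer range (default 3..8).
#' @param window_years_range Observation window length, uniform (default
#'   0.5..4 years).
#' @param min_gap_days Minimum spacing between visits (default 28).
#' @param prob_sy0_zero Probability that `rho_sy0` is exactly 0
#'   (default 0.2).
#' @param rho_sy0_meanlog,rho_sy0_sdlog Log-normal distribution of nonzero
#'   `rho_sy0`, truncated to `rho_sy0_max` (defaults log(0.6), 0.8, 5).
#' @param rho_dy1_meanlog,rho_dy1_sdlog Log-normal distribution of
#'   `rho_dy1`, truncated to `rho_dy1_range` (defaults log(0.13), 0.6,
#'   (0.01, 1.1)).
#' @param rho_sy0_max Upper truncation for `rho_sy0`.
#' @param rho_dy1_range Truncation interval for `rho_dy1`.
#' @param noise_sd Measurement noise standard deviation in VAF units
#'   (default 0.02).
#' @param seed Integer seed fixing the cohort exactly.
#' @return An object of class `mpn_cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 24,
                        doses = c(rep(35, 18), rep(20, 6)),
                        baseline_mean = 0.76, baseline_sd = 0.12,
                        baseline_range = c(0.3, 0.98),
                        points_range = c(3, 8),
                        window_years_range = c(0.5, 4),
                        min_gap_days = 28,
                        prob_sy0_zero = 0.2,
                        rho_sy0_meanlog = log(0.6), rho_sy0_sdlog = 0.8,
                        rho_sy0_max = 5,
                        rho_dy1_meanlog = log(0.13), rho_dy1_sdlog = 0.6,
                        rho_dy1_range = c(0.01, 1.1),
                        noise_sd = 0.02,
                        seed = 1L) {
  stopifnot(n_patients >= 1, all(doses > 0),
            baseline_range[1] > 0, baseline_range[2] < 1,
            points_range[1] >= 2, window_years_range[1] > 0,
            prob_sy0_zero >= 0, prob_sy0_zero <= 1,
            noise_sd >= 0, min_gap_days >= 0)
  structure(as.list(environment()), class = "mpn_cohort_spec")
}

rtrunc <- function(n, rfun, lower, upper) {
  out <- numeric(0)
  for (it in 1:1000) {
    draw <- rfun(n - length(out))
    out <- c(out, draw[draw >= lower & draw <= upper])
    if (length(out) >= n) return(out[seq_len(n)])
  }
  stop("truncated sampling failed to accept enough draws", call. = FALSE)
}

# visit schedule: first visit at day 0, the rest uniform over the window,
# resampled until all gaps respect the minimum spacing
draw_times <- function(m, window_days, min_gap) {
  if ((m - 1) * min_gap >= window_days) {
    return(seq(0, window_days, length.out = m))
  }
  for (it in 1:200) {
    tt <- c(0, sort(stats::runif(m - 1, 0, window_days)))
    if (all(diff(tt) >= min_gap)) return(tt)
  }
  seq(0, window_days, length.out = m)
}

#' Generate one synthetic patient
#'
#' Draws true response strengths and a baseline VAF from the cohort
#' specification, reconstructs the pre-treatment anchor state via
#' [baseline_state()], simulates the treated dynamics, samples the VAF at
#' the drawn visit times and adds clipped Gaussian measurement noise. The
#' returned ground truth enables parameter-recovery testing.
#'
#' @param spec An `mpn_cohort_spec`.
#' @param params An `mpn_params` object.
#' @param patient_id Identifier for the series.
#' @param dose Daily dose, mg/day.
#' @return List with `series` (an `mpn_patient_series`) and `truth`
#'   (data frame: `patient_id`, `rho_sy0`, `rho_dy1`, `baseline_vaf`,
#'   `dose`, `noise_sd`). Uses and advances R's RNG stream.
#' @export
generate_patient <- function(spec, params, patient_id = "p1",
                             dose = spec$doses[1]) {
  stopifnot(inherits(spec, "mpn_cohort_spec"), inherits(params, "mpn_params"))
  rho_sy0 <- if (stats::runif(1) < spec$prob_sy0_zero) 0 else {
    rtrunc(1, function(n) stats::rlnorm(n, spec$rho_sy0_meanlog,
                                        spec$rho_sy0_sdlog),
           0, spec$rho_sy0_max)
  }
  rho_dy1 <- rtrunc(1, function(n) stats::rlnorm(n, spec$rho_dy1_meanlog,
                                                 spec$rho_dy1_sdlog),
                    spec$rho_dy1_range[1], spec$rho_dy1_range[2])
  baseline <- rtrunc(1, function(n) stats::rnorm(n, spec$baseline_mean,
                                                 spec$baseline_sd),
                     spec$baseline_range[1], spec$baseline_range[2])
  m_choices <- seq.int(spec$points_range[1], spec$points_range[2])
  m <- m_choices[sample.int(length(m_choices), 1)]
  window <- stats::runif(1, spec$window_years_range[1],
                         spec$window_years_range[2]) * 365
  times <- draw_times(m, window, spec$min_gap_days)

  treat <- treatment_response(rho_sy0, rho_dy1, dose = dose)
  anchor <- baseline_state(baseline, params)
  clean <- predict_vaf(treat,
                       patient_series(patient_id, times,
                                      rep(baseline, m), dose),
                       params, anchor = anchor, times = times)
  clean[1] <- baseline
  noisy <- pmin(pmax(clean + stats::rnorm(m, 0, spec$noise_sd), 0), 1)
  list(series = patient_series(patient_id, times, noisy, dose),
       truth = data.frame(patient_id = as.character(patient_id),
                          rho_sy0 = rho_sy0, rho_dy1 = rho_dy1,
                          baseline_vaf = baseline, dose = dose,
                          noise_sd = spec$noise_sd,
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort
#'
#' `n_patients` independent draws of [generate_patient()] under the
#' cohort's fixed seed; optionally writes the series file (the fitting
#' input format) plus a ground-truth table.
#'
#' @param spec An `mpn_cohort_spec`.
#' @param params An `mpn_params` object.
#' @param dir Optional output directory; when given, writes
#'   `patients.csv` and `truth.csv` there.
#' @return List with `series` (named list of `mpn_patient_series`) and
#'   `truth` (data frame, one row per patient).
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_patients = 2, seed = 7),
#'                           mpn_params())
#' cohort$truth
#' }
#' @export
generate_cohort <- function(spec, params, dir = NULL) {
  stopifnot(inherits(spec, "mpn_cohort_spec"))
  set.seed(spec$seed)
  doses <- rep_len(spec$doses, spec$n_patients)
  ids <- sprintf("p%02d", seq_len(spec$n_patients))
  out <- lapply(seq_len(spec$n_patients), function(i) {
    generate_patient(spec, params, patient_id = ids[i], dose = doses[i])
  })
  series <- lapply(out, `[[`, "series")
  names(series) <- ids
  truth <- do.call(rbind, lapply(out, `[[`, "truth"))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_patient_series(series, file.path(dir, "patients.csv"))
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  list(series = series, truth = truth)
}
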