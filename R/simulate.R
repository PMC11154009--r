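#' Default initial state for disease-onset simulations
#'
#' The calibrated healthy steady state (approximately 1.0e5 stem, 2.5e6
#' progenitor, 6.4e11 mature cells, debris 8.1e2, cytokine 1) with a single
#' malignant stem cell seeded, the canonical starting point for simulating
#' disease development from one mutated cell.
#'
#' @return Named state vector of length 8.
#' @export
disease_onset_state <- function() {
  mpn_state(x0 = 1.0e5, x1 = 2.5e6, x2 = 6.4e11,
            y0 = 1, y1 = 0, y2 = 0,
            a = 8.1e2, s = 1)
}

#' Integrate the MPN model
#'
#' Stiff integration of the model from a given initial state. The debris and
#' cytokine compartments relax on time scales of fractions of a second while
#' the clonal competition plays out over decades: the system is stiff at all
#' times, so a BDF integrator (vode) with tight relative tolerance is used
#' throughout.
#'
#' @param initial Named non-negative state vector (see [mpn_state()]).
#' @param params An `mpn_params` object.
#' @param horizon_days Simulation horizon in days (> 0).
#' @param treat Optional `mpn_treatment`; when given, the integration uses
#'   [effective_parameters()] so that treatment acts purely through the two
#'   affected constants.
#' @param step_days Output sampling interval in days (default 7, i.e. weekly;
#'   internal solver steps are adaptive and unrelated).
#' @param times Optional explicit output times (days, starting at 0);
#'   overrides `step_days`.
#' @param rtol,atol Solver tolerances.
#' @param hmax Maximum internal step in days (default 50): near-constant
#'   stretches otherwise let the step grow until the stiff corrector fails.
#' @param hini Initial internal step in days (default 1e-6): the debris
#'   compartment relaxes within fractions of a second, so the automatic
#'   initial step can overshoot when the first output time is far away.
#' @return An `mpn_trajectory`: a data frame with columns `time_days`,
#'   `time_years`, the 8 state variables, and the VAF readout `vaf`
#'   (`NA` while no mature cells exist).
#' @examples
#' \donttest{
#' traj <- simulate_mpn(disease_onset_state(), mpn_params(),
#'                      horizon_days = 30 * 365)
#' tail(traj$vaf, 1)  # approximately 0.5 after 30 years
#' }
#' @export
simulate_mpn <- function(initial, params, horizon_days,
                         treat = NULL, step_days = 7, times = NULL,
                         rtol = 1e-8, atol = 1e-6, hmax = 50,
                         hini = 1e-6) {
  stopifnot(inherits(params, "mpn_params"))
  if (length(initial) != 8L || anyNA(initial) || any(!is.finite(initial))) {
    stop("initial state must be 8 finite components", call. = FALSE)
  }
  if (any(initial < 0)) {
    stop("initial state must be non-negative", call. = FALSE)
  }
  if (!is.null(treat)) {
    stopifnot(inherits(treat, "mpn_treatment"))
    params <- effective_parameters(params, treat)
  }
  if (is.null(times)) {
    if (!is.numeric(horizon_days) || horizon_days <= 0) {
      stop("horizon_days must be positive", call. = FALSE)
    }
    times <- unique(c(seq(0, horizon_days, by = step_days), horizon_days))
  }
  y <- stats::setNames(as.numeric(initial), mpn_state_names())
  out <- deSolve::ode(
    y = y, times = times, func = "mpn_derivs", parms = param_vector(params),
    dllname = "mpnrux", initfunc = "mpn_initmod",
    method = "vode", rtol = rtol, atol = atol, hmax = hmax, hini = hini,
    maxsteps = 50000
  )
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) {
    stop(sprintf("integration failed; last valid time %.6g days",
                 out[nrow(out), 1]), call. = FALSE)
  }
  as_trajectory(out)
}

as_trajectory <- function(out) {
  df <- as.data.frame(out)
  names(df)[1] <- "time_days"
  # solver tolerance can leave tiny negative counts; clamp for the readout
  state_cols <- mpn_state_names()
  for (cc in state_cols) df[[cc]] <- pmax(df[[cc]], 0)
  tot <- df$x2 + df$y2
  df$vaf <- ifelse(tot > 0, df$y2 / tot, NA_real_)
  df <- cbind(df[1], time_years = df$time_days / 365, df[-1])
  class(df) <- c("mpn_trajectory", "data.frame")
  df
}

#' @export
print.mpn_trajectory <- function(x, ...) {
  cat(sprintf("MPN trajectory: %d samples over %.2f years\n",
              nrow(x), max(x$time_years)))
  ts <- attr(x, "treatment_start_days")
  if (!is.null(ts)) cat(sprintf("  treatment starts at %.2f years\n", ts / 365))
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("  ...\n")
  invisible(x)
}

#' Integrate a single-lineage reduction of the model
#'
#' The 5-variable subsystem (stem, progenitor, mature cells of one lineage
#' plus debris and cytokine) obtained by deleting the other lineage's
#' equations. Integrating the reduction rather than the full system with
#' zeros is essential for long-horizon collapse experiments: carried-along
#' exact zeros expose the other clone's unstable directions to solver
#' round-off. The integration stops early (reporting the truncated
#' trajectory) if the lineage's total cell count falls below half a cell,
#' at which point the trivial equilibrium's basin has been entered.
#'
#' @param initial Named 5-vector `(n0, n1, n2, a, s)`, non-negative.
#' @param params An `mpn_params` object.
#' @param lineage `"healthy"` or `"malignant"`.
#' @param horizon_days Horizon in days.
#' @param step_days Output interval (default 365).
#' @inheritParams simulate_mpn
#' @return Data frame with `time_days` and the five state columns; fewer
#'   rows than requested when the collapse root stopped the run.
#' @export
simulate_lineage <- function(initial, params,
                             lineage = c("healthy", "malignant"),
                             horizon_days, step_days = 365,
                             rtol = 1e-8, atol = 1e-6, hmax = 50,
                             hini = 0) {
  lineage <- match.arg(lineage)
  stopifnot(inherits(params, "mpn_params"), length(initial) == 5L,
            all(is.finite(initial)), all(initial >= 0), horizon_days > 0)
  times <- unique(c(seq(0, horizon_days, by = step_days), horizon_days))
  nm <- c("n0", "n1", "n2", "a", "s")
  func <- if (lineage == "healthy") "mpn_derivs_healthy" else
    "mpn_derivs_malignant"
  # integrate chunk by chunk, checking the collapse condition at each
  # output time: once fewer than half a cell remains the trivial basin has
  # been entered, and integrating the vanishing tail only invites error-
  # test churn on the near-zero counts
  state <- stats::setNames(as.numeric(initial), nm)
  rows <- matrix(c(0, state), nrow = 1,
                 dimnames = list(NULL, c("time_days", nm)))
  collapsed <- sum(state[1:3]) < 0.5
  for (k in seq_len(length(times) - 1L)) {
    if (collapsed) break
    out <- deSolve::ode(
      y = state, times = times[c(k, k + 1L)],
      func = func, parms = param_vector(params),
      dllname = "mpnrux", initfunc = "mpn_initmod",
      method = "vode", rtol = rtol, atol = atol, hmax = hmax, hini = hini,
      maxsteps = 50000
    )
    if (attr(out, "istate")[1] < 0 || nrow(out) < 2L) {
      stop(sprintf("integration failed; last valid time %.6g days",
                   times[k]), call. = FALSE)
    }
    state <- out[2L, nm]
    rows <- rbind(rows, c(times[k + 1L], state))
    collapsed <- sum(pmax(state[1:3], 0)) < 0.5
  }
  df <- as.data.frame(rows)
  attr(df, "collapsed") <- collapsed
  df
}
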