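#' Specification of a treatment scenario experiment
#'
#' The canonical in-silico experiment: disease develops untreated from a
#' single malignant stem cell seeded into the calibrated healthy state for
#' `pre_treatment_years` (by which time the VAF has reached roughly 50%),
#' then therapy multiplies the affected constants. The four scenarios probe
#' the hypothesised drug mechanisms: (a) no effect, (b) only the malignant
#' stem-cell half-saturation constant `s_y0` is raised, (c) only the
#' malignant progenitor death rate `d_y1`, (d) both.
#'
#' @param scenario One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param pre_treatment_years Untreated disease development (default 30).
#' @param post_treatment_years On-treatment horizon (default 70).
#' @param fold_sy0,fold_dy1 Multiplicative factors (>= 1) applied at
#'   treatment start to `s_y0` and `d_y1` (default 6); the scenario decides
#'   which are active.
#' @param initial Initial state (default [disease_onset_state()]).
#' @return An object of class `mpn_scenario_spec`.
#' @export
scenario_spec <- function(scenario = c("a", "b", "c", "d"),
                          pre_treatment_years = 30,
                          post_treatment_years = 70,
                          fold_sy0 = 6, fold_dy1 = 6,
                          initial = disease_onset_state()) {
  scenario <- match.arg(scenario)
  stopifnot(pre_treatment_years > 0, post_treatment_years >= 0,
            fold_sy0 >= 1, fold_dy1 >= 1)
  structure(list(scenario = scenario,
                 pre_treatment_years = pre_treatment_years,
                 post_treatment_years = post_treatment_years,
                 fold_sy0 = fold_sy0, fold_dy1 = fold_dy1,
                 initial = initial),
            class = "mpn_scenario_spec")
}

#' Run a treatment scenario
#'
#' Simulates the untreated phase, then continues from its final state with
#' the scenario's parameter folds applied (internally expressed through the
#' dose-response map with unit dose, so the treated integration exercises
#' the same code path as patient fitting). Returns the stitched trajectory
#' with the treatment start time attached as attribute
#' `"treatment_start_days"`.
#'
#' @param spec An `mpn_scenario_spec`.
#' @param params An `mpn_params` object.
#' @param step_days Output sampling interval (default 7 days).
#' @return An `mpn_trajectory`.
#' @examples
#' \donttest{
#' traj <- run_scenario(scenario_spec("b", post_treatment_years = 10),
#'                      mpn_params())
#' }
#' @export
run_scenario <- function(spec, params, step_days = 7) {
  stopifnot(inherits(spec, "mpn_scenario_spec"), inherits(params, "mpn_params"))
  pre_days <- spec$pre_treatment_years * 365
  pre <- simulate_mpn(spec$initial, params, pre_days, step_days = step_days)
  folds <- switch(spec$scenario,
    a = c(sy0 = 1, dy1 = 1),
    b = c(sy0 = spec$fold_sy0, dy1 = 1),
    c = c(sy0 = 1, dy1 = spec$fold_dy1),
    d = c(sy0 = spec$fold_sy0, dy1 = spec$fold_dy1))
  treat <- treatment_response(rho_sy0 = folds[["sy0"]] - 1,
                              rho_dy1 = folds[["dy1"]] - 1,
                              dose = 1)
  if (spec$post_treatment_years > 0) {
    start_state <- as.numeric(pre[nrow(pre), mpn_state_names()])
    post <- simulate_mpn(pmax(start_state, 0), params,
                         spec$post_treatment_years * 365,
                         treat = treat, step_days = step_days)
    post$time_days <- post$time_days + pre_days
    post$time_years <- post$time_days / 365
    traj <- rbind(pre, post[-1, ])
  } else {
    traj <- pre
  }
  rownames(traj) <- NULL
  class(traj) <- c("mpn_trajectory", "data.frame")
  attr(traj, "treatment_start_days") <- pre_days
  attr(traj, "scenario") <- spec$scenario
  traj
}

#' Time for a quantity to return to its pre-treatment level
#'
#' Some treatment effects transiently worsen the disease: raising `s_y0`
#' alone pushes malignant stem cells towards differentiation, so mature
#' malignant counts and the VAF first overshoot before declining. This
#' measures the duration of that excursion: the first time after treatment
#' start at which the quantity, having first risen strictly above its level
#' at treatment start, crosses back down to that level (linear interpolation
#' between samples). Monotone-declining trajectories have no excursion and
#' return `NA`.
#'
#' @param traj An `mpn_trajectory` from [run_scenario()] (or any trajectory
#'   plus an explicit `reference_time`).
#' @param quantity `"mMBC"` (malignant mature cells, `y2`) or `"VAF"`.
#' @param reference_time Treatment start in days (default: the trajectory's
#'   `"treatment_start_days"` attribute).
#' @return Return time in days after treatment start, or `NA` if there is no
#'   excursion or no return within the horizon.
#' @export
time_to_return <- function(traj, quantity = c("mMBC", "VAF"),
                           reference_time = attr(traj, "treatment_start_days")) {
  quantity <- match.arg(quantity)
  if (is.null(reference_time)) {
    stop("reference_time missing and trajectory carries no treatment start",
         call. = FALSE)
  }
  tt <- traj$time_days
  v <- if (quantity == "mMBC") traj$y2 else traj$vaf
  if (quantity == "VAF" && anyNA(v[tt >= reference_time])) {
    stop("VAF undefined on part of the trajectory", call. = FALSE)
  }
  ref <- stats::approx(tt, v, xout = reference_time)$y
  post <- which(tt >= reference_time)
  above <- FALSE
  for (k in post[-1]) {
    if (!above && v[k] > ref) above <- TRUE
    if (above && v[k] <= ref) {
      # linear interpolation of the downward crossing
      t0 <- tt[k - 1]; t1 <- tt[k]
      v0 <- v[k - 1]; v1 <- v[k]
      tc <- if (v1 == v0) t1 else t0 + (ref - v0) * (t1 - t0) / (v1 - v0)
      return(tc - reference_time)
    }
  }
  NA_real_
}

#' Basin-of-attraction threshold of a single-lineage stable state
#'
#' Although the trivial (cell-free) equilibrium is locally stable, its
#' basin is minute: only when a lineage's three cell compartments are
#' simultaneously scaled far enough below their stable steady-state values
#' does the system collapse rather than regrow. This bisects the scale
#' factor `f`: initialise the lineage's compartments at `f` times the
#' stable single-lineage steady state (the other lineage absent; debris and
#' cytokine at their steady-state values), integrate a long horizon, and
#' classify the attractor by the final total cell count (fewer than one
#' cell counts as collapse to the trivial state).
#'
#' @param which `"healthy"` or `"malignant"`: which lineage's stable state
#'   to scale down.
#' @param params An `mpn_params` object.
#' @param horizon_years Classification horizon (default 200).
#' @param f_bracket Initial bracket for the scale factor.
#' @param rel_width Relative bisection width at which to stop (default
#'   1e-3).
#' @return The critical scale factor as a percentage, with attributes
#'   `iterations` and `bracket`.
#' @examples
#' \donttest{
#' basin_threshold("healthy", mpn_params())  # about 3.2 (percent)
#' }
#' @export
basin_threshold <- function(which = c("healthy", "malignant"), params,
                            horizon_years = 200,
                            f_bracket = c(1e-5, 1), rel_width = 1e-3) {
  which <- match.arg(which)
  stopifnot(inherits(params, "mpn_params"))
  ss <- if (which == "healthy") {
    reduced_healthy_steady_states(params)
  } else {
    find_steady_states(params)
  }
  ok <- ss$feasible & ss$label == which & ss$stability == "stable"
  if (!any(ok)) {
    stop(sprintf("no locally stable %s steady state under these parameters",
                 which), call. = FALSE)
  }
  # the larger state if several qualify
  row <- ss[ok, ][which.max(rowSums(ss[ok, c("x0", "y0")])), ]
  cells <- if (which == "healthy") c("x0", "x1", "x2") else c("y0", "y1", "y2")

  classify <- function(f) {
    init <- c(f * as.numeric(row[cells]), row$a, row$s)
    fin <- simulate_lineage(init, params, lineage = which,
                            horizon_days = horizon_years * 365)
    attr(fin, "collapsed") ||
      sum(fin[nrow(fin), c("n0", "n1", "n2")]) < 1
  }

  lo <- f_bracket[1]; hi <- f_bracket[2]
  if (!classify(lo) || classify(hi)) {
    stop("bracket failure: both endpoints classify identically", call. = FALSE)
  }
  it <- 0L
  while ((hi - lo) / lo > rel_width) {
    mid <- sqrt(lo * hi)  # log-scale bisection: thresholds span decades
    if (classify(mid)) lo <- mid else hi <- mid
    it <- it + 1L
    if (it > 60L) break
  }
  structure(100 * sqrt(lo * hi), iterations = it, bracket = c(lo, hi))
}

#' One-at-a-time local parameter sensitivity ranking
#'
#' Relative central-difference perturbation of each model constant,
#' normalised as `|d output / output| / |d parameter / parameter|`, sorted
#' descending. The default output is the VAF after 30 untreated years from
#' the disease-onset state; `"malignant_ss"` uses the malignant stem-cell
#' count of the stable malignant steady state. The self-renewal drivers
#' (`p_x0`, `p_y0`, then crowding and cytokine constants) dominate, since
#' realised stem-cell self-renewal sets each clone's fitness.
#'
#' @param params An `mpn_params` object.
#' @param output `"vaf30"` or `"malignant_ss"`.
#' @param rel_step Relative perturbation in (0, 0.1] (default 0.01).
#' @return A data frame with `parameter`, `sensitivity` (normalised),
#'   sorted descending; parameters whose perturbed run failed carry `NA`
#'   and a warning is raised.
#' @export
local_sensitivity <- function(params, output = c("vaf30", "malignant_ss"),
                              rel_step = 0.01) {
  output <- match.arg(output)
  stopifnot(inherits(params, "mpn_params"),
            rel_step > 0, rel_step <= 0.1)
  out_fun <- switch(output,
    vaf30 = function(p) {
      traj <- simulate_mpn(disease_onset_state(), p, 30 * 365,
                           step_days = 365)
      traj$vaf[nrow(traj)]
    },
    malignant_ss = function(p) {
      ss <- find_steady_states(p, stability = TRUE)
      ok <- ss$feasible & ss$label == "malignant" & ss$stability == "stable"
      if (!any(ok)) stop("no stable malignant state")
      max(ss$y0[ok])
    })
  base <- out_fun(params)
  sens <- vapply(mpn_param_names(), function(nm) {
    tryCatch({
      up <- params; up[[nm]] <- params[[nm]] * (1 + rel_step)
      dn <- params; dn[[nm]] <- params[[nm]] * (1 - rel_step)
      o_up <- out_fun(validate_params(up))
      o_dn <- out_fun(validate_params(dn))
      abs((o_up - o_dn) / base) / (2 * rel_step)
    }, error = function(e) {
      warning(sprintf("sensitivity of %s failed: %s", nm,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }, numeric(1))
  res <- data.frame(parameter = mpn_param_names(), sensitivity = sens,
                    row.names = NULL)
  res[order(-res$sensitivity), ]
}
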