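test_that("trajectories started in the non-negative orthant stay there", {
  p <- default_params
  set.seed(77)
  for (i in 1:6) {
    init <- mpn_state(x0 = runif(1, 0, 2e5), x1 = runif(1, 0, 5e6),
                      x2 = runif(1, 0, 1e12), y0 = runif(1, 0, 2e5),
                      y1 = runif(1, 0, 1e7), y2 = runif(1, 0, 3e12),
                      a = runif(1, 0, 2e3), s = runif(1, 0, 3))
    traj <- simulate_mpn(init, p, 10 * 365, step_days = 30)
    expect_true(all(as.matrix(traj[mpn_state_names()]) >= 0))
    expect_true(all(traj$vaf >= 0 & traj$vaf <= 1, na.rm = TRUE))
  }
})

test_that("trajectory bookkeeping: strictly increasing times, VAF series attached", {
  traj <- simulate_mpn(fig2_state, default_params, 365)
  expect_s3_class(traj, "mpn_trajectory")
  expect_true(all(diff(traj$time_days) > 0))
  expect_equal(traj$time_years, traj$time_days / 365)
  expect_equal(traj$vaf, traj$y2 / (traj$x2 + traj$y2))
  expect_error(simulate_mpn(rep(-1, 8), default_params, 10), "non-negative")
  expect_error(simulate_mpn(fig2_state, default_params, -5), "positive")
})

test_that("treatment with zero strengths reproduces the untreated trajectory exactly", {
  p <- default_params
  t1 <- simulate_mpn(fig2_state, p, 2 * 365)
  t2 <- simulate_mpn(fig2_state, p, 2 * 365,
                     treat = treatment_response(0, 0, 35))
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("scenario a is the untreated continuation", {
  p <- default_params
  spec <- scenario_spec("a", pre_treatment_years = 2,
                        post_treatment_years = 1)
  sc <- run_scenario(spec, p)
  expect_equal(attr(sc, "treatment_start_days"), 2 * 365)
  # piecewise restart is bit-identical to calling simulate on each leg
  pre <- simulate_mpn(fig2_state, p, 2 * 365)
  expect_identical(sc$x2[sc$time_days <= 2 * 365], pre$x2)
})

test_that("return-time detection interpolates the crossing and requires an excursion", {
  # synthetic triangular excursion with a hand-computed crossing time:
  # ref level 10 at t = 0, peak 20 at t = 100, linear back to 5 at t = 200;
  # crossing of 10 on the way down at t = 100 + 100 * (20-10)/(20-5)
  tt <- c(-50, 0, 100, 200)
  y2 <- c(10, 10, 20, 5)
  traj <- data.frame(time_days = tt, y2 = y2, x2 = 100 - y2)
  traj$vaf <- traj$y2 / 100
  expect_equal(time_to_return(traj, "mMBC", reference_time = 0),
               100 + 100 * (20 - 10) / (20 - 5))
  expect_equal(time_to_return(traj, "VAF", reference_time = 0),
               100 + 100 * (20 - 10) / (20 - 5))
  # monotone decline: no excursion, no return
  mono <- data.frame(time_days = 0:10, y2 = 10 - (0:10), x2 = rep(100, 11))
  mono$vaf <- mono$y2 / (mono$y2 + mono$x2)
  expect_true(is.na(time_to_return(mono, "mMBC", reference_time = 0)))
  # flat-at-reference does not count as an excursion either
  flat <- data.frame(time_days = 0:5, y2 = rep(3, 6), x2 = rep(7, 6))
  flat$vaf <- flat$y2 / 10
  expect_true(is.na(time_to_return(flat, "mMBC", reference_time = 0)))
})

test_that("single-lineage reduction agrees with the full system while the other lineage is empty", {
  p <- default_params
  init5 <- c(5e4, 1.2e6, 3e11, 600, 0.9)
  lin <- simulate_lineage(init5, p, "healthy", horizon_days = 3 * 365,
                          step_days = 365)
  full <- simulate_mpn(mpn_state(x0 = init5[1], x1 = init5[2],
                                 x2 = init5[3], a = init5[4], s = init5[5]),
                       p, 3 * 365, step_days = 365)
  expect_equal(lin$n0, full$x0[full$time_days %in% lin$time_days],
               tolerance = 1e-6)
  expect_equal(lin$n2, full$x2[full$time_days %in% lin$time_days],
               tolerance = 1e-6)
})

test_that("local sensitivity ranks the self-renewal drivers on top", {
  sens <- local_sensitivity(default_params)
  expect_setequal(sens$parameter[1:2], c("p_x0", "p_y0"))
  expect_true(all(c("c_xx", "c_yx", "alpha_y0", "s_x0") %in%
                    sens$parameter[1:6]))
  # a constant with no influence on the chosen output ranks at zero:
  # d_x2 does not enter the malignant-only stable state (x2 = 0 there)
  sens2 <- local_sensitivity(default_params, output = "malignant_ss")
  expect_lt(sens2$sensitivity[sens2$parameter == "d_x2"], 1e-10)
  expect_error(local_sensitivity(default_params, rel_step = 0.5), "rel_step")
})
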