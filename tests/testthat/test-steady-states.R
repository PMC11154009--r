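test_that("steady-state census finds 12 roots, 5 biologically feasible, labelled as in the model analysis", {
  ss <- find_steady_states(default_params)
  expect_equal(nrow(ss), 12L)
  expect_equal(sum(ss$feasible), 5L)
  feas <- ss[ss$feasible, ]
  expect_setequal(feas$label,
                  c("trivial", "healthy", "healthy", "malignant", "malignant"))

  trivial <- feas[feas$label == "trivial", ]
  expect_equal(trivial$s, default_params$I / default_params$e_s,
               tolerance = 1e-10)
  expect_equal(sum(trivial[c("x0", "x1", "x2", "y0", "y1", "y2", "a")]), 0)

  healthy <- feas[feas$label == "healthy", ]
  big_h <- healthy[which.max(healthy$x0), ]
  expect_equal(big_h$x0, 1.0e5, tolerance = 0.05)
  expect_equal(big_h$x1, 2.5e6, tolerance = 0.05)
  expect_equal(big_h$x2, 6.3e11, tolerance = 0.05)

  malignant <- feas[feas$label == "malignant", ]
  big_m <- malignant[which.max(malignant$y0), ]
  expect_equal(big_m$y0, 1.7e5, tolerance = 0.05)
  expect_equal(big_m$s, 2.0, tolerance = 0.05)
})

test_that("every feasible steady state is an equilibrium of the dynamics", {
  # oracle: direct evaluation of the right-hand side, independent of the
  # polynomial path that produced the roots
  ss <- find_steady_states(default_params)
  for (i in which(ss$feasible)) {
    st <- stats::setNames(as.numeric(ss[i, mpn_state_names()]),
                          mpn_state_names())
    f <- mpn_rhs(st, default_params)
    sc <- mpnrux:::rhs_flux_scale(st, default_params)
    expect_lt(max(abs(f) / pmax(sc, 1e-12)), 1e-6)
  }
})

test_that("stability pattern: trivial and large malignant stable, others unstable", {
  ss <- find_steady_states(default_params)
  feas <- ss[ss$feasible, ]
  stab <- function(label, pick = identity) {
    rows <- feas[feas$label == label, ]
    rows[order(rows$x0 + rows$y0), ]$stability
  }
  expect_equal(feas$stability[feas$label == "trivial"], "stable")
  expect_equal(stab("healthy"), c("unstable", "unstable"))
  expect_equal(stab("malignant"), c("unstable", "stable"))
})

test_that("trivial-state stability agrees with the analytic growth-rate signs", {
  p <- default_params
  s0 <- p$I / p$e_s
  trivial <- mpn_state(s = s0)
  cls <- classify_stability(trivial, p)
  # invasion eigenvalues of the two stem compartments have closed forms
  lam_x <- p$alpha_x0 * (2 * p$p_x0 * s0 / (p$s_x0 + s0) - 1)
  lam_y <- p$alpha_y0 * (2 * p$p_y0 * s0 / (p$s_y0 + s0) - 1)
  ev <- sort(Re(cls$eigenvalues))
  expect_true(any(abs(ev - lam_x) < 1e-8 * max(1, abs(lam_x))))
  expect_true(any(abs(ev - lam_y) < 1e-8 * max(1, abs(lam_y))))
  expect_lt(lam_x, 0)
  expect_lt(lam_y, 0)
  expect_equal(cls$stability, "stable")
})

test_that("healthy-only reduction keeps the healthy equilibria and stabilises the calibrated one", {
  rs <- reduced_healthy_steady_states(default_params)
  expect_equal(sum(rs$feasible), 3L)
  feas <- rs[rs$feasible, ]
  expect_setequal(feas$label, c("trivial", "healthy", "healthy"))
  big <- feas[which.max(feas$x0), ]
  expect_equal(big$stability, "stable")
  expect_equal(big$x0, 1.0e5, tolerance = 0.05)
  expect_equal(big$x1, 2.5e6, tolerance = 0.05)

  # component-wise match with the healthy rows of the full census
  full <- find_steady_states(default_params)
  fh <- full[full$feasible & full$label == "healthy", ]
  for (i in seq_len(nrow(feas[feas$label == "healthy", ]))) {
    row <- feas[feas$label == "healthy", ][i, ]
    match_row <- fh[which.min(abs(fh$x0 - row$x0)), ]
    expect_equal(as.numeric(row[mpn_state_names()]),
                 as.numeric(match_row[mpn_state_names()]),
                 tolerance = 1e-8)
  }
})

test_that("an independent multi-start root search finds no equilibria beyond the census", {
  skip_if_not_installed("pracma")
  p <- default_params
  ss <- find_steady_states(p)
  feas <- ss[ss$feasible, ]
  # search the healthy+none branch system in (x0, s) from random starts:
  # stem balance and debris balance must vanish simultaneously
  fun <- function(z) {
    x0 <- exp(z[1]); s <- exp(z[2])
    st <- mpn_state(x0 = x0,
                    x1 = 0, x2 = 0, a = max((p$e_s * s - p$I) / p$r_s, 0),
                    s = s)
    # complete the progenitor/mature levels from the linear balances
    Dx <- p$d_x1 - p$alpha_x1 * (2 * p$p_x1 - 1)
    x1 <- p$A_x0 * p$alpha_x0 * x0 / Dx
    x2 <- 2 * p$A_x1 * p$alpha_x1 * (1 - p$p_x1) * x1 / p$d_x2
    bal_stem <- 2 * p$p_x0 * crowding_phi("healthy", x0, 0, p) *
      s / (p$s_x0 + s) - 1
    a <- (p$e_s * s - p$I) / p$r_s
    bal_debris <- (p$d_x1 * x1 + p$d_x2 * x2 - p$e_a * a * s) /
      (p$e_a * max(a, 1e-12) * s)
    c(bal_stem, bal_debris)
  }
  set.seed(7)
  found <- NULL
  for (k in 1:50) {
    z0 <- c(log(10^runif(1, 0, 7)), log(10^runif(1, -4, 2)))
    sol <- tryCatch(
      suppressWarnings(pracma::fsolve(fun, z0, maxiter = 200)),
      error = function(e) NULL)
    if (is.null(sol) || max(abs(fun(sol$x))) > 1e-8) next
    found <- rbind(found, exp(sol$x))
  }
  expect_gt(nrow(found), 0)
  hx <- feas[feas$label == "healthy", ]
  for (i in seq_len(nrow(found))) {
    rel <- abs(outer(found[i, 1], hx$x0, "-")) / hx$x0
    expect_lt(min(rel), 1e-4)  # every converged root is a census root
  }
})
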