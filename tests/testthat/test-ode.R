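test_that("the sawtooth trajectory hits the documented landmarks", {
  inp <- effective_growth_inputs(0.3, 0.05, -0.5, 0.1, omega = 0.25,
                                 t_on = 4, t_off = 6)
  # full traversal from 0 takes exactly 1/omega on-drug days
  expect_equal(phenotype_trajectory(inp, 0, 1 / 0.25), 1)
  # short on-interval with t_off >= t_on returns to 0 after a full cycle
  inp2 <- effective_growth_inputs(0.3, 0.05, -0.5, 0.1, omega = 0.1,
                                  t_on = 3, t_off = 5)
  expect_equal(phenotype_trajectory(inp2, 0, 8), 0)
  expect_equal(phenotype_trajectory(inp2, 0, 3), 0.3)
})

test_that("the trajectory matches an explicit Euler integration", {
  set.seed(77)
  for (i in 1:4) {
    inp <- rand_inputs()
    e <- euler_trajectory(inp, 0, t_end = 3 * inp$tau, dt = 1e-3)
    idx <- seq(1, length(e$t), by = 37)
    x_pkg <- phenotype_trajectory(inp, 0, e$t[idx])
    expect_lt(max(abs(x_pkg - e$x[idx])), 5e-3)
  }
})

test_that("flat fitness gives the flat rate for any schedule", {
  set.seed(5)
  for (i in 1:5) {
    c0 <- runif(1, -0.5, 0.5)
    inp <- effective_growth_inputs(c0, c0, c0, c0,
                                   omega = runif(1, 0.05, 1),
                                   t_on = runif(1, 0.5, 10),
                                   t_off = runif(1, 0.5, 10))
    expect_equal(lambda_eff_numeric(inp), c0, tolerance = 1e-12)
    expect_equal(lambda_eff_closed_form(inp), c0, tolerance = 1e-12)
  }
})

test_that("quadrature agrees with a trapezoid oracle on random schedules", {
  set.seed(99)
  for (i in 1:12) {
    inp <- rand_inputs(equal_T = i %% 3 == 0)
    expect_equal(lambda_eff_numeric(inp), trapezoid_lambda(inp),
                 tolerance = 1e-6)
  }
})

test_that("closed form is continuous across its case boundaries", {
  set.seed(13)
  for (i in 1:20) {
    inp <- rand_inputs()
    w <- inp$omega
    eps <- 1e-9
    remake <- function(a, b) {
      effective_growth_inputs(inp$fm00, inp$fm10, inp$fm0D, inp$fm1D, w,
                              a, b)
    }
    # across the equal-interval manifold. From the t_on < t_off side the
    # limit cycle stays anchored at x = 0 and the limit is two-sided only
    # when both intervals exceed the traversal time; for t_on > t_off with
    # T < 1/omega the cycle re-anchors at x = 1 and the closed form has a
    # genuine one-sided jump, so only the continuous sides are asserted.
    T0 <- inp$t_on
    expect_equal(lambda_eff_closed_form(remake(T0, T0 + eps)),
                 lambda_eff_closed_form(remake(T0, T0)),
                 tolerance = 1e-6)
    if (T0 > 1 / w) {
      expect_equal(lambda_eff_closed_form(remake(T0 + eps, T0)),
                   lambda_eff_closed_form(remake(T0, T0)),
                   tolerance = 1e-6)
    }
    # across the full-traversal manifold at T = 1/omega
    expect_equal(lambda_eff_closed_form(remake(1 / w - eps, 1 / w - eps)),
                 lambda_eff_closed_form(remake(1 / w, 1 / w)),
                 tolerance = 1e-6)
    expect_equal(lambda_eff_closed_form(remake(1 / w + eps, 1 / w + eps)),
                 lambda_eff_closed_form(remake(1 / w, 1 / w)),
                 tolerance = 1e-6)
  }
})

test_that("effective rates are bounded by the corner rates", {
  set.seed(21)
  for (i in 1:50) {
    inp <- rand_inputs(equal_T = i %% 2 == 0)
    corners <- c(inp$fm00, inp$fm10, inp$fm0D, inp$fm1D)
    l <- lambda_eff_closed_form(inp)
    expect_gte(l, min(corners) - 1e-12)
    expect_lte(l, max(corners) + 1e-12)
  }
})

test_that("1:1 effective rates are non-decreasing in T beyond full traversal", {
  set.seed(31)
  for (i in 1:10) {
    base <- rand_inputs()
    w <- base$omega
    Ts <- seq(1 / w, 8 / w, length.out = 12)
    ls <- vapply(Ts, function(T) {
      lambda_eff_closed_form(
        effective_growth_inputs(base$fm00, base$fm10, base$fm0D,
                                base$fm1D, w, T, T))
    }, numeric(1))
    expect_true(all(diff(ls) >= -1e-12))
  }
})

test_that("continuous treatment is the vanishing-holiday limit", {
  inp <- effective_growth_inputs(0.3, 0.05, -0.5, 0.1, omega = 0.2,
                                 t_on = 9, t_off = 1e-9)
  expect_equal(continuous_rate(inp), 0.1)
  expect_equal(lambda_eff_closed_form(inp), 0.1, tolerance = 1e-6)
  expect_equal(lambda_eff_numeric(inp), 0.1, tolerance = 1e-6)
})

test_that("the critical 1:1 interval solves the tie with continuous dosing", {
  # synthetic corners: closed-form critical product is
  # (dFM0 - dFMD) / (2 (fm1D - fm00)) = 2.125
  inp <- effective_growth_inputs(0.3, 0.05, -0.5, 0.1, omega = 0.2,
                                 t_on = 1, t_off = 1)
  cs <- critical_schedule(inp)
  expect_equal(cs$status, "crossing")
  expect_equal(cs$T_omega, 2.125, tolerance = 1e-10)
  expect_equal(cs$T_eta, 21.25, tolerance = 1e-8)
  # the tie really is a tie, by the independent quadrature
  tie <- effective_growth_inputs(0.3, 0.05, -0.5, 0.1, 0.2,
                                 cs$T_crit, cs$T_crit)
  expect_equal(lambda_eff_numeric(tie), continuous_rate(tie),
               tolerance = 1e-9)

  # corners whose four-way mean equals FM(1, D): tie at exactly T = 1/omega
  inp2 <- effective_growth_inputs(0.2, 0, -0.5, -0.1, omega = 0.5,
                                  t_on = 1, t_off = 1)
  cs2 <- critical_schedule(inp2)
  expect_equal(cs2$T_crit, 1 / 0.5, tolerance = 1e-6)

  # always-better and always-worse regimes are classified, not solved
  ab <- critical_schedule(
    effective_growth_inputs(-0.2, -0.4, -0.5, 0.1, 0.5, 1, 1))
  expect_equal(ab$status, "always_better")   # (fm00 + fm1D)/2 < fm1D
  aw <- critical_schedule(
    effective_growth_inputs(0.5, 0.2, 0.3, 0.4, 0.5, 1, 1))
  expect_equal(aw$status, "always_worse")    # rapid switching already worse
})

test_that("ODE heatmaps classify cells consistently with the critical product", {
  fm <- make_two_dose_fm()
  hm <- schedule_heatmap(fm, 500, eta_grid = c(0.5, 1, 2, 4),
                         T_grid = c(1, 2, 4, 7, 14, 28), mode = "ode")
  for (i in seq_len(nrow(hm))) {
    inp <- eg_inputs_from_fm(fm, 500, omega = hm$eta[i] * fm$delta,
                             t_on = hm$T[i], t_off = hm$T[i])
    crit <- critical_schedule(inp, delta = fm$delta)
    want <- if (hm$T[i] * inp$omega < crit$T_omega) "intermittent_better"
            else if (hm$T[i] * inp$omega > crit$T_omega) "continuous_better"
            else "equal"
    expect_equal(hm$class[i], want)
  }
})

test_that("IBM heatmap mode matches the ODE mode within Monte-Carlo error", {
  # small-magnitude rates, where daily probabilities approximate
  # instantaneous rates well
  fm <- make_two_dose_fm(naive = c(0.010, -0.012),
                         adapted = c(0.002, 0.006), n = 19)
  hm_ode <- schedule_heatmap(fm, 500, eta_grid = 2, T_grid = c(4, 7),
                             mode = "ode")
  hm_ibm <- schedule_heatmap(fm, 500, eta_grid = 2, T_grid = c(4, 7),
                             mode = "ibm", n0 = 5000, n_runs = 12,
                             horizon = 56, seed = 60)
  expect_lt(max(abs(hm_ibm$lambda_eff - hm_ode$lambda_eff) /
                  pmax(2 * hm_ibm$se, 1e-4)), 1)
})
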