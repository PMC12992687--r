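test_that("schedules lay out doses and re-challenge days correctly", {
  s <- schedule_intermittent(500, 7, 7, 28)
  expect_equal(s$doses, rep(c(rep(500, 7), rep(0, 7)), 2))
  expect_equal(rechallenge_days(s), 15)
  d <- schedule_intermittent(500, 2, 3, 12, delay = 2)
  expect_equal(d$doses, c(0, 0, 500, 500, 0, 0, 0, 500, 500, 0, 0, 0))
  expect_equal(rechallenge_days(d), c(3, 8))
  expect_equal(schedule_continuous(300, 5)$doses, rep(300, 5))
  expect_equal(sum(schedule_none(10)$doses), 0)
})

test_that("update frequencies outside the declared set are rejected", {
  fm <- make_flat_fm(0)
  st <- update_strategy("none")
  expect_error(simulation_config(fm, st, eta_on = 0.3), "eta_on")
  expect_error(simulation_config(fm, st, eta_off = 11), "eta_off")
  expect_silent(simulation_config(fm, st, eta_on = 1 / 7, eta_off = 10))
})

test_that("fractional frequencies update every h-th day only", {
  expect_equal(vapply(1:10, function(d) phenadapt:::opportunities(1 / 3, d),
                      integer(1)),
               as.integer(1:10 %% 3 == 0))
  expect_equal(phenadapt:::opportunities(2, 5), 2L)
  expect_equal(phenadapt:::opportunities(0, 5), 0L)
})

test_that("zero fitness keeps counts constant for every strategy", {
  fm <- make_flat_fm(0)
  for (kind in c("none", "unbiased", "semibiased", "biased")) {
    cfg <- simulation_config(fm, update_strategy(kind), eta_on = 2,
                             eta_off = 2, n0 = 50, init = "uniform")
    r <- run_simulation(cfg, schedule_intermittent(500, 3, 4, 14), seed = 9)
    expect_true(all(r$data$count == 50))
  }
})

test_that("runs are bit-for-bit reproducible from the seed", {
  fm <- make_two_dose_fm()
  cfg <- simulation_config(fm, update_strategy("semibiased", 0.8),
                           eta_on = 2, eta_off = 1, n0 = 200,
                           init = "uniform")
  sch <- schedule_intermittent(500, 7, 7, 28)
  a <- run_simulation(cfg, sch, seed = 123)
  b <- run_simulation(cfg, sch, seed = 123)
  expect_identical(a$data, b$data)
  ens1 <- run_replicates(cfg, sch, n_runs = 5, seed = 7)
  ens2 <- run_replicates(cfg, sch, n_runs = 5, seed = 7)
  expect_identical(ens1$counts, ens2$counts)
})

test_that("daily bookkeeping identity holds and histograms sum to counts", {
  fm <- make_two_dose_fm()
  cfg <- simulation_config(fm, update_strategy("unbiased", 1), eta_on = 2,
                           eta_off = 2, n0 = 300, init = "uniform")
  r <- run_simulation(cfg, schedule_intermittent(500, 5, 3, 20), seed = 4)
  d <- r$data
  T_ <- nrow(d) - 1
  expect_equal(d$count_raw[2:(T_ + 1)],
               d$count_raw[1:T_] + d$births[1:T_] - d$deaths[1:T_])
  hist_cols <- grep("^state_", names(d))
  expect_equal(rowSums(d[, hist_cols]), d$count_raw, ignore_attr = TRUE)
  expect_equal(d$count, d$count_raw * d$scale)
})

test_that("a dose missing from the matrix fails before any event", {
  cfg <- simulation_config(make_two_dose_fm(), update_strategy("none"),
                           n0 = 10)
  expect_error(run_simulation(cfg, schedule_continuous(123, 5), seed = 1),
               "add_dose_loglinear")
})

test_that("biased updates keep a homogeneous population homogeneous", {
  fm <- make_two_dose_fm()
  cfg <- simulation_config(fm, update_strategy("biased"), eta_on = 2,
                           eta_off = 2, n0 = 400, init = "all_x0")
  r <- run_simulation(cfg, schedule_intermittent(500, 7, 7, 28), seed = 21)
  hist_cols <- grep("^state_", names(r$data))
  occupied <- rowSums(r$data[, hist_cols] > 0)
  expect_true(all(occupied[r$data$count_raw > 0] == 1))
})

test_that("without update opportunities the histogram is frozen", {
  fm <- make_flat_fm(0)   # no births/deaths either, so shape is exact
  for (kind in c("unbiased", "semibiased", "biased")) {
    cfg <- simulation_config(fm, update_strategy(kind), eta_on = 0,
                             eta_off = 0, n0 = 120, init = "uniform")
    r <- run_simulation(cfg, schedule_continuous(500, 10), seed = 2)
    hist_cols <- grep("^state_", names(r$data))
    h <- as.matrix(r$data[, hist_cols])
    expect_true(all(apply(h, 2, function(col) length(unique(col)) == 1)))
  }
})

test_that("seeding modes produce the documented histograms", {
  fm <- make_two_dose_fm()
  st <- update_strategy("biased")
  expect_equal(initial_distribution("all_x0", fm, st, 100),
               c(100, rep(0, 10)))
  expect_equal(initial_distribution("all_x1", fm, st, 100),
               c(rep(0, 10), 100))
  expect_equal(initial_distribution("uniform", fm, st, 11 * 7),
               rep(7, 11))
  expect_error(initial_distribution("bananas", fm, st, 10), "unknown")

  # drug-free burn-in with biased updates absorbs everyone at x = 0
  # once the burn-in exceeds the traversal time (n + 1) / eta_off
  set.seed(10)
  h <- initial_distribution("burn_in", fm, st, 100, eta_off = 1,
                            burn_in_days = 12)
  expect_equal(h[1], 100)
})

test_that("replicate summaries anchor at day 1 and are order-invariant", {
  fm <- make_two_dose_fm()
  cfg <- simulation_config(fm, update_strategy("biased"), eta_on = 2,
                           eta_off = 2, n0 = 100, init = "all_x0")
  sch <- schedule_continuous(500, 14)
  one <- run_replicates(cfg, sch, n_runs = 1, seed = 5)
  expect_true(all(one$summary$sd_norm == 0))
  expect_equal(one$summary$mean_norm[1], 1)

  ens <- run_replicates(cfg, sch, n_runs = 30, seed = 5)
  # summary statistics do not depend on replicate ordering
  perm <- sample(30)
  expect_equal(rowMeans(ens$norm[, perm]), ens$summary$mean_norm)
  expect_equal(apply(ens$norm[, perm], 1, sd), ens$summary$sd_norm)
})

test_that("growing ensembles track the branching expectation", {
  fm <- make_flat_fm(0.1)
  cfg <- simulation_config(fm, update_strategy("none"), n0 = 500,
                           init = "uniform")
  ens <- run_replicates(cfg, schedule_none(15), n_runs = 60, seed = 31)
  expected <- branching_expectation(1, 0.1, seq_len(16))
  err <- abs(ens$summary$mean_norm - expected)
  se <- ens$summary$sd_norm / sqrt(60)
  expect_true(all(err[-1] < 5 * se[-1]))
  expect_equal(err[1], 0)
})

test_that("the population cap keeps expected counts unbiased", {
  fm <- make_flat_fm(0.2)
  sch <- schedule_none(12)
  capped <- simulation_config(fm, update_strategy("none"), n0 = 400,
                              init = "all_x0", cap = 800)
  free <- simulation_config(fm, update_strategy("none"), n0 = 400,
                            init = "all_x0")
  e_cap <- run_replicates(capped, sch, n_runs = 150, seed = 8)
  e_free <- run_replicates(free, sch, n_runs = 150, seed = 9)
  final_cap <- e_cap$counts[13, ]
  final_free <- e_free$counts[13, ]
  expect_true(any(e_cap$counts != round(e_cap$counts)) ||
                max(e_cap$counts) <= 800 * 1.2)  # scaling happened
  se <- sqrt(var(final_cap) / 150 + var(final_free) / 150)
  expect_lt(abs(mean(final_cap) - mean(final_free)), 4 * se)
  expect_lt(abs(mean(final_cap) - 400 * 1.2^12), 5 * sd(final_cap) /
              sqrt(150))
})

test_that("effective growth rates follow the log-ratio definition", {
  fm <- make_flat_fm(0)
  cfg <- simulation_config(fm, update_strategy("none"), n0 = 100)
  r <- run_simulation(cfg, schedule_none(7), seed = 1)
  expect_equal(effective_growth_rate(r), 0)

  # hand-built doubling series
  r2 <- r
  r2$data$count[8] <- 200
  expect_equal(effective_growth_rate(r2, window = c(1, 8)), log(2) / 7)
  expect_error(effective_growth_rate(r, window = c(1, 40)), "window")

  # certain death: rate is -Inf and the ensemble reports extinction
  dead <- simulation_config(make_flat_fm(-1), update_strategy("none"),
                            n0 = 20)
  rd <- run_simulation(dead, schedule_none(3), seed = 2)
  expect_true(rd$extinct)
  expect_equal(effective_growth_rate(rd), -Inf)
  ens <- run_replicates(dead, schedule_none(3), n_runs = 4, seed = 3)
  expect_equal(effective_growth_rate(ens)$extinct_fraction, 1)
})

test_that("mean death events of directed strategies peak on the re-challenge day", {
  sch <- schedule_intermittent(500, 7, 7, 28)
  fitted <- list(
    semibiased = list(fm0 = -0.335, fm1 = 0.146, eta_on = 3, eta_off = 4),
    biased = list(fm0 = -0.268, fm1 = 0.171, eta_on = 1, eta_off = 3)
  )
  for (kind in names(fitted)) {
    pars <- fitted[[kind]]
    fm <- make_two_dose_fm(naive = c(0.3, pars$fm0),
                           adapted = c(0.05, pars$fm1))
    cfg <- simulation_config(fm, update_strategy(kind, 1),
                             eta_on = pars$eta_on, eta_off = pars$eta_off,
                             n0 = 1000, init = "all_x1")
    ens <- run_replicates(cfg, sch, n_runs = 100, seed = 500)
    mean_dpc <- ens$summary$mean_deaths_per_cell[1:28]
    expect_equal(which.max(mean_dpc), rechallenge_days(sch))
  }
})

test_that("delaying treatment of resistant cells beyond the traversal time helps", {
  fm <- make_two_dose_fm()
  cfg <- simulation_config(fm, update_strategy("biased"), eta_on = 1,
                           eta_off = 1, n0 = 200, init = "all_x1")
  horizon <- 40
  final_mean <- function(delay) {
    ens <- run_replicates(cfg,
                          schedule_intermittent(500, 1, 1, horizon, delay),
                          n_runs = 30, seed = 44)
    mean(ens$counts[horizon + 1, ])
  }
  # traversal time (n + 1) / eta_off = 10 days
  expect_lt(final_mean(10), final_mean(1))
})
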