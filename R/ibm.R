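eta_allowed <- function() sort(c(0:10, 1 / (2:10)))

check_eta <- function(eta, name) {
  if (length(eta) != 1 || !is.finite(eta) ||
      min(abs(eta - eta_allowed())) > 1e-9) {
    stop("`", name, "` must be an integer 0..10 or 1/h for integer h in ",
         "2..10, got ", eta, call. = FALSE)
  }
  eta
}

# Number of update opportunities on a given day. A fractional frequency 1/h
# means one opportunity every h-th day, first on day h.
opportunities <- function(eta, day) {
  if (eta >= 1) return(as.integer(round(eta)))
  if (eta == 0) return(0L)
  h <- as.integer(round(1 / eta))
  if (day %% h == 0) 1L else 0L
}

#' Configuration for the individual-based simulator
#'
#' Bundles everything a run needs besides the schedule: the fitness matrix,
#' the phenotype update strategy, the number of update opportunities per day
#' when the drug is on (`eta_on`) and off (`eta_off`), the seeded population
#' size and initial phenotype distribution, and the population cap. Update
#' frequencies may be integers 0..10 (that many opportunities per day) or
#' 1/h for integer h in 2..10 (one opportunity every h-th day, first on day
#' h).
#'
#' @param fm A [build_fitness_matrix()] object.
#' @param strategy An [update_strategy()].
#' @param eta_on,eta_off Update opportunities per day on drug-on / drug-off
#'   days.
#' @param n0 Initial cell count (>= 1).
#' @param init Initial phenotype distribution: `"all_x0"`, `"all_x1"`,
#'   `"uniform"` (deterministic stratified), `"burn_in"` (uniform seeding
#'   followed by `burn_in_days` drug-free days, then `n0` cells sampled from
#'   the resulting distribution), or an integer histogram over the S states.
#' @param cap Population cap; when the cell count exceeds it the population
#'   is down-sampled uniformly (multivariate hypergeometric across states)
#'   and a multiplicative scaling factor is tracked so reported counts stay
#'   unbiased.
#' @param burn_in_days Length of the drug-free burn-in when
#'   `init = "burn_in"`.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(fm, strategy, eta_on = 1, eta_off = 1,
                              n0 = 100, init = "all_x0", cap = 1e6,
                              burn_in_days = 28) {
  stopifnot(inherits(fm, "fitness_matrix"),
            inherits(strategy, "update_strategy"))
  check_eta(eta_on, "eta_on")
  check_eta(eta_off, "eta_off")
  if (n0 < 1 || n0 != round(n0)) stop("`n0` must be a positive integer",
                                      call. = FALSE)
  if (cap < n0) stop("`cap` must be >= `n0`", call. = FALSE)
  if (is.numeric(init)) {
    if (length(init) != length(fm$states) || any(init < 0) ||
        sum(init) != n0) {
      stop("numeric `init` must be a histogram over the ",
           length(fm$states), " states summing to n0", call. = FALSE)
    }
  } else if (!init %in% c("all_x0", "all_x1", "uniform", "burn_in")) {
    stop("unknown `init` mode: ", init, call. = FALSE)
  }
  structure(list(fm = fm, strategy = strategy, eta_on = eta_on,
                 eta_off = eta_off, n0 = as.integer(n0), init = init,
                 cap = cap, burn_in_days = burn_in_days),
            class = "simulation_config")
}

#' Initial phenotype histogram for seeding a simulation
#'
#' Builds the seeding histogram over the S lattice states for the modes
#' described in [simulation_config()]. The `"uniform"` mode is deterministic
#' stratified: each state gets `floor(n0 / S)` cells and the remainder goes
#' one cell each to the lowest states. The `"burn_in"` mode consumes random
#' numbers from the current stream.
#'
#' @param init Mode string or explicit histogram (see
#'   [simulation_config()]).
#' @param fm A `fitness_matrix`.
#' @param strategy An [update_strategy()] (used during burn-in).
#' @param n0 Number of cells to seed.
#' @param eta_off Drug-off update frequency used during burn-in.
#' @param burn_in_days Drug-free burn-in length in days.
#' @return Integer histogram of length S summing to `n0`.
#' @export
initial_distribution <- function(init, fm, strategy, n0, eta_off = 1,
                                 burn_in_days = 28) {
  S <- length(fm$states)
  if (is.numeric(init) && length(init) == S) return(as.integer(init))
  switch(init,
    all_x0 = {h <- integer(S); h[1] <- n0; h},
    all_x1 = {h <- integer(S); h[S] <- n0; h},
    uniform = {
      h <- rep(n0 %/% S, S)
      rem <- n0 - sum(h)
      if (rem > 0) h[seq_len(rem)] <- h[seq_len(rem)] + 1L
      as.integer(h)
    },
    burn_in = {
      seed_h <- initial_distribution("uniform", fm, strategy, n0)
      cfg <- simulation_config(fm, strategy, eta_on = eta_off,
                               eta_off = eta_off, n0 = n0, init = seed_h,
                               cap = 1e7)
      res <- sim_core(cfg, schedule_none(burn_in_days))
      final <- res$hist[, ncol(res$hist)]
      if (sum(final) == 0) stop("population went extinct during burn-in",
                                call. = FALSE)
      as.integer(stats::rmultinom(1, n0, final / sum(final)))
    },
    stop("unknown `init` mode: ", init, call. = FALSE)
  )
}

# Exact uniform down-sampling of a histogram to k cells (multivariate
# hypergeometric, state by state).
downsample_hist <- function(h, k) {
  out <- integer(length(h))
  rem <- k
  left <- sum(h)
  for (s in seq_along(h)) {
    if (rem == 0L) break
    left <- left - h[s]
    draw <- stats::rhyper(1, h[s], left, rem)
    out[s] <- draw
    rem <- rem - draw
  }
  out
}

# One birth/death pass over the histogram snapshot (daughters created here
# are not revisited within the pass).
step_birth_death <- function(h, g) {
  births <- integer(length(h))
  deaths <- integer(length(h))
  pos <- which(h > 0L & g > 0)
  neg <- which(h > 0L & g < 0)
  if (length(pos)) births[pos] <- stats::rbinom(length(pos), h[pos], g[pos])
  if (length(neg)) deaths[neg] <- stats::rbinom(length(neg), h[neg],
                                                -g[neg])
  list(h = h + births - deaths, births = sum(births), deaths = sum(deaths))
}

# One update opportunity for every cell (kernel rows: down/stay/up).
step_update <- function(h, kernel) {
  occ <- which(h > 0L)
  if (length(occ) == 0L) return(h)
  nh <- integer(length(h))
  for (s in occ) {
    p <- kernel[s, ]
    det <- which(p == 1)
    if (length(det) == 1L) {            # deterministic row, no draw needed
      tgt <- s + c(-1L, 0L, 1L)[det]
      nh[tgt] <- nh[tgt] + h[s]
    } else {
      m <- stats::rmultinom(1L, h[s], p)
      if (m[1L] > 0L) nh[s - 1L] <- nh[s - 1L] + m[1L]
      nh[s] <- nh[s] + m[2L]
      if (m[3L] > 0L) nh[s + 1L] <- nh[s + 1L] + m[3L]
    }
  }
  nh
}

# Core day loop. Uses the current RNG stream; returns plain vectors and the
# state-by-day histogram (columns 1..horizon+1, start-of-day populations).
sim_core <- function(config, schedule) {
  fm <- config$fm
  S <- length(fm$states)
  T_total <- schedule$horizon
  udoses <- unique(schedule$doses)
  jmap <- vapply(udoses, function(d) dose_col(fm, d), integer(1))
  gcols <- lapply(jmap, function(j) fm$values[, j])
  kernels <- lapply(jmap, function(j)
    transition_kernel(fm$values[, j], config$strategy))

  h <- initial_distribution(config$init, fm, config$strategy, config$n0,
                            eta_off = config$eta_off,
                            burn_in_days = config$burn_in_days)
  scale <- 1
  hist <- matrix(0L, S, T_total + 1L)
  count_raw <- births <- deaths <- numeric(T_total + 1L)
  scales <- numeric(T_total + 1L)
  capped <- logical(T_total + 1L)

  for (t in seq_len(T_total)) {
    hist[, t] <- h
    count_raw[t] <- sum(h)
    scales[t] <- scale
    d <- schedule$doses[t]
    u <- match(d, udoses)
    g <- gcols[[u]]
    kern <- kernels[[u]]
    eta <- if (d > 0) config$eta_on else config$eta_off
    k <- opportunities(eta, t)
    v <- stats::runif(1)
    if (sum(h) > 0L) {
      if (v < 0.5) {
        bd <- step_birth_death(h, g)
        h <- bd$h
        for (u in seq_len(k)) h <- step_update(h, kern)
      } else {
        for (u in seq_len(k)) h <- step_update(h, kern)
        bd <- step_birth_death(h, g)
        h <- bd$h
      }
      births[t] <- bd$births
      deaths[t] <- bd$deaths
    }
    if (sum(h) > config$cap) {
      scale <- scale * sum(h) / config$cap
      h <- downsample_hist(h, as.integer(config$cap))
      capped[t] <- TRUE
    }
  }
  hist[, T_total + 1L] <- h
  count_raw[T_total + 1L] <- sum(h)
  scales[T_total + 1L] <- scale
  list(hist = hist, count_raw = count_raw, births = births,
       deaths = deaths, scales = scales, capped = capped,
       count = count_raw * scales,
       extinct = sum(h) == 0L)
}

#' Run one stochastic simulation
#'
#' Simulates the daily loop: set the day's dose, then resolve cell
#' division/death and phenotype updates in random order (each order with
#' probability 0.5, probabilistic path branching). Division and death use the
#' fitness-matrix entry of each cell's state as a daily probability; updates
#' apply the configured kernel for the day's number of opportunities. Day
#' indexing is 1-based; the row for day t holds the population at the start
#' of day t, so row `horizon + 1` is the final population and
#' `count[t + 1] == count[t] + births[t] - deaths[t]` on uncapped days.
#'
#' @param config A [simulation_config()].
#' @param schedule A [schedule_continuous()]-family schedule.
#' @param seed Optional integer seed (runs are bit-reproducible given
#'   `config`, `schedule`, `seed`).
#' @return An `ibm_result`: a list with a tidy `data` tibble (columns `day`,
#'   `dose`, `count` (cap-corrected), `count_raw`, `norm_count`, `births`,
#'   `deaths`, `scale`, `capped`, `state_0` ..), and fields `extinct`,
#'   `horizon`.
#' @export
run_simulation <- function(config, schedule, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- sim_core(config, schedule)
  S <- length(config$fm$states)
  hist_t <- t(res$hist)
  colnames(hist_t) <- paste0("state_", 0:(S - 1L))
  data <- tibble::as_tibble(cbind(
    data.frame(day = seq_len(schedule$horizon + 1L),
               dose = c(schedule$doses, NA),
               count = res$count,
               count_raw = res$count_raw,
               norm_count = res$count / res$count[1L],
               births = res$births,
               deaths = res$deaths,
               scale = res$scales,
               capped = res$capped),
    hist_t
  ))
  structure(list(data = data, extinct = res$extinct,
                 horizon = schedule$horizon, schedule = schedule$spec,
                 n = config$fm$n, seed = seed),
            class = "ibm_result")
}

#' @export
print.ibm_result <- function(x, ...) {
  cat("IBM run (", x$schedule, "), ", x$horizon, " days, final count ",
      format(x$data$count[nrow(x$data)], digits = 6),
      if (x$extinct) " [extinct]", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.ibm_result <- function(x, ...) x$data

#' @export
glance.ibm_result <- function(x, ...) {
  tibble::tibble(
    horizon = x$horizon,
    final_count = x$data$count[nrow(x$data)],
    extinct = x$extinct,
    lambda_eff = effective_growth_rate(x)
  )
}

#' Run a replicate ensemble
#'
#' Runs `n_runs` independent simulations; replicate r uses a seed drawn from
#' a root-seeded stream, so the ensemble is reproducible from `seed` and
#' replicates are order-independent. Counts are normalised to each run's
#' day-1 count.
#'
#' @inheritParams run_simulation
#' @param n_runs Number of replicate runs (default 100).
#' @return An `ibm_ensemble`: per-day matrices of cap-corrected counts,
#'   births, deaths and deaths-per-cell (days by runs), the mean phenotype
#'   histogram, and a `summary` tibble (per-day mean/sd of normalised counts
#'   and deaths-per-cell).
#' @export
run_replicates <- function(config, schedule, n_runs = 100, seed = NULL) {
  stopifnot(n_runs >= 1)
  if (!is.null(seed)) set.seed(seed)
  run_seeds <- sample.int(.Machine$integer.max, n_runs)
  S <- length(config$fm$states)
  days <- schedule$horizon + 1L
  counts <- births <- deaths <- dpc <- matrix(0, days, n_runs)
  hist_mean <- matrix(0, S, days)
  extinct <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(run_seeds[r])
    res <- sim_core(config, schedule)
    counts[, r] <- res$count
    births[, r] <- res$births
    deaths[, r] <- res$deaths
    dpc[, r] <- ifelse(res$count_raw > 0, res$deaths / res$count_raw, 0)
    hist_mean <- hist_mean + res$hist
    extinct[r] <- res$extinct
  }
  hist_mean <- hist_mean / n_runs
  norm <- sweep(counts, 2, counts[1L, ], "/")
  sdv <- function(m) if (ncol(m) > 1) apply(m, 1, stats::sd) else
    rep(0, nrow(m))
  summary <- tibble::tibble(
    day = seq_len(days),
    mean_count = rowMeans(counts),
    mean_norm = rowMeans(norm),
    sd_norm = sdv(norm),
    mean_deaths_per_cell = rowMeans(dpc),
    sd_deaths_per_cell = sdv(dpc)
  )
  structure(list(counts = counts, norm = norm, births = births,
                 deaths = deaths, deaths_per_cell = dpc,
                 hist_mean = hist_mean, summary = summary,
                 extinct = extinct, n_runs = n_runs,
                 horizon = schedule$horizon, schedule = schedule$spec),
            class = "ibm_ensemble")
}

#' @export
print.ibm_ensemble <- function(x, ...) {
  cat("IBM ensemble: ", x$n_runs, " runs of ", x$schedule, " over ",
      x$horizon, " days (", sum(x$extinct), " extinct)\n", sep = "")
  invisible(x)
}

#' @export
tidy.ibm_ensemble <- function(x, ...) x$summary

#' @export
glance.ibm_ensemble <- function(x, ...) {
  eg <- effective_growth_rate(x)
  tibble::tibble(n_runs = x$n_runs, horizon = x$horizon,
                 final_mean_norm = x$summary$mean_norm[nrow(x$summary)],
                 lambda_eff = eg$lambda_eff,
                 extinct_fraction = eg$extinct_fraction)
}

#' Ensemble trajectory plot
#'
#' @param object An `ibm_ensemble`.
#' @param ... Unused.
#' @return A ggplot: mean normalised count with a +/- 1 sd ribbon.
#' @export
autoplot.ibm_ensemble <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$day, y = .data$mean_norm)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_norm - .data$sd_norm,
      ymax = .data$mean_norm + .data$sd_norm), alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = "normalised cell count",
                  title = object$schedule)
}

#' Effective growth rate of a run or ensemble
#'
#' The per-cell, per-day average net growth rate over a window:
#' `log(N_end / N_start) / (end - start)` on cap-corrected counts. For an
#' ensemble, per-run rates are averaged over non-extinct runs (a run whose
#' window-end count is 0 counts as extinct) and the extinct fraction is
#' reported alongside the Monte-Carlo standard error.
#'
#' @param x An `ibm_result` or `ibm_ensemble`.
#' @param window `c(start_day, end_day)` in 1..horizon+1; default the whole
#'   run.
#' @param ... Unused.
#' @return For a single run, a number (`-Inf` if extinct at window end).
#'   For an ensemble, a one-row tibble with `lambda_eff`, `sd`, `se`,
#'   `extinct_fraction`, `n_runs`.
#' @export
effective_growth_rate <- function(x, ...) {
  UseMethod("effective_growth_rate")
}

check_window <- function(window, horizon) {
  if (length(window) != 2 || window[1] < 1 || window[2] > horizon + 1 ||
      window[1] >= window[2]) {
    stop("`window` must be c(start, end) within 1..", horizon + 1,
         call. = FALSE)
  }
  window
}

#' @rdname effective_growth_rate
#' @export
effective_growth_rate.ibm_result <- function(x, window = c(1, x$horizon + 1),
                                             ...) {
  window <- check_window(window, x$horizon)
  n0 <- x$data$count[window[1]]
  n1 <- x$data$count[window[2]]
  if (n0 <= 0) stop("count at window start is not positive", call. = FALSE)
  if (n1 <= 0) return(-Inf)
  log(n1 / n0) / diff(window)
}

#' @rdname effective_growth_rate
#' @export
effective_growth_rate.ibm_ensemble <- function(x,
                                               window = c(1, x$horizon + 1),
                                               ...) {
  window <- check_window(window, x$horizon)
  n0 <- x$counts[window[1], ]
  n1 <- x$counts[window[2], ]
  if (any(n0 <= 0)) stop("count at window start is not positive in every ",
                         "run", call. = FALSE)
  alive <- n1 > 0
  rates <- log(n1[alive] / n0[alive]) / diff(window)
  tibble::tibble(
    lambda_eff = mean(rates),
    sd = if (sum(alive) > 1) stats::sd(rates) else 0,
    se = if (sum(alive) > 1) stats::sd(rates) / sqrt(sum(alive)) else 0,
    extinct_fraction = mean(!alive),
    n_runs = x$n_runs
  )
}
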