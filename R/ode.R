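#' Inputs for the effective-growth-rate theory
#'
#' Under the biased update strategy a homogeneous population stays
#' homogeneous, and in the continuum limit its common phenotype x(t) follows
#' a sawtooth: dx/dt = +omega while the drug is on and x < 1, -omega while
#' the drug is off and x > 0, and 0 at the clipped boundaries. The long-term
#' behaviour under a periodic schedule is then determined by the four
#' fitness-matrix corners, the adaptation speed omega (phenotype units per
#' day; omega = eta * Delta on a lattice with step Delta), and the on/off
#' durations.
#'
#' The theory presumes fitness increases with x on drug (`fm1D >= fm0D`) and
#' decreases with x off drug (`fm10 <= fm00`); violations are rejected.
#'
#' @param fm00,fm10 Per-day rates FM(0, 0) and FM(1, 0) (off-drug corners).
#' @param fm0D,fm1D Per-day rates FM(0, D) and FM(1, D) (on-drug corners at
#'   the scheduled dose D).
#' @param omega Adaptation speed (> 0, phenotype units per day).
#' @param t_on,t_off On/off durations per cycle in days (> 0; need not be
#'   integers for the theory).
#' @return An `eg_inputs` object with derived fields `tau`, `dFM0 = fm10 -
#'   fm00`, `dFMD = fm1D - fm0D`.
#' @export
#' @examples
#' effective_growth_inputs(0.3, 0.05, -0.5, 0.1, omega = 0.2,
#'                         t_on = 7, t_off = 7)
effective_growth_inputs <- function(fm00, fm10, fm0D, fm1D, omega,
                                    t_on, t_off) {
  vals <- c(fm00 = fm00, fm10 = fm10, fm0D = fm0D, fm1D = fm1D)
  if (any(!is.finite(vals))) stop("corner rates must be finite",
                                  call. = FALSE)
  if (!is.finite(omega) || omega <= 0) stop("`omega` must be > 0",
                                            call. = FALSE)
  if (t_on <= 0 || t_off <= 0) stop("`t_on` and `t_off` must be > 0",
                                    call. = FALSE)
  dFM0 <- fm10 - fm00
  dFMD <- fm1D - fm0D
  if (dFMD < 0 || dFM0 > 0) {
    stop("theory requires fitness non-decreasing in x on drug ",
         "(fm1D >= fm0D) and non-increasing off drug (fm10 <= fm00)",
         call. = FALSE)
  }
  structure(list(fm00 = fm00, fm10 = fm10, fm0D = fm0D, fm1D = fm1D,
                 omega = omega, t_on = t_on, t_off = t_off,
                 tau = t_on + t_off, dFM0 = dFM0, dFMD = dFMD),
            class = "eg_inputs")
}

#' Corner inputs taken from a fitness matrix
#'
#' @param fm A `fitness_matrix` whose grid contains dose 0 and `dose`.
#' @param dose The scheduled drug dose D (nM).
#' @inheritParams effective_growth_inputs
#' @return An `eg_inputs` object.
#' @export
eg_inputs_from_fm <- function(fm, dose, omega, t_on, t_off) {
  S <- nrow(fm$values)
  effective_growth_inputs(
    fm00 = fm$values[1L, dose_col(fm, 0)],
    fm10 = fm$values[S, dose_col(fm, 0)],
    fm0D = fm$values[1L, dose_col(fm, dose)],
    fm1D = fm$values[S, dose_col(fm, dose)],
    omega = omega, t_on = t_on, t_off = t_off
  )
}

# Map taking the phenotype at a cycle start to the next cycle start
# (drug-on phase first, both phases clipped to [0, 1]).
cycle_map <- function(x, inputs) {
  max(0, min(1, x + inputs$omega * inputs$t_on) -
        inputs$omega * inputs$t_off)
}

# Cycle-start phenotype on the limit cycle reached from x0.
limit_cycle_start <- function(inputs, x0 = 0) {
  x <- x0
  for (k in seq_len(1e6)) {
    xn <- cycle_map(x, inputs)
    if (abs(xn - x) < 1e-14) return(xn)
    x <- xn
  }
  x
}

#' Sawtooth phenotype trajectory
#'
#' Exact piecewise-linear solution of the clipped phenotype ODE, starting
#' drug-on at t = 0 from `x0`: slope +omega while on (until x = 1), -omega
#' while off (until x = 0).
#'
#' @param inputs An [effective_growth_inputs()] object.
#' @param x0 Initial phenotype in [0, 1].
#' @param t Time(s) >= 0 in days.
#' @return x(t), same length as `t`.
#' @export
phenotype_trajectory <- function(inputs, x0 = 0, t) {
  stopifnot(inherits(inputs, "eg_inputs"), x0 >= 0, x0 <= 1, all(t >= 0))
  tau <- inputs$tau
  k_needed <- floor(max(t) / tau)
  starts <- numeric(k_needed + 1L)
  starts[1L] <- x0
  if (k_needed >= 1) {
    for (k in seq_len(k_needed)) {
      starts[k + 1L] <- cycle_map(starts[k], inputs)
      if (k > 1 && abs(starts[k + 1L] - starts[k]) < 1e-15) {
        starts[(k + 1L):(k_needed + 1L)] <- starts[k + 1L]
        break
      }
    }
  }
  vapply(t, function(ti) {
    k <- floor(ti / tau)
    s <- ti - k * tau
    xs <- starts[k + 1L]
    if (s <= inputs$t_on) {
      min(1, xs + inputs$omega * s)
    } else {
      max(0, min(1, xs + inputs$omega * inputs$t_on) -
            inputs$omega * (s - inputs$t_on))
    }
  }, numeric(1))
}

# Integral of a linear-in-x fitness f0 + x * df along a clipped linear ramp
# from x_start with slope +/- omega over duration len.
ramp_integral <- function(x_start, sgn, omega, len, f0, df) {
  if (len <= 0) return(list(int = 0, x_end = x_start))
  bound <- if (sgn > 0) 1 else 0
  t_hit <- (bound - x_start) / (sgn * omega)
  t1 <- min(max(t_hit, 0), len)
  x_mid_end <- x_start + sgn * omega * t1
  int <- t1 * (2 * f0 + (x_start + x_mid_end) * df) / 2 +
    (len - t1) * (f0 + bound * df)
  x_end <- if (t1 < len) bound else x_mid_end
  list(int = int, x_end = x_end)
}

#' Effective growth rate by quadrature of the limit cycle
#'
#' Integrates the fitness along the exact sawtooth trajectory over one
#' period of the limit cycle reached from x(0) = 0 (drug-on phase first) and
#' divides by the cycle length. The integrands are piecewise linear, so the
#' quadrature is closed-form segment by segment; this routine is structurally
#' independent of [lambda_eff_closed_form()] and serves as its oracle.
#'
#' @param inputs An [effective_growth_inputs()] object.
#' @param x0 Starting phenotype from which the limit cycle is approached.
#' @return Per-day effective growth rate.
#' @export
lambda_eff_numeric <- function(inputs, x0 = 0) {
  stopifnot(inherits(inputs, "eg_inputs"))
  xs <- limit_cycle_start(inputs, x0)
  on <- ramp_integral(xs, +1, inputs$omega, inputs$t_on,
                      inputs$fm0D, inputs$dFMD)
  off <- ramp_integral(on$x_end, -1, inputs$omega, inputs$t_off,
                       inputs$fm00, inputs$dFM0)
  (on$int + off$int) / inputs$tau
}

#' Closed-form effective growth rate for periodic schedules
#'
#' Evaluates the six-case closed form for the long-term effective growth
#' rate of a homogeneous biased-update population under an on/off schedule,
#' on the limit cycle reached from the drug-naive state. The cases are
#' anchored at x = 1 when the off interval is the shorter one and at x = 0
#' when the on interval is, with dedicated expressions on the equal-interval
#' manifold (`t_on == t_off`) and full-traversal manifold
#' (`T * omega == 1`); in particular at `t_on == t_off == 1/omega` the rate
#' is exactly the arithmetic mean of the four corners.
#'
#' @inheritParams lambda_eff_numeric
#' @return Per-day effective growth rate.
#' @export
lambda_eff_closed_form <- function(inputs) {
  stopifnot(inherits(inputs, "eg_inputs"))
  w <- inputs$omega
  a <- inputs$t_on
  b <- inputs$t_off
  tau <- inputs$tau
  f00 <- inputs$fm00; f10 <- inputs$fm10
  f0D <- inputs$fm0D; f1D <- inputs$fm1D
  d0 <- inputs$dFM0; dD <- inputs$dFMD
  if (a == b) {
    Tw <- a * w
    if (Tw == 1) {
      (f00 + f0D + f10 + f1D) / 4
    } else if (Tw < 1) {
      w * a * (d0 + dD) / 4 + (f00 + f0D) / 2
    } else {
      (d0 - dD) / (4 * a * w) + (f00 + f1D) / 2
    }
  } else if (a < b && a <= 1 / w) {
    (w * a^2 * (d0 + dD) / 2 + a * f0D + b * f00) / tau
  } else if (b < a && b <= 1 / w) {
    (-w * b^2 * (d0 + dD) / 2 + a * f1D + b * f10) / tau
  } else {
    ((d0 - dD) / (2 * w) + a * f1D + b * f00) / tau
  }
}

#' Long-term rate under continuous treatment
#'
#' Continuously treated cells adapt once and stay at the drug-adapted
#' endpoint, so (ignoring the initial desensitisation transient) their
#' long-term effective growth rate is FM(1, D). It equals the t_off -> 0
#' limit of the intermittent closed form and is the comparison baseline for
#' schedule classification.
#'
#' @inheritParams lambda_eff_numeric
#' @return FM(1, D), per day.
#' @export
continuous_rate <- function(inputs) {
  stopifnot(inherits(inputs, "eg_inputs"))
  inputs$fm1D
}

#' Critical 1:1 interval where intermittent and continuous dosing tie
#'
#' For equal on/off intervals T, the effective growth rate is non-decreasing
#' in T (it interpolates from the rapid-switching average of the drug-naive
#' row towards the mixture of trapped corners), so intermittent dosing
#' outperforms continuous dosing exactly for T below a critical value. On
#' the T >= 1/omega branch the tie is closed-form:
#' \deqn{T\omega = (\Delta FM(0) - \Delta FM(D)) / (2 (FM(1,D) - FM(0,0))),}
#' otherwise the tie (if any) is bracketed on (0, 1/omega] and found by
#' root-finding on the quadrature oracle. Requires strict gradient signs
#' (`dFMD > 0`, `dFM0 < 0`).
#'
#' @param inputs An [effective_growth_inputs()] object; its `t_on`/`t_off`
#'   are ignored (the 1:1 interval is the unknown).
#' @param delta Lattice step used to convert omega to updates per day
#'   (`T_eta = T_omega / delta`). Default 0.1 (n = 9).
#' @return One-row tibble: `T_crit` (days), `T_omega`, `T_eta`, `status`
#'   (`"crossing"`, `"always_better"`, or `"always_worse"` for intermittent
#'   vs continuous; `T_*` are `NA` when there is no tie).
#' @export
critical_schedule <- function(inputs, delta = 0.1) {
  stopifnot(inherits(inputs, "eg_inputs"))
  if (inputs$dFMD <= 0 || inputs$dFM0 >= 0) {
    stop("critical-schedule analysis requires dFMD > 0 and dFM0 < 0",
         call. = FALSE)
  }
  w <- inputs$omega
  target <- continuous_rate(inputs)
  at_T <- function(T) {
    lambda_eff_closed_form(
      effective_growth_inputs(inputs$fm00, inputs$fm10, inputs$fm0D,
                              inputs$fm1D, w, T, T))
  }
  g_small <- (inputs$fm00 + inputs$fm0D) / 2 - target    # T -> 0 limit
  g_unit <- at_T(1 / w) - target                         # T = 1/omega
  g_inf <- (inputs$fm00 + inputs$fm1D) / 2 - target      # T -> infinity
  done <- function(T_crit, status) {
    tibble::tibble(T_crit = T_crit,
                   T_omega = T_crit * w,
                   T_eta = T_crit * w / delta,
                   status = status)
  }
  if (g_small >= 0) return(done(NA_real_, "always_worse"))
  if (g_unit >= 0) {
    root <- stats::uniroot(
      function(T) lambda_eff_numeric(
        effective_growth_inputs(inputs$fm00, inputs$fm10, inputs$fm0D,
                                inputs$fm1D, w, T, T)) - target,
      lower = 1e-9, upper = 1 / w, tol = 1e-12)
    return(done(root$root, "crossing"))
  }
  if (g_inf < 0) return(done(NA_real_, "always_better"))
  Tw <- (inputs$dFM0 - inputs$dFMD) / (2 * (target - inputs$fm00))
  done(Tw / w, "crossing")
}

#' Effective-growth-rate heatmap over (eta, T)
#'
#' Computes the 1:1 intermittent effective growth rate on a grid of update
#' frequencies eta (per day) and interval lengths T (days), either from the
#' closed form (`mode = "ode"`, with omega = eta * Delta) or from
#' biased-strategy IBM ensembles (`mode = "ibm"`), and classifies each cell
#' against the continuous baseline FM(1, D).
#'
#' @param fm A `fitness_matrix` containing dose 0 and `dose`.
#' @param dose Scheduled dose D (nM).
#' @param eta_grid Update frequencies per day (for `"ibm"` they must be in
#'   the frequency set of [simulation_config()]).
#' @param T_grid 1:1 interval lengths in days (integers for `"ibm"`).
#' @param mode `"ode"` (closed form) or `"ibm"` (stochastic ensembles).
#' @param init Initial condition for IBM runs (`"all_x0"` or `"all_x1"`).
#' @param n0,n_runs,horizon,delay,seed IBM ensemble options (8-week default
#'   horizon).
#' @param tol Equality tolerance for the ODE classification.
#' @return A tibble with columns `eta`, `T`, `lambda_eff`, `class`
#'   (`"intermittent_better"`, `"equal"`, `"continuous_better"`), and for
#'   IBM mode `se` and `extinct_fraction`.
#' @export
schedule_heatmap <- function(fm, dose, eta_grid, T_grid,
                             mode = c("ode", "ibm"), init = "all_x0",
                             n0 = 1e4, n_runs = 20, horizon = 56,
                             delay = 0, seed = NULL, tol = 1e-10) {
  mode <- match.arg(mode)
  grid <- tidyr::expand_grid(eta = eta_grid, T = T_grid)
  S <- nrow(fm$values)
  baseline <- fm$values[S, dose_col(fm, dose)]
  if (mode == "ode") {
    grid$lambda_eff <- purrr::pmap_dbl(grid, function(eta, T) {
      lambda_eff_closed_form(
        eg_inputs_from_fm(fm, dose, omega = eta * fm$delta,
                          t_on = T, t_off = T))
    })
    grid$class <- dplyr::case_when(
      abs(grid$lambda_eff - baseline) <= tol ~ "equal",
      grid$lambda_eff < baseline ~ "intermittent_better",
      TRUE ~ "continuous_better"
    )
  } else {
    if (!is.null(seed)) set.seed(seed)
    cell_seeds <- sample.int(.Machine$integer.max, nrow(grid))
    res <- purrr::pmap(
      list(grid$eta, grid$T, cell_seeds),
      function(eta, T, s) {
        cfg <- simulation_config(fm, update_strategy("biased"),
                                 eta_on = eta, eta_off = eta, n0 = n0,
                                 init = init)
        ens <- run_replicates(cfg,
                              schedule_intermittent(dose, T, T, horizon,
                                                    delay),
                              n_runs = n_runs, seed = s)
        effective_growth_rate(ens)
      })
    grid$lambda_eff <- purrr::map_dbl(res, "lambda_eff")
    grid$se <- purrr::map_dbl(res, "se")
    grid$extinct_fraction <- purrr::map_dbl(res, "extinct_fraction")
    grid$class <- dplyr::case_when(
      abs(grid$lambda_eff - baseline) <= 2 * grid$se ~ "equal",
      grid$lambda_eff < baseline ~ "intermittent_better",
      TRUE ~ "continuous_better"
    )
  }
  class(grid) <- c("pa_heatmap", class(grid))
  attr(grid, "baseline") <- baseline
  grid
}

#' @export
autoplot.pa_heatmap <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$T), y = factor(.data$eta),
                               fill = .data$lambda_eff)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = dplyr::filter(object,
                                             .data$class == "equal"),
                        shape = 4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "on/off interval T (days)",
                  y = "updates per day (eta)",
                  fill = "effective\ngrowth rate (/day)")
}
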