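# Shared fixtures and independent oracles.

# Flat fitness matrix: every state and dose has the same per-day rate.
make_flat_fm <- function(g, doses = c(0, 500), n = 9) {
  build_fitness_matrix(
    data.frame(dose_nM = doses, naive_rate = g, adapted_rate = g), n = n
  )
}

# Canonical two-dose matrix with the usual crossing structure: fitness
# decreases with x off drug and increases with x at 500 nM.
make_two_dose_fm <- function(naive = c(0.3, -0.5), adapted = c(0.05, 0.1),
                             n = 9) {
  build_fitness_matrix(
    data.frame(dose_nM = c(0, 500), naive_rate = naive,
               adapted_rate = adapted), n = n
  )
}

# Random effective-growth inputs honouring the gradient sign structure.
rand_inputs <- function(equal_T = FALSE, unit_Tw = FALSE) {
  fm10 <- stats::runif(1, -0.5, 0.5)
  fm00 <- fm10 + stats::runif(1, 0.01, 0.4)   # dFM0 < 0
  fm0D <- stats::runif(1, -0.9, 0)
  fm1D <- fm0D + stats::runif(1, 0.01, 0.6)   # dFMD > 0
  omega <- stats::runif(1, 0.05, 1.5)
  if (unit_Tw) {
    t_on <- t_off <- 1 / omega
  } else if (equal_T) {
    t_on <- t_off <- stats::runif(1, 0.2, 12)
  } else {
    t_on <- stats::runif(1, 0.2, 12)
    t_off <- stats::runif(1, 0.2, 12)
  }
  effective_growth_inputs(fm00, fm10, fm0D, fm1D, omega, t_on, t_off)
}

# Explicit-Euler integration of the clipped phenotype ODE (drug on first).
euler_trajectory <- function(inputs, x0, t_end, dt = 1e-4) {
  nt <- ceiling(t_end / dt)
  x <- numeric(nt + 1)
  x[1] <- x0
  tau <- inputs$tau
  for (i in seq_len(nt)) {
    ti <- (i - 1) * dt
    on <- (ti %% tau) < inputs$t_on
    dx <- if (on && x[i] < 1) inputs$omega else
      if (!on && x[i] > 0) -inputs$omega else 0
    x[i + 1] <- min(1, max(0, x[i] + dx * dt))
  }
  list(t = seq(0, by = dt, length.out = nt + 1), x = x)
}

# Trapezoid quadrature of the fitness along a late (converged) cycle of the
# trajectory; independent of the segment quadrature in the package.
trapezoid_lambda <- function(inputs, x0 = 0, npts = 20001) {
  k <- min(2000, 2 + ceiling(1 / (inputs$omega *
                                    max(abs(inputs$t_on - inputs$t_off),
                                        1e-3))))
  t0 <- k * inputs$tau
  trap <- function(t_from, t_to, f0, df) {
    ts <- seq(t_from, t_to, length.out = npts)
    xs <- phenotype_trajectory(inputs, x0, ts)
    fs <- f0 + xs * df
    sum((fs[-1] + fs[-npts]) / 2 * diff(ts))
  }
  on_int <- trap(t0, t0 + inputs$t_on, inputs$fm0D, inputs$dFMD)
  off_int <- trap(t0 + inputs$t_on, t0 + inputs$tau, inputs$fm00,
                  inputs$dFM0)
  (on_int + off_int) / inputs$tau
}

# Branching-process expectation for a constant daily net rate g: the count
# recorded at the start of day d is N0 * (1 + g)^(d - 1).
branching_expectation <- function(n0, g, day) n0 * (1 + g)^(day - 1)
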