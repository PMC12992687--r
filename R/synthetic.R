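#' Parameters for the synthetic dose-response generator
#'
#' Defines two Hill-type dose-response curves of per-day net growth rate —
#' one for drug-naive cells, one for drug-adapted (pre-incubated) cells —
#' on the standard twelve-dose challenge grid, plus the replicate layout and
#' noise level of the emulated assay. The defaults encode the qualitative
#' structure of the real system: naive cells grow faster off drug, adapted
#' cells grow faster at and above the 500 nM pre-incubation dose (so the
#' fitness gradient changes sign across the dose grid), all rates within
#' [-1, 1], four replicates per (dose, week), and a per-day reference rate
#' of 0.1059 for the 500 nM-treated reference condition.
#'
#' @param dose_grid Challenge doses in nM; default [pa_dose_grid()].
#' @param naive,adapted Named lists `list(top, bottom, ec50, hill)` for the
#'   two curves; the rate at dose d is
#'   `bottom + (top - bottom) / (1 + (d / ec50)^hill)`.
#' @param reference_rate Per-day rate of the reference (500 nM, 7-day)
#'   condition used in the fold-change conversion.
#' @param replicates Replicates per (dose, week); default 4.
#' @param sigma Multiplicative lognormal noise sd on fold changes.
#' @param preincubation_dose Dose (nM) at and above which the adapted curve
#'   must dominate the naive one.
#' @return A `synth_params` object.
#' @export
synth_params <- function(dose_grid = pa_dose_grid(),
                         naive = list(top = 0.30, bottom = -0.55,
                                      ec50 = 80, hill = 1.5),
                         adapted = list(top = 0.05, bottom = -0.10,
                                        ec50 = 1500, hill = 1.2),
                         reference_rate = 0.1059,
                         replicates = 4,
                         sigma = 0.05,
                         preincubation_dose = 500) {
  p <- structure(list(dose_grid = sort(dose_grid), naive = naive,
                      adapted = adapted, reference_rate = reference_rate,
                      replicates = replicates, sigma = sigma,
                      preincubation_dose = preincubation_dose),
                 class = "synth_params")
  rn <- hill_rate(p$dose_grid, naive)
  ra <- hill_rate(p$dose_grid, adapted)
  if (any(abs(c(rn, ra)) > 1)) {
    stop("synthetic curves leave [-1, 1]: not interpretable as daily ",
         "probabilities", call. = FALSE)
  }
  if (hill_rate(0, naive) <= hill_rate(0, adapted)) {
    stop("crossing structure violated: naive rate must exceed adapted ",
         "rate at dose 0", call. = FALSE)
  }
  high <- p$dose_grid[p$dose_grid >= preincubation_dose]
  if (length(high) == 0 || any(hill_rate(high, adapted) <=
                               hill_rate(high, naive))) {
    stop("crossing structure violated: adapted rate must exceed naive ",
         "rate at doses >= ", preincubation_dose, " nM", call. = FALSE)
  }
  p
}

hill_rate <- function(dose, curve) {
  curve$bottom + (curve$top - curve$bottom) /
    (1 + (dose / curve$ec50)^curve$hill)
}

#' Ground-truth stratified rates of a parameter set
#'
#' @param params A [synth_params()] object.
#' @return A `stratified_rates` tibble evaluated from the noise-free curves.
#' @export
synth_true_rates <- function(params) {
  new_stratified_rates(
    tibble::tibble(dose_nM = params$dose_grid,
                   naive_rate = hill_rate(params$dose_grid, params$naive),
                   adapted_rate = hill_rate(params$dose_grid,
                                            params$adapted)),
    params$reference_rate
  )
}

#' Generate a synthetic fold-change dataset with known ground truth
#'
#' Emulates the 72-hour drug-challenge assay layout: for every dose on the
#' grid, every pre-incubation duration 0-4 weeks and every replicate, the
#' true per-day rate (naive curve for week 0, adapted curve for weeks 1-4)
#' is converted to a relative fold change by inverting the rate equation,
#' then multiplied by lognormal noise. The ground truth ships alongside so
#' recovery tests are self-describing.
#'
#' @param params A [synth_params()] object.
#' @param seed Optional seed.
#' @return A list with `records` (tibble: `dose_nM`, `weeks`, `replicate`,
#'   `fc_rel_72h`), `truth` (a `stratified_rates` tibble) and
#'   `reference_rate`.
#' @export
synth_foldchange_dataset <- function(params = synth_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- synth_true_rates(params)
  grid <- tidyr::expand_grid(dose_nM = params$dose_grid, weeks = 0:4,
                             replicate = seq_len(params$replicates))
  rate <- ifelse(grid$weeks == 0,
                 hill_rate(grid$dose_nM, params$naive),
                 hill_rate(grid$dose_nM, params$adapted))
  fc <- foldchange_from_growth_rate(rate, params$reference_rate) *
    exp(stats::rnorm(nrow(grid), 0, params$sigma))
  records <- dplyr::mutate(grid, fc_rel_72h = fc)
  list(records = records, truth = truth,
       reference_rate = params$reference_rate)
}

#' Synthetic cell-count time series under exponential growth
#'
#' Emulates the 7-day reference-condition count series from which the
#' reference rate is regressed.
#'
#' @param rate True per-day net growth rate.
#' @param n0 Count at day 0.
#' @param days Measurement days.
#' @param sigma Multiplicative lognormal noise sd on counts.
#' @param seed Optional seed.
#' @return A tibble with columns `day`, `count`.
#' @export
synth_count_series <- function(rate = 0.1059, n0 = 1000, days = 0:7,
                               sigma = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    day = days,
    count = n0 * exp(rate * days) * exp(stats::rnorm(length(days), 0,
                                                     sigma))
  )
}

#' Synthetic fitness matrix with a sign-changing gradient
#'
#' Builds the fitness matrix directly from the noise-free curves. The
#' crossing structure enforced by [synth_params()] guarantees the dose
#' gradient is negative at dose 0 and positive at the top of the grid.
#'
#' @param params A [synth_params()] object.
#' @param n Number of intermediate phenotype states.
#' @return A list with `fm` (a `fitness_matrix`) and `gradient` (the
#'   [gradient_direction()] table).
#' @export
synth_fitness_matrix <- function(params = synth_params(), n = 9) {
  fm <- build_fitness_matrix(synth_true_rates(params), n = n)
  list(fm = fm, gradient = gradient_direction(fm))
}

#' Synthetic treatment-response curves from a known candidate
#'
#' Simulates the continuous and intermittent schedules at the generating
#' candidate and records ensemble-mean normalised counts at the comparison
#' days — the ground truth for parameter-recovery experiments. With
#' `noise_sd = 0` and the same seed, [sse_objective()] at the generating
#' candidate is exactly zero.
#'
#' @param candidate List or one-row data frame with `fm0`, `fm1`, `eta_on`,
#'   `eta_off`.
#' @param strategy An [update_strategy()].
#' @param fm Base `fitness_matrix`.
#' @param n_runs Replicates per setting.
#' @param seed Root seed (shared with the fit for common random numbers).
#' @param noise_sd Additive observation noise sd on the recorded points.
#' @param ... Passed to the simulator (e.g. `times`, `dose`, `n0`, `init`).
#' @return A list with `data` (tibble `setting`, `day`, `value`) and
#'   `truth` (the candidate).
#' @export
synth_treatment_dataset <- function(candidate, strategy, fm, n_runs = 100,
                                    seed = NULL, noise_sd = 0, ...) {
  curves <- model_curves(candidate, strategy, fm, n_runs = n_runs,
                         seed = seed, ...)
  if (noise_sd > 0) {
    curves$value <- curves$value * exp(stats::rnorm(nrow(curves), 0,
                                                    noise_sd))
  }
  list(data = curves, truth = tibble::as_tibble(candidate))
}
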