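#' Treatment schedules
#'
#' A treatment schedule is a piecewise-constant dose-per-day function over
#' the simulated horizon (days 1..horizon). Constructors:
#'
#' * `schedule_none(horizon)` — no drug.
#' * `schedule_continuous(dose, horizon)` — constant dose every day.
#' * `schedule_intermittent(dose, t_on, t_off, horizon, delay = 0)` —
#'   `delay` drug-free days, then alternating `t_on` days at `dose` and
#'   `t_off` days at 0 (1:1 scheduling means `t_on == t_off`).
#'
#' @param dose Dose in nM (>= 0); must be on the fitness-matrix grid when the
#'   schedule is simulated.
#' @param horizon Number of simulated days (>= 1).
#' @param t_on,t_off Integer on/off interval lengths in days (>= 1).
#' @param delay Integer number of drug-free days before the first on
#'   interval.
#' @return A `treatment_schedule` object.
#' @export
#' @examples
#' schedule_intermittent(500, 7, 7, horizon = 28)
schedule_continuous <- function(dose, horizon) {
  new_schedule(rep(dose, horizon), paste0("cont:", dose, "nM"))
}

#' @rdname schedule_continuous
#' @export
schedule_none <- function(horizon) {
  new_schedule(rep(0, horizon), "none")
}

#' @rdname schedule_continuous
#' @export
schedule_intermittent <- function(dose, t_on, t_off, horizon, delay = 0) {
  stopifnot(t_on >= 1, t_off >= 1, t_on == round(t_on),
            t_off == round(t_off), delay >= 0, delay == round(delay),
            dose >= 0)
  cycle <- c(rep(dose, t_on), rep(0, t_off))
  doses <- c(rep(0, delay),
             rep(cycle, length.out = max(0, horizon - delay)))
  new_schedule(doses[seq_len(horizon)],
               paste0("int:", dose, "nM:", t_on, "on:", t_off, "off:delay",
                      delay))
}

new_schedule <- function(doses, spec) {
  horizon <- length(doses)
  if (horizon < 1 || any(doses < 0)) {
    stop("schedule must cover >= 1 day with non-negative doses",
         call. = FALSE)
  }
  structure(list(doses = doses, horizon = horizon, spec = spec),
            class = "treatment_schedule")
}

#' @export
print.treatment_schedule <- function(x, ...) {
  cat("Treatment schedule ", x$spec, " over ", x$horizon, " days\n",
      sep = "")
  invisible(x)
}

#' Days on which dosing resumes after a drug holiday
#'
#' Re-challenge days are drug-on days immediately preceded by a drug-off day;
#' the directed update strategies predict a death-event spike on these days.
#'
#' @param schedule A `treatment_schedule`.
#' @return Integer vector of day indices (possibly empty).
#' @export
rechallenge_days <- function(schedule) {
  on <- schedule$doses > 0
  which(on & !c(TRUE, on[-length(on)]))
}
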