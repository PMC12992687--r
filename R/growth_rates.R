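#' Default drug dose grid
#'
#' The twelve-point encorafenib challenge grid (nM) used throughout the
#' package: 0, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000, 10000.
#'
#' @return Numeric vector of doses in nM, ascending.
#' @export
#' @examples
#' pa_dose_grid()
pa_dose_grid <- function() {
  c(0, 0.1, 0.3, 1, 3, 10, 30, 100, 300, 1000, 3000, 10000)
}

#' Convert a relative fold change to a per-day net growth rate
#'
#' Under exponential growth over the assay window, a fold change in cell
#' counts relative to the reference condition maps to a net growth rate
#' \deqn{\lambda_d = \log(FC^{rel,d}) / \Delta t + \lambda_{ref},}
#' where the log is natural and \eqn{\Delta t} is the assay duration in days
#' (default 3, i.e. a 72-hour assay). `foldchange_from_growth_rate()` is the
#' exact inverse and is used by the synthetic-data generator.
#'
#' @param fc_rel Positive fold change(s) relative to the reference condition.
#' @param reference_rate Per-day net growth rate of the reference condition
#'   (e.g. the rate estimated under 500 nM by [estimate_reference_rate()]).
#' @param duration_days Assay duration in days (> 0). Default 3.
#' @return Per-day net growth rate(s), same length as `fc_rel`.
#' @export
#' @examples
#' growth_rate_from_foldchange(1, reference_rate = 0.1059)
#' growth_rate_from_foldchange(2, reference_rate = 0.1059)
growth_rate_from_foldchange <- function(fc_rel, reference_rate,
                                        duration_days = 3) {
  if (length(duration_days) != 1 || !is.finite(duration_days) ||
      duration_days <= 0) {
    stop("`duration_days` must be a single positive number, got ",
         deparse(duration_days), call. = FALSE)
  }
  bad <- which(!is.finite(fc_rel) | fc_rel <= 0)
  if (length(bad) > 0) {
    stop("`fc_rel` must be positive and finite; offending record(s) at ",
         "position(s) ", paste(bad, collapse = ", "),
         " with value(s) ", paste(fc_rel[bad], collapse = ", "),
         call. = FALSE)
  }
  log(fc_rel) / duration_days + reference_rate
}

#' @rdname growth_rate_from_foldchange
#' @param rate Per-day net growth rate(s) to convert back to fold changes.
#' @export
foldchange_from_growth_rate <- function(rate, reference_rate,
                                        duration_days = 3) {
  exp(duration_days * (rate - reference_rate))
}

#' Estimate the reference growth rate from a cell-count time series
#'
#' Fits a least-squares line to `log(count)` against `day` (natural log),
#' assuming approximately exponential growth; the slope is the per-day net
#' growth rate. Used for the 7-day 500 nM series that anchors the
#' fold-change-to-rate conversion.
#'
#' @param series A data frame with columns `day` (strictly increasing,
#'   >= 2 distinct values) and `count` (positive).
#' @return A single per-day rate (the regression slope).
#' @export
#' @examples
#' estimate_reference_rate(data.frame(day = 0:7, count = 100 * exp(0.2 * 0:7)))
estimate_reference_rate <- function(series) {
  series <- as.data.frame(series)
  if (!all(c("day", "count") %in% names(series))) {
    stop("`series` needs columns `day` and `count`", call. = FALSE)
  }
  if (any(!is.finite(series$count) | series$count <= 0)) {
    stop("all counts must be positive and finite", call. = FALSE)
  }
  if (length(unique(series$day)) < 2) {
    stop("need at least 2 distinct days to estimate a growth rate",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(log(count) ~ day, data = series))["day"])
}

#' Stratify fold-change records into drug-naive and drug-adapted rates
#'
#' Converts each fold-change record to a per-day rate and averages, per dose,
#' the week-0 records into a drug-naive rate (phenotype endpoint x = 0) and
#' the week 1-4 records into a drug-adapted rate (x = 1). Pre-incubated
#' populations at 1-4 weeks are treated as a single adapted stratum because
#' their dose-response rates are statistically indistinguishable; by default
#' all 1-4 week replicates are pooled with equal weight
#' (`adapted = "pooled"`), the alternative `"week_means"` averages per-week
#' means first.
#'
#' @param records Data frame of fold-change records with columns `dose_nM`,
#'   `weeks` (integers 0-4), `replicate`, `fc_rel_72h` (> 0), e.g. from
#'   [read_foldchange_table()] or [synth_foldchange_dataset()].
#' @param reference_rate Per-day reference rate (see
#'   [estimate_reference_rate()]).
#' @param duration_days Assay duration in days, default 3.
#' @param adapted How to average the 1-4 week stratum: `"pooled"` (default)
#'   or `"week_means"`.
#' @param incomplete What to do with doses missing one stratum: `"error"`
#'   (default) or `"drop"` (exclude those doses with a warning).
#' @return A `stratified_rates` tibble with columns `dose_nM`, `naive_rate`,
#'   `adapted_rate` (per day) and attribute `reference_rate`.
#' @export
stratify_phenotype_rates <- function(records, reference_rate,
                                     duration_days = 3,
                                     adapted = c("pooled", "week_means"),
                                     incomplete = c("error", "drop")) {
  adapted <- match.arg(adapted)
  incomplete <- match.arg(incomplete)
  records <- tibble::as_tibble(records)
  need <- c("dose_nM", "weeks", "fc_rel_72h")
  if (!all(need %in% names(records))) {
    stop("`records` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$weeks %in% 0:4)) {
    stop("`weeks` must be integers in 0..4", call. = FALSE)
  }
  records$rate <- growth_rate_from_foldchange(
    records$fc_rel_72h, reference_rate, duration_days
  )
  records$stratum <- ifelse(records$weeks == 0, "naive", "adapted")

  have <- records |>
    dplyr::distinct(.data$dose_nM, .data$stratum) |>
    dplyr::count(.data$dose_nM)
  missing_doses <- have$dose_nM[have$n < 2]
  if (length(missing_doses) > 0) {
    msg <- paste0("dose(s) ", paste(missing_doses, collapse = ", "),
                  " nM lack a naive or adapted stratum")
    if (incomplete == "error") stop(msg, call. = FALSE)
    warning(msg, "; dropping", call. = FALSE)
    records <- dplyr::filter(records, !.data$dose_nM %in% missing_doses)
  }

  naive <- records |>
    dplyr::filter(.data$stratum == "naive") |>
    dplyr::summarise(naive_rate = mean(.data$rate), .by = "dose_nM")
  ad <- dplyr::filter(records, .data$stratum == "adapted")
  adapted_tbl <- if (adapted == "pooled") {
    dplyr::summarise(ad, adapted_rate = mean(.data$rate), .by = "dose_nM")
  } else {
    ad |>
      dplyr::summarise(wm = mean(.data$rate),
                       .by = c("dose_nM", "weeks")) |>
      dplyr::summarise(adapted_rate = mean(.data$wm), .by = "dose_nM")
  }
  out <- naive |>
    dplyr::inner_join(adapted_tbl, by = "dose_nM") |>
    dplyr::arrange(.data$dose_nM)
  new_stratified_rates(out, reference_rate)
}

new_stratified_rates <- function(tbl, reference_rate) {
  tbl <- tibble::as_tibble(tbl)
  attr(tbl, "reference_rate") <- reference_rate
  class(tbl) <- c("stratified_rates", class(tbl))
  tbl
}

#' @export
print.stratified_rates <- function(x, ...) {
  cat("Stratified per-day growth rates (reference rate ",
      format(attr(x, "reference_rate"), digits = 4), " /day)\n", sep = "")
  NextMethod()
}

#' Reference rate carried by a stratified-rates table
#' @param x A `stratified_rates` object.
#' @return The per-day reference rate used in the fold-change conversion.
#' @export
reference_rate <- function(x) attr(x, "reference_rate")

#' Read and write fold-change tables
#'
#' CSV plumbing for the fold-change assay layout: columns `dose_nM`, `weeks`,
#' `replicate`, `fc_rel_72h`. Doses are validated against a declared grid and
#' offending rows are reported by row number.
#'
#' @param path Path to a CSV file.
#' @param dose_grid Allowed doses; default [pa_dose_grid()]. `NULL` skips the
#'   dose check.
#' @return A tibble of validated fold-change records.
#' @export
read_foldchange_table <- function(path, dose_grid = pa_dose_grid()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("dose_nM", "weeks", "replicate", "fc_rel_72h")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("dose_nM", "weeks", "fc_rel_72h")) {
    vals <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      stop("unparsable `", col, "` at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    tbl[[col]] <- vals
  }
  bad <- which(tbl$fc_rel_72h <= 0)
  if (length(bad) > 0) {
    stop("non-positive `fc_rel_72h` at data row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(dose_grid)) {
    bad <- which(!tbl$dose_nM %in% dose_grid)
    if (length(bad) > 0) {
      stop("dose not on the declared grid at data row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  tbl[need]
}

#' @rdname read_foldchange_table
#' @param records Fold-change records to serialize.
#' @export
write_foldchange_table <- function(records, path) {
  readr::write_csv(
    tibble::as_tibble(records)[c("dose_nM", "weeks", "replicate",
                                 "fc_rel_72h")],
    path
  )
  invisible(path)
}
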