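#' Build a phenotype-by-dose fitness matrix
#'
#' The fitness matrix FM(x, d) stores the per-day net growth rate of a cell
#' in phenotype state x under dose d. States live on the lattice
#' x_i = i / (n + 1), i = 0..n+1, so there are S = n + 2 states with step
#' Delta = 1/(n+1); x = 0 is the drug-naive endpoint and x = 1 the
#' drug-adapted endpoint. Column endpoints come from the stratified rates and
#' interior states are linearly interpolated, so every column is exactly
#' linear in x. Entries are interpreted as daily division (positive) or death
#' (negative) probabilities and must lie in [-1, 1]; out-of-range rates are
#' rejected, never clipped.
#'
#' @param rates A data frame with columns `dose_nM`, `naive_rate`,
#'   `adapted_rate` (e.g. a `stratified_rates` table).
#' @param n Number of intermediate phenotype states (>= 0). Default 9, giving
#'   11 states with step 0.1.
#' @return A `fitness_matrix` object.
#' @export
#' @examples
#' r <- data.frame(dose_nM = c(0, 500), naive_rate = c(0.3, -0.5),
#'                 adapted_rate = c(0.05, 0.1))
#' fm <- build_fitness_matrix(r, n = 9)
#' fm_lookup(fm, 5, 500)
build_fitness_matrix <- function(rates, n = 9) {
  rates <- as.data.frame(rates)
  need <- c("dose_nM", "naive_rate", "adapted_rate")
  if (!all(need %in% names(rates))) {
    stop("`rates` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(n) != 1 || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  rates <- rates[order(rates$dose_nM), ]
  if (anyDuplicated(rates$dose_nM)) {
    stop("duplicate doses in `rates`", call. = FALSE)
  }
  for (col in c("naive_rate", "adapted_rate")) {
    bad <- which(abs(rates[[col]]) > 1 | !is.finite(rates[[col]]))
    if (length(bad) > 0) {
      stop("|rate| > 1 cannot be a daily probability: `", col,
           "` at dose(s) ", paste(rates$dose_nM[bad], collapse = ", "),
           " nM", call. = FALSE)
    }
  }
  S <- n + 2L
  x <- seq(0, 1, length.out = S)
  values <- outer(x, seq_len(nrow(rates)), function(xi, j) {
    rates$naive_rate[j] + xi * (rates$adapted_rate[j] - rates$naive_rate[j])
  })
  dimnames(values) <- list(state = paste0("x", 0:(S - 1L)),
                           dose = format(rates$dose_nM))
  structure(
    list(values = values, doses = rates$dose_nM, n = as.integer(n),
         states = x, delta = 1 / (n + 1)),
    class = "fitness_matrix"
  )
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat("Fitness matrix: ", length(x$states), " phenotype states (n = ", x$n,
      ", step ", format(x$delta, digits = 4), "), ",
      length(x$doses), " doses\n", sep = "")
  print(round(t(x$values), 4))
  invisible(x)
}

dose_col <- function(fm, dose) {
  j <- match(dose, fm$doses)
  if (is.na(j)) {
    stop("dose ", dose, " nM is not on the matrix grid (",
         paste(fm$doses, collapse = ", "),
         "); insert it with add_dose_loglinear()", call. = FALSE)
  }
  j
}

#' Look up a fitness-matrix entry
#'
#' Returns the stored per-day rate for an integer phenotype state index and a
#' dose already on the matrix grid. No silent dose interpolation: unknown
#' doses are an error pointing at [add_dose_loglinear()].
#'
#' @param fm A `fitness_matrix`.
#' @param state Integer state index in 0..n+1 (0 = drug-naive endpoint).
#' @param dose Dose in nM, must be on the grid.
#' @return Per-day net growth rate.
#' @export
fm_lookup <- function(fm, state, dose) {
  if (any(state < 0 | state > fm$n + 1 | state != round(state))) {
    stop("state index must be an integer in 0..", fm$n + 1, call. = FALSE)
  }
  fm$values[state + 1L, dose_col(fm, dose)]
}

#' Insert a dose column by log-linear interpolation
#'
#' Adds a new positive dose strictly between two adjacent positive grid doses;
#' each state's rate is interpolated linearly in log-dose between the
#' bracketing columns (the weight is log-base invariant). Dose 0 can never be
#' an anchor. Column linearity in x is preserved exactly.
#'
#' @param fm A `fitness_matrix`.
#' @param new_dose Positive dose (nM) strictly inside a positive-dose
#'   interval of the grid.
#' @return A `fitness_matrix` with the enlarged dose grid.
#' @export
add_dose_loglinear <- function(fm, new_dose) {
  if (length(new_dose) != 1 || !is.finite(new_dose) || new_dose <= 0) {
    stop("`new_dose` must be a single positive dose", call. = FALSE)
  }
  if (new_dose %in% fm$doses) {
    stop("dose ", new_dose, " nM is already on the grid", call. = FALSE)
  }
  pos <- fm$doses[fm$doses > 0]
  lo <- max(pos[pos < new_dose], -Inf)
  hi <- min(pos[pos > new_dose], Inf)
  if (!is.finite(lo) || !is.finite(hi)) {
    stop("dose ", new_dose,
         " nM is outside the positive-dose interpolation range [",
         min(pos), ", ", max(pos), "]", call. = FALSE)
  }
  w <- (log(new_dose) - log(lo)) / (log(hi) - log(lo))
  col <- (1 - w) * fm$values[, dose_col(fm, lo)] +
    w * fm$values[, dose_col(fm, hi)]
  rates <- data.frame(
    dose_nM = c(fm$doses, new_dose),
    naive_rate = c(fm$values[1L, ], col[1L]),
    adapted_rate = c(fm$values[nrow(fm$values), ], col[length(col)])
  )
  build_fitness_matrix(rates, fm$n)
}

#' Overwrite (or add) a dose column from endpoint rates
#'
#' Sets the drug-naive and drug-adapted endpoint rates of one dose column and
#' re-derives the interior states by linear interpolation. Used by the
#' calibration routine to insert candidate 500 nM rates.
#'
#' @param fm A `fitness_matrix`.
#' @param dose Dose in nM (added to the grid if absent).
#' @param naive_rate,adapted_rate Endpoint per-day rates in [-1, 1].
#' @return A `fitness_matrix`.
#' @export
fm_set_dose <- function(fm, dose, naive_rate, adapted_rate) {
  keep <- fm$doses != dose
  rates <- data.frame(
    dose_nM = c(fm$doses[keep], dose),
    naive_rate = c(fm$values[1L, keep], naive_rate),
    adapted_rate = c(fm$values[nrow(fm$values), keep], adapted_rate)
  )
  build_fitness_matrix(rates, fm$n)
}

#' Fitness gradient along the phenotype axis
#'
#' For each requested dose, the dose gradient Delta FM(d) = FM(1, d) -
#' FM(0, d) and its sign, which is the direction in which directed phenotype
#' updates move cells: +1 means fitness increases towards the drug-adapted
#' endpoint (typical when the drug is on), -1 towards the drug-naive endpoint
#' (typical off drug), 0 for a flat column.
#'
#' @param fm A `fitness_matrix`.
#' @param dose Dose(s) in nM on the grid; default all grid doses.
#' @return A tibble with columns `dose_nM`, `delta_fm`, `direction`.
#' @export
gradient_direction <- function(fm, dose = fm$doses) {
  j <- vapply(dose, function(d) dose_col(fm, d), integer(1))
  delta <- fm$values[nrow(fm$values), j] - fm$values[1L, j]
  tibble::tibble(dose_nM = dose, delta_fm = unname(delta),
                 direction = sign(unname(delta)))
}

#' @export
as_tibble.fitness_matrix <- function(x, ...) {
  tibble::tibble(
    dose_nM = rep(x$doses, each = length(x$states)),
    state = rep(0:(x$n + 1L), times = length(x$doses)),
    phenotype = rep(x$states, times = length(x$doses)),
    rate = as.vector(x$values)
  )
}

#' Read and write a fitness matrix as CSV
#'
#' Layout: one row per dose, first column `dose_nM`, then one column per
#' phenotype state (`x0` .. `x{n+1}`), mirroring the usual printed form of
#' the matrix.
#'
#' @param fm A `fitness_matrix`.
#' @param path CSV path.
#' @return `read_fitness_matrix()` returns a `fitness_matrix`.
#' @export
write_fitness_matrix <- function(fm, path) {
  tbl <- as.data.frame(t(fm$values))
  tbl <- cbind(dose_nM = fm$doses, tbl)
  readr::write_csv(tibble::as_tibble(tbl), path)
  invisible(path)
}

#' @rdname write_fitness_matrix
#' @export
read_fitness_matrix <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  scol <- grep("^x[0-9]+$", names(tbl), value = TRUE)
  if (length(scol) < 2 || !"dose_nM" %in% names(tbl)) {
    stop("not a fitness-matrix CSV: need `dose_nM` and >= 2 `x<i>` columns",
         call. = FALSE)
  }
  scol <- scol[order(as.integer(sub("x", "", scol)))]
  rates <- data.frame(dose_nM = tbl$dose_nM,
                      naive_rate = tbl[[scol[1]]],
                      adapted_rate = tbl[[scol[length(scol)]]])
  build_fitness_matrix(rates, n = length(scol) - 2L)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @export
tidy.fitness_matrix <- function(x, ...) as_tibble(x)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a fitness matrix
#'
#' @param object A `fitness_matrix`.
#' @param ... Unused.
#' @return A ggplot object: phenotype state vs dose, filled by per-day rate.
#' @export
autoplot.fitness_matrix <- function(object, ...) {
  tbl <- as_tibble(object)
  tbl$dose <- factor(tbl$dose_nM, levels = sort(unique(tbl$dose_nM)))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$phenotype, y = .data$dose,
                                    fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "phenotype state x", y = "dose (nM)",
                  fill = "net growth\nrate (/day)")
}
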