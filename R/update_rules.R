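#' Phenotype update strategies
#'
#' The four candidate per-opportunity kernels on the phenotype lattice:
#'
#' * `"none"` — cells never change state.
#' * `"unbiased"` — propose each neighbour with probability rho/2 and always
#'   accept (phenotypic instability).
#' * `"semibiased"` — propose each neighbour with probability rho/2 but accept
#'   only moves to strictly higher fitness (noisy gradient sensing).
#' * `"biased"` — move to a strictly fitter neighbour whenever one exists
#'   (stress-induced directed adaptation; the rho/2 prefactor is omitted).
#'
#' `rho` is the per-opportunity update probability in [0, 1]; it is ignored
#' by `"none"` and `"biased"`. Moves that would leave the lattice are
#' rejected (their mass stays on the current state), and equal-fitness moves
#' are rejected too (strict Heaviside convention, H(0) = 0).
#'
#' @param kind One of `"none"`, `"unbiased"`, `"semibiased"`, `"biased"`.
#' @param rho Per-opportunity update probability, default 1.
#' @return An `update_strategy` object.
#' @export
#' @examples
#' update_strategy("biased")
#' update_strategy("semibiased", rho = 0.5)
update_strategy <- function(kind = c("none", "unbiased", "semibiased",
                                     "biased"),
                            rho = 1) {
  kind <- match.arg(kind)
  if (length(rho) != 1 || !is.finite(rho) || rho < 0 || rho > 1) {
    stop("`rho` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(kind = kind, rho = rho), class = "update_strategy")
}

#' @export
print.update_strategy <- function(x, ...) {
  cat("Phenotype update strategy: ", x$kind,
      if (x$kind %in% c("unbiased", "semibiased"))
        paste0(" (rho = ", x$rho, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Per-opportunity transition probabilities at one lattice state
#'
#' Evaluates the selected update kernel at phenotype state index `state`
#' under dose `dose`, returning the probabilities of moving down one state,
#' staying, and moving up one state. The three probabilities always sum to 1;
#' boundary-blocked or fitness-rejected directions contribute their mass to
#' staying. For the biased kernel on a (never arising from linear columns,
#' but allowed) non-monotone column where both neighbours improve, the larger
#' fitness gain wins and an exact tie splits equally.
#'
#' @param state Integer state index in 0..n+1.
#' @param dose Dose (nM) on the matrix grid.
#' @param strategy An [update_strategy()].
#' @param fm A [build_fitness_matrix()] object.
#' @return Named numeric vector `c(p_minus, p_stay, p_plus)`.
#' @export
transition_probabilities <- function(state, dose, strategy, fm) {
  stopifnot(inherits(strategy, "update_strategy"),
            inherits(fm, "fitness_matrix"))
  col <- fm$values[, dose_col(fm, dose)]
  kernel <- transition_kernel(col, strategy)
  if (any(state < 0 | state > fm$n + 1 | state != round(state))) {
    stop("state index must be an integer in 0..", fm$n + 1, call. = FALSE)
  }
  p <- kernel[state + 1L, ]
  names(p) <- c("p_minus", "p_stay", "p_plus")
  p
}

# Full S x 3 kernel for one dose column; row i = state i-1,
# columns (down, stay, up). Vectorized core used by the simulator.
transition_kernel <- function(col, strategy) {
  S <- length(col)
  down <- numeric(S)
  up <- numeric(S)
  ok_down <- c(FALSE, rep(TRUE, S - 1L))   # state 0 cannot move down
  ok_up <- c(rep(TRUE, S - 1L), FALSE)     # state n+1 cannot move up
  gain_down <- c(0, col[-S]) - col         # FM(x_-) - FM(x_0)
  gain_up <- c(col[-1L], 0) - col          # FM(x_+) - FM(x_0)
  switch(strategy$kind,
    none = NULL,
    unbiased = {
      down <- ifelse(ok_down, strategy$rho / 2, 0)
      up <- ifelse(ok_up, strategy$rho / 2, 0)
    },
    semibiased = {
      down <- ifelse(ok_down & gain_down > 0, strategy$rho / 2, 0)
      up <- ifelse(ok_up & gain_up > 0, strategy$rho / 2, 0)
    },
    biased = {
      down <- as.numeric(ok_down & gain_down > 0)
      up <- as.numeric(ok_up & gain_up > 0)
      both <- down > 0 & up > 0
      if (any(both)) {
        tie <- both & gain_down == gain_up
        down[both] <- as.numeric(gain_down[both] > gain_up[both])
        up[both] <- as.numeric(gain_up[both] > gain_down[both])
        down[tie] <- 0.5
        up[tie] <- 0.5
      }
    }
  )
  cbind(down = down, stay = 1 - down - up, up = up)
}

#' Sample a phenotype update
#'
#' Draws the next state index from a transition triple; the result always
#' stays on the lattice because blocked directions carry zero probability.
#'
#' @param state Current integer state index.
#' @param triple Probabilities `c(p_minus, p_stay, p_plus)` summing to 1.
#' @return The new state index.
#' @export
apply_update <- function(state, triple) {
  if (abs(sum(triple) - 1) > 1e-12 || any(triple < 0)) {
    stop("`triple` must be non-negative and sum to 1", call. = FALSE)
  }
  state + sample(c(-1L, 0L, 1L), 1L, prob = triple)
}
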