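# Spatially-indexed leaky competing accumulators. One integrator per
# location; the value signal V is gated to the currently attended location
# only. Update (Euler, step dt):
#
#   dx_i/dt = -lambda x_i + alpha I_i - beta sum_{j!=i} I_j
#             + gamma f(x_i) - delta sum_{j!=i} f(x_j) + N(0, sigma)
#
# with f = ReLU. All four gains are stored nonnegative; the inhibitory
# pathways (beta: forward inhibition, delta: feedback inhibition) act
# through an inhibitory inter-node and therefore enter with a minus sign.

#' Leaky competing accumulator bank
#'
#' @param n_locations Number of accumulators (one per spatial location).
#' @param alpha Forward excitation gain on the gated value input.
#' @param beta Forward inhibition: the attended value also suppresses the
#'   competing accumulators. Raising it trades speed for accuracy.
#' @param gamma Feedback self-excitation on the ReLU output.
#' @param delta Feedback (lateral) inhibition between accumulators.
#' @param lambda Leak; with `lambda > 0` early evidence is forgotten.
#' @param sigma Additive Gaussian noise s.d. per unit time (scaled by
#'   `sqrt(dt)` per step), drawn independently per accumulator per step.
#' @param dt Euler step, default 1.
#' @param clamp_state If TRUE the state itself is clamped at 0; by default
#'   only the outputs pass through ReLU and the state may go negative.
#' @return A list of class `accumulator_bank`.
#' @export
accumulator_bank <- function(n_locations, alpha = 1, beta = 0, gamma = 0,
                             delta = 0, lambda = 0, sigma = 0, dt = 1,
                             clamp_state = FALSE) {
  n_locations <- as.integer(n_locations)
  stopifnot(n_locations >= 1L, alpha >= 0, beta >= 0, gamma >= 0,
            delta >= 0, lambda >= 0, sigma >= 0, dt > 0)
  structure(list(x = numeric(n_locations), n = n_locations,
                 alpha = alpha, beta = beta, gamma = gamma, delta = delta,
                 lambda = lambda, sigma = sigma, dt = dt,
                 clamp_state = isTRUE(clamp_state)),
            class = "accumulator_bank")
}

#' @export
print.accumulator_bank <- function(x, ...) {
  cat("<accumulator_bank> ", x$n, " accumulator(s); gains a=", x$alpha,
      " b=", x$beta, " g=", x$gamma, " d=", x$delta,
      "; leak=", x$lambda, " sigma=", x$sigma, "\n", sep = "")
  cat("  state: ", paste(signif(x$x, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Advance the accumulator bank one step
#'
#' The value input is gated by spatial attention: `I_selected = V`, all
#' other inputs 0, so at any step only the attended location's value
#' excites its own accumulator (weight `alpha`) and inhibits the others
#' (weight `beta`).
#'
#' @param bank An [accumulator_bank()].
#' @param V Scalar value signal from the valuation stage.
#' @param selected 1-based index of the attended accumulator.
#' @return Updated bank.
#' @export
acc_step <- function(bank, V, selected) {
  stopifnot(inherits(bank, "accumulator_bank"))
  selected <- as.integer(selected)
  if (is.na(selected) || selected < 1L || selected > bank$n) {
    stop("selected accumulator index out of range: ", selected, call. = FALSE)
  }
  I <- numeric(bank$n); I[selected] <- V
  fa <- pmax(bank$x, 0)
  sumI <- sum(I); sumf <- sum(fa)
  dx <- -bank$lambda * bank$x + bank$alpha * I - bank$beta * (sumI - I) +
    bank$gamma * fa - bank$delta * (sumf - fa)
  x_new <- bank$x + bank$dt * dx
  if (bank$sigma > 0) {
    x_new <- x_new + stats::rnorm(bank$n, 0, bank$sigma * sqrt(bank$dt))
  }
  if (!all(is.finite(x_new))) {
    stop("accumulator state diverged (non-finite); check gains", call. = FALSE)
  }
  if (bank$clamp_state) x_new <- pmax(x_new, 0)
  bank$x <- x_new
  bank
}

#' Winner-takes-all decision check
#'
#' Fires once any accumulator reaches the decision threshold; among those
#' at or above threshold the largest wins, exact ties being broken
#' uniformly at random (reproducible under the seeded stream).
#'
#' @param bank An [accumulator_bank()].
#' @param threshold Decision threshold, > 0 (all reported simulations use 1).
#' @return 1-based winner index, or `NA_integer_` if no accumulator has
#'   reached threshold.
#' @export
check_decision <- function(bank, threshold = 1) {
  stopifnot(inherits(bank, "accumulator_bank"), threshold > 0)
  crossed <- which(bank$x >= threshold)
  if (length(crossed) == 0L) return(NA_integer_)
  top <- crossed[bank$x[crossed] == max(bank$x[crossed])]
  if (length(top) == 1L) return(top)
  idx <- floor(stats::runif(1) * length(top)) + 1L
  if (idx > length(top)) idx <- length(top)
  top[idx]
}

#' Reset all accumulators to zero
#'
#' Applied by the decision layer after a choice fires.
#'
#' @param bank An [accumulator_bank()].
#' @return Bank with all states 0.
#' @export
reset_bank <- function(bank) {
  stopifnot(inherits(bank, "accumulator_bank"))
  bank$x <- numeric(bank$n)
  bank
}
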