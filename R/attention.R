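# Stochastic spatial attention. Each step, attention may switch to
# location i with probability
#
#   p_i = eps * (s_i + phi * g_i^n) / sum_j (s_j + phi * g_j^n)
#
# where s is bottom-up salience, g is top-down feedback from the
# accumulators (their ReLU outputs), phi the feedback gain and n a
# contrast-enhancement exponent (2 in all reported simulations).
# With probability 1 - eps attention stays put. After a decision fires,
# attention locks onto the chosen object.

#' Attention configuration
#'
#' @param epsilon Base rate of attention shifts per step, in `[0, 1]`.
#'   The total switch probability each step is exactly `epsilon`.
#' @param phi Gain of top-down feedback from the accumulators (>= 0).
#' @param n Contrast-enhancement exponent on the feedback (default 2).
#' @return A list of class `attention_config`.
#' @export
attention_config <- function(epsilon = 0.02, phi = 0, n = 2) {
  stopifnot(epsilon >= 0, epsilon <= 1, phi >= 0, n > 0)
  structure(list(epsilon = epsilon, phi = phi, n = n),
            class = "attention_config")
}

#' Attention state
#'
#' @param current 0-based location index currently attended.
#' @param locked TRUE once a decision has fired and attention is locked.
#' @return A list of class `attention_state`.
#' @export
attention_state <- function(current = 0L, locked = FALSE) {
  structure(list(current = as.integer(current), locked = isTRUE(locked)),
            class = "attention_state")
}

#' Per-location switch probabilities
#'
#' @param s Salience vector (elementwise >= 0), one entry per location.
#' @param g Accumulator feedback vector (elementwise >= 0), same length.
#' @param cfg An [attention_config()].
#' @return Probability vector `p`; `sum(p) == epsilon`.
#' @export
switch_probabilities <- function(s, g, cfg) {
  stopifnot(inherits(cfg, "attention_config"))
  if (length(s) != length(g)) {
    stop("salience and feedback vectors must have the same length",
         call. = FALSE)
  }
  if (any(s < 0) || any(g < 0)) {
    stop("salience and feedback must be nonnegative", call. = FALSE)
  }
  w <- s + cfg$phi * g^cfg$n
  tot <- sum(w)
  if (tot <= 0) {
    stop("degenerate scene: no location has positive salience or feedback",
         call. = FALSE)
  }
  cfg$epsilon * w / tot
}

#' Maybe shift attention
#'
#' Draws a single uniform variate: with probability `p_i` attention moves
#' to location i (which may be the currently attended one — that counts as
#' a dwell continuation, not a re-fixation), otherwise it stays. A locked
#' state never moves.
#'
#' @param state An [attention_state()].
#' @param p Probability vector from [switch_probabilities()].
#' @return List with the updated `state` and `shifted` (TRUE only when the
#'   attended location actually changed).
#' @export
maybe_shift <- function(state, p) {
  stopifnot(inherits(state, "attention_state"))
  if (state$locked) return(list(state = state, shifted = FALSE))
  u <- stats::runif(1)
  cum <- cumsum(p)
  k <- length(p)
  if (u >= cum[k]) return(list(state = state, shifted = FALSE))
  target <- findInterval(u, cum) # 0-based: u < cum[1] -> 0
  shifted <- target != state$current
  state$current <- as.integer(target)
  list(state = state, shifted = shifted)
}

#' Lock attention on the chosen location
#'
#' Called by the decision layer when an accumulator crosses threshold;
#' a locked state ignores further shift draws until the trial is reset.
#'
#' @param state An [attention_state()].
#' @param winner 0-based location index of the chosen object.
#' @return Locked `attention_state`.
#' @export
lock_attention <- function(state, winner) {
  stopifnot(inherits(state, "attention_state"))
  state$current <- as.integer(winner)
  state$locked <- TRUE
  state
}
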