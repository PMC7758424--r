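# Recurrent memory network: fast semantic attractors with synaptic
# depression (latching), plus long-latency episodic connections that replay
# stored sequences. Dynamics, per node i:
#
#   dx_i/dt = I_i + sum_j (1 - d_ji) w_ji f(x_j(t - tau_ji)) - leak * x_i
#
# with one delay per connection class: tau_fast for semantic weights,
# tau_slow for episodic weights. f is a saturating piecewise-linear
# activation clip(x, 0, 1); the readout is m = f(x). Depression d_ji grows
# with the signal flowing through the connection and recovers slowly,
# which collapses the active attractor after a dwell (latching).

act_clip <- function(x) pmin(pmax(x, 0), 1)

#' Memory network configuration
#'
#' @param dt Integration step (Euler); the time unit is one simulation step.
#' @param tau_fast Delay (steps) of semantic connections; must be >= 1.
#' @param tau_slow Delay (steps) of episodic connections; >= `tau_fast`.
#' @param depression_gain Rate at which per-connection depression grows with
#'   the signal passing through the connection. 0 disables latching.
#' @param depression_recovery Recovery rate of depression back toward 0.
#' @param leak Optional passive decay of the activation `x` (default 0).
#'   A positive leak is required for attractor states to dissolve once
#'   depression removes their recurrent support.
#' @param noise Optional additive Gaussian noise s.d. on `x` per step
#'   (default 0; kept as a hook, all bundled scenarios leave it at 0).
#' @return A list of class `memory_config`.
#' @export
memory_config <- function(dt = 1, tau_fast = 1L, tau_slow = 25L,
                          depression_gain = 0, depression_recovery = 0,
                          leak = 0, noise = 0) {
  tau_fast <- as.integer(tau_fast); tau_slow <- as.integer(tau_slow)
  stopifnot(dt > 0, tau_fast >= 1L, tau_slow >= tau_fast,
            depression_gain >= 0, depression_recovery >= 0,
            leak >= 0, noise >= 0)
  structure(list(dt = dt, tau_fast = tau_fast, tau_slow = tau_slow,
                 depression_gain = depression_gain,
                 depression_recovery = depression_recovery,
                 leak = leak, noise = noise),
            class = "memory_config")
}

#' Association set
#'
#' Holds the two recurrent weight matrices of the memory network —
#' semantic (fast, latency `tau_fast`) and episodic (slow, latency
#' `tau_slow`) — together with the named binary patterns they encode.
#' Convention: `W[i, j]` is the weight of the connection from node `j`
#' to node `i`.
#'
#' @param semantic,episodic N x N numeric matrices.
#' @param patterns Named list of binary vectors of length N.
#' @return A list of class `association_set`.
#' @export
association_set <- function(semantic, episodic = NULL,
                            patterns = list()) {
  semantic <- as.matrix(semantic)
  n <- nrow(semantic)
  if (ncol(semantic) != n) stop("semantic weights must be square", call. = FALSE)
  if (is.null(episodic)) episodic <- matrix(0, n, n)
  episodic <- as.matrix(episodic)
  if (!identical(dim(episodic), dim(semantic))) {
    stop("episodic and semantic weight matrices must have identical shape",
         call. = FALSE)
  }
  if (!all(is.finite(semantic)) || !all(is.finite(episodic))) {
    stop("association weights must be finite", call. = FALSE)
  }
  for (nm in names(patterns)) {
    p <- patterns[[nm]]
    if (length(p) != n || !all(p %in% c(0, 1))) {
      stop("stored pattern '", nm, "' is not a binary vector of length ",
           n, call. = FALSE)
    }
  }
  structure(list(semantic = semantic, episodic = episodic,
                 patterns = patterns, n = n),
            class = "association_set")
}

#' @export
print.association_set <- function(x, ...) {
  cat("<association_set> ", x$n, " nodes, ",
      length(x$patterns), " stored pattern(s)\n", sep = "")
  cat("  semantic nonzero: ", sum(x$semantic != 0),
      ", episodic nonzero: ", sum(x$episodic != 0), "\n", sep = "")
  invisible(x)
}

#' Encode binary patterns as semantic attractors
#'
#' Hebbian outer-product encoding, normalised per pattern so that a node of
#' a fully active pattern receives total recurrent drive `gain`:
#' `W += gain * p %o% p / sum(p)`. With `gain > leak` the pattern is a
#' fixed point of the undepressed readout dynamics.
#'
#' @param patterns List of binary vectors (same length). May be named.
#' @param n_nodes Required when `patterns` is empty.
#' @param gain Recurrent drive at a fully active pattern (default 0.5).
#' @return N x N semantic weight matrix.
#' @export
encode_attractors <- function(patterns, n_nodes = NULL, gain = 0.5) {
  if (length(patterns) == 0L) {
    if (is.null(n_nodes)) stop("n_nodes required for empty pattern list",
                               call. = FALSE)
    return(matrix(0, n_nodes, n_nodes))
  }
  lens <- lengths(patterns)
  if (length(unique(lens)) != 1L) {
    stop("all patterns must have the same length", call. = FALSE)
  }
  n <- lens[[1]]
  w <- matrix(0, n, n)
  for (p in patterns) {
    p <- as.numeric(p)
    if (!all(p %in% c(0, 1))) stop("patterns must be binary", call. = FALSE)
    w <- w + gain * (p %o% p) / sum(p)
  }
  w
}

#' Encode an ordered pattern sequence as delayed episodic weights
#'
#' Hetero-associative weights from each pattern to its successor,
#' normalised like [encode_attractors()]: when pattern k is fully active,
#' each node of pattern k+1 receives drive `gain` through the slow
#' (delay `tau_slow`) pathway, so the readout reaches pattern k+1 roughly
#' `tau_slow` steps plus a short rise time later.
#'
#' @param sequence Ordered list of >= 2 binary vectors.
#' @param gain Drive delivered to the successor pattern (default 0.3).
#' @return N x N episodic weight matrix.
#' @export
encode_episodic_chain <- function(sequence, gain = 0.3) {
  if (length(sequence) < 2L) {
    stop("an episodic chain needs at least 2 patterns", call. = FALSE)
  }
  lens <- lengths(sequence)
  if (length(unique(lens)) != 1L) {
    stop("all patterns must have the same length", call. = FALSE)
  }
  n <- lens[[1]]
  w <- matrix(0, n, n)
  for (k in seq_len(length(sequence) - 1L)) {
    from <- as.numeric(sequence[[k]]); to <- as.numeric(sequence[[k + 1L]])
    if (!all(from %in% c(0, 1)) || !all(to %in% c(0, 1))) {
      stop("patterns must be binary", call. = FALSE)
    }
    w <- w + gain * (to %o% from) / sum(from)
  }
  w
}

#' Fresh memory state
#'
#' Activation x = 0, no depression, empty delay history. The history ring
#' buffer stores past readouts to depth `tau_slow`, enough for the longest
#' connection delay.
#'
#' @param n Number of nodes.
#' @param cfg A [memory_config()].
#' @return A list of class `memory_state`.
#' @export
memory_state <- function(n, cfg = memory_config()) {
  stopifnot(inherits(cfg, "memory_config"))
  depth <- max(cfg$tau_slow, cfg$tau_fast)
  structure(list(x = numeric(n),
                 d = matrix(0, n, n),
                 hist = matrix(0, n, depth),
                 t = 0L, n = n),
            class = "memory_state")
}

# readout stored after step s (>=1); zeros before the trial started
hist_readout <- function(state, s) {
  if (s < 1L || s < state$t - ncol(state$hist) + 1L) return(numeric(state$n))
  state$hist[, ((s - 1L) %% ncol(state$hist)) + 1L]
}

#' Advance the memory network one step
#'
#' Explicit Euler update of the delayed recurrent dynamics. Depression on
#' each connection grows in proportion to the signal flowing through it,
#' `w_ji * f(x_j(t - tau_ji))`, and recovers at `depression_recovery`;
#' it is clipped to `[0, 1]`.
#'
#' @param state A [memory_state()].
#' @param input External input vector I (already scaled).
#' @param assoc An [association_set()].
#' @param cfg A [memory_config()].
#' @return Updated `memory_state`.
#' @export
memory_step <- function(state, input, assoc, cfg) {
  stopifnot(inherits(state, "memory_state"),
            inherits(assoc, "association_set"),
            inherits(cfg, "memory_config"))
  n <- state$n
  if (length(input) != n || assoc$n != n) {
    stop("dimension mismatch: state has ", n, " nodes, input ",
         length(input), ", associations ", assoc$n, call. = FALSE)
  }
  f_fast <- hist_readout(state, state$t - cfg$tau_fast + 1L)
  f_slow <- hist_readout(state, state$t - cfg$tau_slow + 1L)
  omd <- 1 - state$d
  rec <- (omd * assoc$semantic) %*% f_fast + (omd * assoc$episodic) %*% f_slow
  dx <- input + as.numeric(rec) - cfg$leak * state$x
  x_new <- state$x + cfg$dt * dx
  if (cfg$noise > 0) {
    x_new <- x_new + stats::rnorm(n, 0, cfg$noise * sqrt(cfg$dt))
  }
  if (!all(is.finite(x_new))) {
    stop("memory state diverged (non-finite activation) at step ",
         state$t + 1L, "; max |x| before update = ", max(abs(state$x)),
         call. = FALSE)
  }
  if (cfg$depression_gain > 0 || cfg$depression_recovery > 0) {
    # signal through connection j -> i, per delay class
    sig <- assoc$semantic * rep(f_fast, each = n) +
      assoc$episodic * rep(f_slow, each = n)
    d_new <- state$d + cfg$dt * (cfg$depression_gain * sig * (1 - state$d) -
                                   cfg$depression_recovery * state$d)
    state$d <- pmin(pmax(d_new, 0), 1)
  }
  state$x <- x_new
  state$t <- state$t + 1L
  m <- act_clip(x_new)
  state$hist[, ((state$t - 1L) %% ncol(state$hist)) + 1L] <- m
  state
}

#' Memory readout
#'
#' Elementwise activation of the state: `m_i = f(x_i)` with the saturating
#' piecewise-linear f.
#'
#' @param state A [memory_state()].
#' @return Numeric vector m in `[0, 1]`.
#' @export
memory_readout <- function(state) {
  act_clip(state$x)
}

#' Reset the memory state
#'
#' Clears the activation and the delay history (as happens when attention
#' shifts to a different object). Synaptic depression is a property of the
#' connections, not of the activity, so it persists and recovers on its own
#' timescale.
#'
#' @param state A [memory_state()].
#' @return Reset `memory_state`.
#' @export
memory_reset <- function(state) {
  state$x <- numeric(state$n)
  state$hist[] <- 0
  state$t <- 0L
  state
}

#' Initialise the memory state at a pattern
#'
#' Sets the activation equal to the pattern (readout equals the pattern
#' exactly since f(1) = 1), as when a stored state is externally cued.
#' The delay history is seeded only back to the fast latency, so semantic
#' recurrent support is available at once while episodic (slow) drive
#' starts flowing `tau_slow` steps after the cue.
#'
#' @param state A [memory_state()].
#' @param pattern Binary vector of length N.
#' @param cfg The [memory_config()] the state will be stepped with.
#' @return Updated `memory_state`.
#' @export
memory_init <- function(state, pattern, cfg = memory_config()) {
  stopifnot(length(pattern) == state$n, inherits(cfg, "memory_config"))
  state <- memory_reset(state)
  state$x <- as.numeric(pattern)
  depth <- ncol(state$hist)
  state$t <- depth
  m <- act_clip(state$x)
  for (s in (depth - cfg$tau_fast + 1L):depth) {
    state$hist[, ((s - 1L) %% depth) + 1L] <- m
  }
  state
}

#' @export
print.memory_state <- function(x, ...) {
  cat("<memory_state> ", x$n, " nodes, t = ", x$t,
      ", active (readout > 0.5): ", sum(act_clip(x$x) > 0.5),
      ", mean depression: ", signif(mean(x$d), 3), "\n", sep = "")
  invisible(x)
}
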