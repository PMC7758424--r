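# Scenario generation. A scenario bundles everything one trial needs:
# the scene (objects, attributes, saliences), the association set encoding
# attribute attractors and episodic chains, the value map, and the
# dynamical configuration of every component. Feature patterns for
# distinct attributes and chain states are non-overlapping one-hot blocks
# by default, which makes attractor encoding exact; a block `overlap`
# parameter is exposed for semantic-similarity experiments.

#' Assemble a scenario
#'
#' Low-level constructor; most users should call [make_scenario()] or
#' [preset_scenario()]. Validates mutual consistency of all components.
#'
#' @param scene A [scene()].
#' @param assoc An [association_set()] with `n == scene$feature_dim`.
#' @param vmap A [value_map()] of the same length.
#' @param mem A [memory_config()].
#' @param acc List of accumulator parameters
#'   (`alpha, beta, gamma, delta, lambda, sigma, threshold, clamp_state`).
#' @param att An [attention_config()].
#' @param input_gain Scale of the attended feature vector as memory input.
#'   Must exceed `mem$leak` so that an attended attribute alone can hold
#'   its attractor at full readout.
#' @param dwell_attr Steps between re-draws of the attended attribute
#'   while attention stays on an object.
#' @param max_steps Trial timeout in steps.
#' @return A list of class `scenario`.
#' @export
scenario <- function(scene, assoc, vmap, mem = memory_config(),
                     acc = list(), att = attention_config(),
                     input_gain = 0.3, dwell_attr = 20L,
                     max_steps = 10000L) {
  acc_defaults <- list(alpha = 0.01, beta = 0, gamma = 0, delta = 0,
                       lambda = 0.001, sigma = 0.01, threshold = 1,
                       clamp_state = FALSE)
  unknown <- setdiff(names(acc), names(acc_defaults))
  if (length(unknown)) {
    stop("unknown accumulator parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  acc <- utils::modifyList(acc_defaults, acc)
  obj <- structure(list(scene = scene, assoc = assoc, vmap = vmap,
                        mem = mem, acc = acc, att = att,
                        input_gain = input_gain,
                        dwell_attr = as.integer(dwell_attr),
                        max_steps = as.integer(max_steps)),
                   class = "scenario")
  validate_scenario(obj)
}

#' Validate a scenario
#'
#' Checks every cross-component invariant: matching dimensions between
#' scene, weights and value map; parameter ranges; that every pattern
#' referenced by the association set is well formed.
#'
#' @param scn A [scenario()].
#' @return The scenario, invisibly unchanged, or an error naming the
#'   violated constraint.
#' @export
validate_scenario <- function(scn) {
  if (!inherits(scn, "scenario")) stop("not a scenario", call. = FALSE)
  if (!inherits(scn$scene, "scene")) stop("scenario$scene must be a scene", call. = FALSE)
  if (!inherits(scn$assoc, "association_set")) {
    stop("scenario$assoc must be an association_set", call. = FALSE)
  }
  if (!inherits(scn$mem, "memory_config")) {
    stop("scenario$mem must be a memory_config", call. = FALSE)
  }
  if (!inherits(scn$att, "attention_config")) {
    stop("scenario$att must be an attention_config", call. = FALSE)
  }
  n <- scn$scene$feature_dim
  if (scn$assoc$n != n) {
    stop("dimension mismatch: scene feature_dim is ", n,
         " but association matrices are ", scn$assoc$n, "x", scn$assoc$n,
         call. = FALSE)
  }
  if (length(scn$vmap) != n) {
    stop("dimension mismatch: value map has length ", length(scn$vmap),
         ", expected ", n, call. = FALSE)
  }
  if (!is.numeric(unclass(scn$vmap))) stop("value map must be numeric", call. = FALSE)
  with(scn$acc, stopifnot(alpha >= 0, beta >= 0, gamma >= 0, delta >= 0,
                          lambda >= 0, sigma >= 0, threshold > 0))
  stopifnot(scn$input_gain >= 0, scn$dwell_attr >= 1L, scn$max_steps >= 1L)
  invisible(scn)
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario>\n")
  print(x$scene)
  vals <- vapply(names(x$assoc$patterns), function(nm) {
    v <- evaluate_value(x$assoc$patterns[[nm]], x$vmap)
    if (v != 0) paste0(nm, "=", signif(v, 3)) else NA_character_
  }, character(1))
  cat("  values at attractors: ",
      paste(vals[!is.na(vals)], collapse = ", "), "\n", sep = "")
  cat("  acc: alpha=", x$acc$alpha, " beta=", x$acc$beta,
      " gamma=", x$acc$gamma, " delta=", x$acc$delta,
      " lambda=", x$acc$lambda, " sigma=", x$acc$sigma,
      " threshold=", x$acc$threshold, "\n", sep = "")
  cat("  att: epsilon=", x$att$epsilon, " phi=", x$att$phi,
      " n=", x$att$n, "\n", sep = "")
  invisible(x)
}

#' Generate a complete scenario
#'
#' Builds a runnable scenario from a compact description: objects at
#' locations `0..n_objects-1`, each with a set of attributes, optional
#' episodic chains, and scalar values attached either to attribute
#' patterns directly (`chain_length = 0`) or to the terminal pattern of an
#' object's episodic chain, so that the stated value is read out exactly
#' at the settled attractor.
#'
#' @param n_objects Number of objects (>= 1).
#' @param attrs_per_object Attributes per object; scalar or one per object.
#'   Objects with an episodic chain must have exactly one attribute (the
#'   chain's start state).
#' @param values Per-object values: a list with one numeric vector per
#'   object (one value per attribute), or a single vector recycled as one
#'   scalar per object. For a chained object the (single) value is placed
#'   on the chain's terminal pattern.
#' @param chain_lengths Episodic transitions required to reach the valued
#'   state; scalar or one per object; 0 = value is immediate.
#' @param feature_dim Total feature dimensionality; `NULL` (default)
#'   allocates exactly enough for all patterns. Too small a value is a
#'   capacity error.
#' @param block_size Features per pattern block (default 1).
#' @param overlap Shared features between consecutively allocated blocks,
#'   `0 <= overlap < block_size`; nonzero values create semantic overlap.
#' @param saliences Per-object salience (recycled; default 1).
#' @param semantic_gain,episodic_gain Recurrent drives for
#'   [encode_attractors()] / [encode_episodic_chain()].
#' @param mem,acc,att Named lists of overrides for [memory_config()],
#'   accumulator parameters and [attention_config()].
#' @param input_gain,dwell_attr,max_steps See [scenario()].
#' @return A validated [scenario()].
#' @export
make_scenario <- function(n_objects = 2, attrs_per_object = 1,
                          values = rep(0.5, n_objects),
                          chain_lengths = 0, feature_dim = NULL,
                          block_size = 1L, overlap = 0L,
                          saliences = 1,
                          semantic_gain = 0.5, episodic_gain = 0.3,
                          mem = list(), acc = list(), att = list(),
                          input_gain = 0.3, dwell_attr = 20L,
                          max_steps = 10000L) {
  n_objects <- as.integer(n_objects)
  stopifnot(n_objects >= 1L)
  attrs <- rep_len(as.integer(attrs_per_object), n_objects)
  chains <- rep_len(as.integer(chain_lengths), n_objects)
  sal <- rep_len(as.numeric(saliences), n_objects)
  block_size <- as.integer(block_size); overlap <- as.integer(overlap)
  stopifnot(all(attrs >= 1L), all(chains >= 0L), block_size >= 1L,
            overlap >= 0L, overlap < block_size)
  if (!is.list(values)) values <- as.list(values)
  if (length(values) != n_objects) {
    stop("values must supply one entry per object", call. = FALSE)
  }
  for (i in seq_len(n_objects)) {
    if (chains[i] > 0L && attrs[i] != 1L) {
      stop("object ", i, ": an episodic chain requires exactly one attribute",
           call. = FALSE)
    }
    if (length(values[[i]]) != (if (chains[i] > 0L) 1L else attrs[i])) {
      stop("object ", i, ": expected ",
           if (chains[i] > 0L) "one terminal value" else
             paste(attrs[i], "attribute value(s)"),
           ", got ", length(values[[i]]), call. = FALSE)
    }
  }

  # allocate one block per pattern: all attributes, then chain states
  n_patterns <- sum(attrs) + sum(chains)
  stride <- block_size - overlap
  need <- stride * (n_patterns - 1L) + block_size
  if (is.null(feature_dim)) feature_dim <- need
  feature_dim <- as.integer(feature_dim)
  if (feature_dim < need) {
    stop("capacity error: ", n_patterns, " patterns of block size ",
         block_size, " (overlap ", overlap, ") need feature_dim >= ", need,
         ", got ", feature_dim, call. = FALSE)
  }
  next_block <- 0L
  take_block <- function() {
    start <- next_block * stride
    next_block <<- next_block + 1L
    p <- numeric(feature_dim)
    p[(start + 1L):(start + block_size)] <- 1
    p
  }

  patterns <- list()
  episodic_chains <- list()
  v <- numeric(feature_dim)
  objects <- vector("list", n_objects)
  obj_ids <- if (n_objects <= 26L) LETTERS[seq_len(n_objects)] else
    paste0("O", seq_len(n_objects))
  for (i in seq_len(n_objects)) {
    atts <- vector("list", attrs[i])
    for (j in seq_len(attrs[i])) {
      p <- take_block()
      nm <- paste0(obj_ids[i], ":a", j)
      patterns[[nm]] <- p
      atts[[j]] <- attribute(paste0("a", j), feature_vector(p))
      if (chains[i] == 0L) v <- v + pattern_value(p, values[[i]][j])
    }
    if (chains[i] > 0L) {
      chain <- list(patterns[[paste0(obj_ids[i], ":a1")]])
      for (k in seq_len(chains[i])) {
        p <- take_block()
        nm <- paste0(obj_ids[i], ":chain", k)
        patterns[[nm]] <- p
        chain[[k + 1L]] <- p
      }
      v <- v + pattern_value(chain[[chains[i] + 1L]], values[[i]][1])
      episodic_chains[[obj_ids[i]]] <- chain
    }
    objects[[i]] <- scene_object(obj_ids[i], location = i - 1L,
                                 attributes = atts, salience = sal[i])
  }

  semantic <- encode_attractors(patterns, gain = semantic_gain)
  episodic <- matrix(0, feature_dim, feature_dim)
  for (ch in episodic_chains) {
    episodic <- episodic + encode_episodic_chain(ch, gain = episodic_gain)
  }

  mem_cfg <- do.call(memory_config, utils::modifyList(
    list(tau_fast = 1L, tau_slow = 25L,
         depression_gain = 0.15, depression_recovery = 0.005,
         leak = 0.2), mem))
  att_cfg <- do.call(attention_config, att)

  scenario(scene = scene(objects, feature_dim),
           assoc = association_set(semantic, episodic, patterns),
           vmap = value_map(v),
           mem = mem_cfg, acc = acc, att = att_cfg,
           input_gain = input_gain, dwell_attr = dwell_attr,
           max_steps = max_steps)
}

#' Calibration of the delayed-reward race
#'
#' The parameter set under which the bundled delayed-reward design
#' (immediate 0.9 vs delayed 1.0) is calibrated so that the preference
#' crossing falls at two episodic transitions. A small forward gain makes
#' trials integrate over many attention dwells (so the value difference,
#' not dwell luck, decides), while the episodic latency per transition is
#' a sizeable fraction of a typical dwell, which is what penalises longer
#' chains; depression is disabled because chain playback is driven by the
#' delayed episodic weights, not by attractor collapse.
#'
#' @return Named list of [make_scenario()] overrides.
#' @export
delayed_reward_calibration <- function() {
  list(mem = list(tau_slow = 7L, depression_gain = 0,
                  depression_recovery = 0, leak = 0.2),
       acc = list(alpha = 0.001, sigma = 0.002, lambda = 0.0005),
       att = list(epsilon = 0.025),
       max_steps = 20000L)
}

#' Bundled scenario presets
#'
#' Ready-made scenarios for the standard simulation designs. Printed
#' stimulus values (0.4/0.6, 0.2/0.8, mirrored 0.2/0.3, 0.9 vs 1.0),
#' the decision threshold of 1 and the contrast exponent n = 2 are fixed;
#' all dynamical gains are this package's calibration.
#'
#' \describe{
#'   \item{two_choice}{Two single-attribute objects valued 0.4 and 0.6.}
#'   \item{two_choice_wide}{As above with values 0.2 and 0.8.}
#'   \item{multi_attribute}{Two objects, two attributes each, values
#'     0.2/0.3 for A and 0.3/0.2 for B (a symmetric summation test).}
#'   \item{delay_race}{Both objects valued 1.0; A immediate, B behind an
#'     episodic chain (default 3 transitions).}
#'   \item{delayed_reward}{Immediate value 0.9 (A) vs delayed value 1.0
#'     (B) behind an episodic chain (default 2 transitions).}
#'   \item{feedback_attention}{As `two_choice` with top-down attention
#'     feedback enabled (phi = 100).}
#' }
#'
#' @param name Preset name.
#' @param ... Overrides forwarded to [make_scenario()]
#'   (e.g. `acc = list(sigma = 0.02)`, `chain_lengths = c(0, 5)`).
#' @return A [scenario()].
#' @export
preset_scenario <- function(name = c("two_choice", "two_choice_wide",
                                     "multi_attribute", "delay_race",
                                     "delayed_reward",
                                     "feedback_attention"),
                            ...) {
  name <- match.arg(name)
  twochoice_cal <- list(acc = list(sigma = 0.01, lambda = 0.003),
                        att = list(epsilon = 0.05))
  base <- switch(name,
    two_choice = c(list(n_objects = 2, attrs_per_object = 1,
                        values = list(0.4, 0.6)), twochoice_cal),
    two_choice_wide = c(list(n_objects = 2, attrs_per_object = 1,
                             values = list(0.2, 0.8)), twochoice_cal),
    multi_attribute = list(n_objects = 2, attrs_per_object = 2,
                           values = list(c(0.2, 0.3), c(0.3, 0.2))),
    delay_race = c(list(n_objects = 2, attrs_per_object = 1,
                        values = list(1, 1), chain_lengths = c(0, 3)),
                   delayed_reward_calibration()),
    delayed_reward = c(list(n_objects = 2, attrs_per_object = 1,
                            values = list(0.9, 1), chain_lengths = c(0, 2)),
                       delayed_reward_calibration()),
    feedback_attention = list(n_objects = 2, attrs_per_object = 1,
                              values = list(0.4, 0.6),
                              acc = list(sigma = 0.01, lambda = 0.003),
                              att = list(epsilon = 0.05, phi = 100)))
  args <- utils::modifyList(base, list(...))
  do.call(make_scenario, args)
}
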