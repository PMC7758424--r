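# Trial engine. One simulation step wires the components together:
# attention (maybe shift, sample an attribute) -> memory step driven by the
# attended feature vector -> readout -> valuation -> accumulator step gated
# by the attended location -> decision check. A decision locks attention,
# resets the accumulators and ends the trial; hitting max_steps is a
# timeout, reported as a result rather than an error.
#
# Two interchangeable engines run this loop: a compiled one (default) and
# a pure-R reference that documents the algorithm. Both consume R's RNG
# stream in the identical order, so they are bit-for-bit reproducible
# against each other under the same seed.

# flatten a scenario into the plain vectors/matrices the engines consume
build_plan <- function(scn) {
  validate_scenario(scn)
  sc <- scn$scene
  n <- sc$feature_dim
  s <- salience_vector(sc)
  L <- length(s)
  n_attrs <- sum(vapply(sc$objects, function(o) length(o$attributes), integer(1)))
  feat <- matrix(0, n, n_attrs)
  attr_start <- integer(L); attr_count <- integer(L)
  col <- 0L
  for (ob in sc$objects) {
    attr_start[ob$location + 1L] <- col
    attr_count[ob$location + 1L] <- length(ob$attributes)
    for (at in ob$attributes) {
      col <- col + 1L
      feat[, col] <- as.numeric(at$features)
    }
  }
  obj_loc <- vapply(sc$objects, `[[`, integer(1), "location")
  list(n = n, L = L, s = s, feat = feat,
       attr_start = attr_start, attr_count = attr_count,
       obj_loc = obj_loc,
       v = as.numeric(scn$vmap),
       Ws = scn$assoc$semantic, We = scn$assoc$episodic,
       dt = scn$mem$dt, tau_fast = scn$mem$tau_fast,
       tau_slow = scn$mem$tau_slow,
       dep_gain = scn$mem$depression_gain,
       dep_rec = scn$mem$depression_recovery,
       mem_leak = scn$mem$leak, mem_noise = scn$mem$noise,
       alpha = scn$acc$alpha, beta = scn$acc$beta,
       gamma = scn$acc$gamma, delta = scn$acc$delta,
       lambda = scn$acc$lambda, sigma = scn$acc$sigma,
       threshold = scn$acc$threshold,
       clamp_state = scn$acc$clamp_state,
       epsilon = scn$att$epsilon, phi = scn$att$phi,
       ncontrast = scn$att$n,
       input_gain = scn$input_gain, dwell_attr = scn$dwell_attr,
       max_steps = scn$max_steps)
}

#' Run a single decision trial
#'
#' Simulates one trial of the full model until an accumulator crosses the
#' decision threshold (a choice) or `max_steps` elapse (a timeout).
#'
#' @param scn A [scenario()].
#' @param seed Optional integer; when given, `set.seed(seed)` is applied
#'   so the trial is fully reproducible, traces included.
#' @param engine `"compiled"` (default) or `"reference"`; the pure-R
#'   reference engine is draw-for-draw identical to the compiled one.
#' @param traces If TRUE, per-step time series are returned: accumulator
#'   states, memory readout, attended location and value signal.
#' @return A list of class `trial_result` with elements `choice` (0-based
#'   location, `NA` on timeout), `rt` (steps, `NA` on timeout), `dwell`
#'   (attended steps per location), `steps`, and optional traces.
#' @export
run_trial <- function(scn, seed = NULL, engine = c("compiled", "reference"),
                      traces = FALSE) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  res <- if (engine == "compiled") {
    cpp_run_trial(build_plan(scn), isTRUE(traces))
  } else {
    run_trial_reference(scn, traces = isTRUE(traces))
  }
  res$choice <- if (res$choice < 0) NA_integer_ else as.integer(res$choice)
  res$rt <- if (res$rt < 0) NA_integer_ else as.integer(res$rt)
  structure(res, class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  if (is.na(x$choice)) {
    cat("<trial_result> timeout after ", x$steps, " steps\n", sep = "")
  } else {
    cat("<trial_result> choice: location ", x$choice,
        ", rt = ", x$rt, " steps\n", sep = "")
  }
  cat("  dwell per location: ", paste(x$dwell, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Pure-R engine; the algorithmic source of truth the compiled engine is
# tested against. Uses the module-level operations step by step.
run_trial_reference <- function(scn, traces = FALSE) {
  plan <- build_plan(scn)
  L <- plan$L
  mem_cfg <- scn$mem
  mstate <- memory_state(plan$n, mem_cfg)
  bank <- accumulator_bank(L, alpha = plan$alpha, beta = plan$beta,
                           gamma = plan$gamma, delta = plan$delta,
                           lambda = plan$lambda, sigma = plan$sigma,
                           dt = plan$dt, clamp_state = plan$clamp_state)
  att_cfg <- scn$att
  assoc <- scn$assoc

  sample_col <- function(loc) {
    k <- plan$attr_count[loc + 1L]
    idx <- floor(stats::runif(1) * k)
    if (idx >= k) idx <- k - 1L
    plan$attr_start[loc + 1L] + idx
  }

  u0 <- stats::runif(1)
  oi <- min(floor(u0 * length(plan$obj_loc)), length(plan$obj_loc) - 1L)
  astate <- attention_state(current = plan$obj_loc[oi + 1L])
  attr_col <- sample_col(astate$current)
  dwell_steps <- 0L
  dwell <- integer(L)
  choice <- -1L; rt <- -1L; steps_run <- 0L
  if (traces) {
    acc_tr <- matrix(NA_real_, plan$max_steps, L)
    mem_tr <- matrix(NA_real_, plan$max_steps, plan$n)
    att_tr <- integer(plan$max_steps)
    v_tr <- numeric(plan$max_steps)
  }

  for (t in seq_len(plan$max_steps)) {
    if (!astate$locked) {
      g <- pmax(bank$x, 0)
      p <- switch_probabilities(plan$s, g, att_cfg)
      ms <- maybe_shift(astate, p)
      astate <- ms$state
      if (ms$shifted) {
        mstate <- memory_reset(mstate)
        attr_col <- sample_col(astate$current)
        dwell_steps <- 0L
      }
    }
    dwell[astate$current + 1L] <- dwell[astate$current + 1L] + 1L
    dwell_steps <- dwell_steps + 1L
    if (dwell_steps >= plan$dwell_attr) {
      attr_col <- sample_col(astate$current)
      dwell_steps <- 0L
    }

    input <- plan$input_gain * plan$feat[, attr_col + 1L]
    mstate <- memory_step(mstate, input, assoc, mem_cfg)
    m <- memory_readout(mstate)
    V <- evaluate_value(m, plan$v)

    bank <- acc_step(bank, V, astate$current + 1L)

    if (traces) {
      acc_tr[t, ] <- bank$x
      mem_tr[t, ] <- m
      att_tr[t] <- astate$current
      v_tr[t] <- V
    }
    steps_run <- t

    winner <- check_decision(bank, plan$threshold)
    if (!is.na(winner)) {
      choice <- winner - 1L
      rt <- t
      astate <- lock_attention(astate, choice)
      bank <- reset_bank(bank)
      break
    }
  }

  out <- list(choice = choice, rt = rt, dwell = dwell, steps = steps_run)
  if (traces) {
    out$acc_trace <- acc_tr[seq_len(steps_run), , drop = FALSE]
    out$mem_trace <- mem_tr[seq_len(steps_run), , drop = FALSE]
    out$att_trace <- att_tr[seq_len(steps_run)]
    out$v_trace <- v_tr[seq_len(steps_run)]
  }
  out
}

#' Run a batch of independent trials
#'
#' Trial i uses seed `base_seed + i - 1`, so any individual trial can be
#' reproduced in isolation with [run_trial()].
#'
#' @param scn A [scenario()].
#' @param n Number of trials (>= 1).
#' @param base_seed Integer seed of the first trial.
#' @param engine Passed to [run_trial()].
#' @return An `experiment_summary`: per-alternative choice probabilities
#'   over decided trials, RT summaries, timeout count, and the per-trial
#'   table (`$trials`: seed, choice, rt, dwell share per location).
#' @export
run_trials <- function(scn, n, base_seed = 1L, engine = "compiled") {
  stopifnot(n >= 1L)
  plan_L <- length(salience_vector(scn$scene))
  choice <- integer(n); rt <- integer(n)
  dwell <- matrix(0L, n, plan_L)
  for (i in seq_len(n)) {
    tr <- run_trial(scn, seed = base_seed + i - 1L, engine = engine)
    choice[i] <- tr$choice
    rt[i] <- tr$rt
    dwell[i, ] <- tr$dwell
  }
  summarize_trials(data.frame(seed = base_seed + seq_len(n) - 1L,
                              choice = choice, rt = rt),
                   dwell, scn)
}

summarize_trials <- function(trials, dwell, scn) {
  locs <- vapply(scn$scene$objects, `[[`, integer(1), "location")
  ids <- vapply(scn$scene$objects, `[[`, character(1), "id")
  decided <- !is.na(trials$choice)
  n_dec <- sum(decided)
  tab <- data.frame(object = ids, location = locs,
                    n_chosen = vapply(locs, function(l)
                      sum(trials$choice[decided] == l), integer(1)))
  tab$p_choice <- if (n_dec > 0) tab$n_chosen / n_dec else NA_real_
  tab$mean_rt <- vapply(locs, function(l) {
    r <- trials$rt[decided & trials$choice == l]
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  tab$median_rt <- vapply(locs, function(l) {
    r <- trials$rt[decided & trials$choice == l]
    if (length(r)) stats::median(r) else NA_real_
  }, numeric(1))
  structure(list(summary = tab, trials = trials, dwell = dwell,
                 n_trials = nrow(trials), n_decided = n_dec,
                 n_timeout = nrow(trials) - n_dec),
            class = "experiment_summary")
}

#' @export
print.experiment_summary <- function(x, ...) {
  cat("<experiment_summary> ", x$n_trials, " trial(s), ",
      x$n_timeout, " timeout(s)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# parameter name -> (component, field) used by sweep_parameter
sweepable_params <- function() {
  list(sigma = c("acc", "sigma"), beta = c("acc", "beta"),
       gamma = c("acc", "gamma"), delta = c("acc", "delta"),
       lambda = c("acc", "lambda"), alpha = c("acc", "alpha"),
       phi = c("att", "phi"), epsilon = c("att", "epsilon"),
       input_gain = c("top", "input_gain"),
       dwell_attr = c("top", "dwell_attr"))
}

set_scenario_param <- function(scn, param, value) {
  map <- sweepable_params()
  if (!param %in% names(map)) {
    stop("unknown sweep parameter '", param, "'; one of: ",
         paste(names(map), collapse = ", "), call. = FALSE)
  }
  slot <- map[[param]]
  if (slot[1] == "top") {
    scn[[slot[2]]] <- value
  } else if (slot[1] == "att") {
    args <- unclass(scn$att); args[[slot[2]]] <- value
    scn$att <- do.call(attention_config, args)
  } else {
    scn$acc[[slot[2]]] <- value
  }
  validate_scenario(scn)
  scn
}

#' Sweep one parameter over a grid
#'
#' Runs `n` trials at each value of `values` with every other parameter
#' held fixed; trial seeds restart at `base_seed` for each grid point so
#' grid points differ only in the swept parameter.
#'
#' @param scn Base [scenario()].
#' @param param One of `sigma, beta, gamma, delta, lambda, alpha, phi,
#'   epsilon, input_gain, dwell_attr`.
#' @param values Numeric grid.
#' @param n Trials per value.
#' @param base_seed Seed of the first trial at each value.
#' @param engine Passed to [run_trial()].
#' @return A list of class `parameter_sweep`: one `experiment_summary`
#'   per value (named by value), plus `$param` and `$values`.
#' @export
sweep_parameter <- function(scn, param, values, n, base_seed = 1L,
                            engine = "compiled") {
  stopifnot(length(values) >= 1L)
  out <- vector("list", length(values))
  for (i in seq_along(values)) {
    out[[i]] <- run_trials(set_scenario_param(scn, param, values[i]),
                           n = n, base_seed = base_seed, engine = engine)
  }
  names(out) <- as.character(values)
  structure(list(summaries = out, param = param, values = values),
            class = "parameter_sweep")
}

#' Flatten a sweep into one table
#'
#' @param sw A [sweep_parameter()] result.
#' @return Data frame with one row per parameter value x alternative.
#' @export
sweep_table <- function(sw) {
  stopifnot(inherits(sw, "parameter_sweep"))
  do.call(rbind, lapply(seq_along(sw$values), function(i) {
    tab <- sw$summaries[[i]]$summary
    cbind(param = sw$param, value = sw$values[i], tab,
          n_timeout = sw$summaries[[i]]$n_timeout)
  }))
}

#' @export
print.parameter_sweep <- function(x, ...) {
  cat("<parameter_sweep> ", x$param, " over {",
      paste(x$values, collapse = ", "), "}\n", sep = "")
  print(sweep_table(x), row.names = FALSE)
  invisible(x)
}

#' Implicit-discounting break-point
#'
#' Races an immediately valued option against a larger reward hidden
#' behind k episodic transitions, for k = 0..`max_chain`. Because a longer
#' chain delays and interrupts delivery of value to its accumulator, the
#' delayed option's choice probability falls with k even though no
#' discount factor exists anywhere in the configuration. Returns the
#' smallest k at which preference for the delayed option drops below 0.5,
#' with a bootstrap confidence interval.
#'
#' @param value_immediate Value of the immediate option (< `value_delayed`).
#' @param value_delayed Value of the delayed option.
#' @param max_chain Longest chain tested.
#' @param n Trials per chain length.
#' @param base_seed Seed of the first trial at each chain length.
#' @param scenario_args Named list of overrides forwarded to
#'   [make_scenario()] (calibration of gains, attention, noise).
#' @param n_boot Bootstrap replicates for the CI.
#' @param conf Confidence level (default 0.95).
#' @param engine Passed to [run_trial()].
#' @return A list of class `discounting_breakpoint`: `$breakpoint`
#'   (smallest k with P(delayed) < 0.5, or `NA` if no crossing),
#'   `$ci` (bootstrap percentile interval), and `$table`
#'   (k, p_delayed, mean RT, timeouts).
#' @export
discounting_breakpoint <- function(value_immediate = 0.9,
                                   value_delayed = 1.0,
                                   max_chain = 9L, n = 1000L,
                                   base_seed = 1L,
                                   scenario_args = list(),
                                   n_boot = 1000L, conf = 0.95,
                                   engine = "compiled") {
  stopifnot(value_immediate < value_delayed, max_chain >= 1L)
  ks <- 0:max_chain
  p_delayed <- numeric(length(ks))
  n_dec <- integer(length(ks))
  n_del <- integer(length(ks))
  mean_rt <- numeric(length(ks))
  n_to <- integer(length(ks))
  for (i in seq_along(ks)) {
    args <- utils::modifyList(
      list(n_objects = 2, attrs_per_object = 1,
           values = list(value_immediate, value_delayed),
           chain_lengths = c(0L, ks[i])),
      scenario_args)
    scn <- do.call(make_scenario, args)
    sm <- run_trials(scn, n = n, base_seed = base_seed, engine = engine)
    dec <- !is.na(sm$trials$choice)
    n_dec[i] <- sum(dec)
    n_del[i] <- sum(sm$trials$choice[dec] == 1L)
    p_delayed[i] <- if (n_dec[i] > 0) n_del[i] / n_dec[i] else NA_real_
    mean_rt[i] <- mean(sm$trials$rt[dec])
    n_to[i] <- sm$n_timeout
  }
  crossing <- function(p) {
    below <- which(p < 0.5)
    if (length(below)) ks[below[1]] else NA_integer_
  }
  bp <- crossing(p_delayed)
  boot <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    pb <- stats::rbinom(length(ks), n_dec, p_delayed) / n_dec
    boot[b] <- crossing(pb)
  }
  a <- (1 - conf) / 2
  ci <- stats::quantile(boot, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  structure(list(breakpoint = bp, ci = ci, boot = boot,
                 table = data.frame(k = ks, p_delayed = p_delayed,
                                    n_decided = n_dec, mean_rt = mean_rt,
                                    n_timeout = n_to)),
            class = "discounting_breakpoint")
}

#' @export
print.discounting_breakpoint <- function(x, ...) {
  if (is.na(x$breakpoint)) {
    cat("<discounting_breakpoint> no crossing below 0.5 in the tested range\n")
  } else {
    cat("<discounting_breakpoint> preference crosses 0.5 at k = ",
        x$breakpoint, " (", length(x$boot), "-rep bootstrap CI [",
        x$ci[1], ", ", x$ci[2], "])\n", sep = "")
  }
  print(x$table, row.names = FALSE)
  invisible(x)
}
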