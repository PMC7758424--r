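# shared test utilities

skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

# one-hot pattern of length n with a single active block
one_hot <- function(n, idx) {
  p <- numeric(n)
  p[idx] <- 1
  p
}

# run the memory network freely for n steps, returning the readout matrix
run_memory <- function(state, assoc, cfg, n_steps, input = numeric(state$n)) {
  out <- matrix(NA_real_, n_steps, state$n)
  for (t in seq_len(n_steps)) {
    state <- memory_step(state, input, assoc, cfg)
    out[t, ] <- memory_readout(state)
  }
  list(state = state, readouts = out)
}

# first step at which the readout matches `pattern` (and nothing outside it)
# at the given activity threshold; NA if never
first_match <- function(readouts, pattern, thr = 0.8) {
  on <- pattern > 0
  hit <- apply(readouts, 1, function(m) all(m[on] >= thr) && all(m[!on] < thr))
  w <- which(hit)
  if (length(w)) w[1] else NA_integer_
}

# ordered distinct pattern visits in a readout trace
visit_order <- function(readouts, patterns, thr = 0.8) {
  lab <- apply(readouts, 1, function(m) {
    for (k in seq_along(patterns)) {
      on <- patterns[[k]] > 0
      if (all(m[on] >= thr) && all(m[!on] < thr)) return(k)
    }
    NA_integer_
  })
  lab <- lab[!is.na(lab)]
  lab[c(TRUE, diff(lab) != 0)]
}

# mean fraction of pre-decision dwell spent on the finally chosen location
mean_dwell_share_chosen <- function(summary) {
  tr <- summary$trials
  dec <- !is.na(tr$choice)
  shares <- summary$dwell[cbind(seq_len(nrow(summary$dwell)),
                                tr$choice + 1L)] / rowSums(summary$dwell)
  mean(shares[dec])
}
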