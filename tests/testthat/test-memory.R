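# Dynamics of the recurrent memory component: attractor encoding,
# depression-driven latching, delayed episodic sequence replay.

p4 <- function(i) one_hot(4, (2 * i - 1):(2 * i)) # 2-node blocks in N=4
p8 <- function(i) one_hot(8, (2 * i - 1):(2 * i)) # 2-node blocks in N=8

test_that("encoded patterns are fixed points of the undepressed dynamics", {
  cfg <- memory_config(leak = 0.2)
  pats <- list(p4(1), p4(2))
  assoc <- association_set(encode_attractors(pats, gain = 0.5))
  for (p in pats) {
    st <- memory_init(memory_state(4, cfg), p, cfg)
    r <- run_memory(st, assoc, cfg, 100)
    expect_true(all(r$readouts[, p > 0] >= 0.99))
    expect_true(all(r$readouts[, p == 0] == 0))
  }
})

test_that("with no stored patterns the state decays to zero", {
  cfg <- memory_config(leak = 0.2)
  w <- encode_attractors(list(), n_nodes = 3)
  expect_identical(w, matrix(0, 3, 3))
  st <- memory_init(memory_state(3, cfg), c(1, 1, 1), cfg)
  r <- run_memory(st, association_set(w), cfg, 100)
  expect_lt(max(r$readouts[100, ]), 1e-6)
})

test_that("an attractor persists without depression and zero weights hold zero", {
  cfg <- memory_config(leak = 0.2, depression_gain = 0)
  assoc <- association_set(encode_attractors(list(p4(1)), gain = 0.5))
  st <- memory_init(memory_state(4, cfg), p4(1), cfg)
  r <- run_memory(st, assoc, cfg, 1000)
  expect_true(all(r$readouts[, p4(1) > 0] >= 0.99))
  # all-zero weights, zero input, zero state: exact fixed point
  z <- memory_state(2, cfg)
  z <- memory_step(z, c(0, 0), association_set(matrix(0, 2, 2)), cfg)
  expect_identical(z$x, c(0, 0))
})

test_that("with zero weights the state is the cumulative integral of the input", {
  cfg <- memory_config(leak = 0)
  assoc <- association_set(matrix(0, 3, 3))
  st <- memory_state(3, cfg)
  I <- c(0.25, 0.5, 0) # dyadic, so the Euler ramp is exact
  for (t in 1:10) {
    st <- memory_step(st, I, assoc, cfg)
    expect_identical(st$x, I * t)
  }
})

test_that("episodic chains replay in order with the slow latency", {
  cfg <- memory_config(tau_slow = 25, leak = 0.2,
                       depression_gain = 0.2, depression_recovery = 0.002)
  pats <- list(p8(1), p8(2))
  assoc <- association_set(
    encode_attractors(pats, gain = 0.5),
    encode_episodic_chain(pats, gain = 0.3))
  st <- memory_init(memory_state(8, cfg), pats[[1]], cfg)
  r <- run_memory(st, assoc, cfg, 200)
  hit <- first_match(r$readouts, pats[[2]])
  # successor becomes the exclusive readout about tau_slow + settling later
  expect_false(is.na(hit))
  expect_gte(hit, cfg$tau_slow)
  expect_lte(hit, cfg$tau_slow + 40)
})

test_that("a chain of length L is visited as L distinct states, in order", {
  cfg <- memory_config(tau_slow = 25, leak = 0.2,
                       depression_gain = 0.25, depression_recovery = 0.002)
  pats <- lapply(1:4, function(i) one_hot(8, (2 * i - 1):(2 * i)))
  assoc <- association_set(
    encode_attractors(pats, gain = 0.5),
    encode_episodic_chain(pats, gain = 0.3))
  st <- memory_init(memory_state(8, cfg), pats[[1]], cfg)
  r <- run_memory(st, assoc, cfg, 300)
  expect_identical(visit_order(r$readouts, pats), 1:4)
  # reversing the chain transposes the hetero-associative weights
  expect_identical(encode_episodic_chain(rev(pats), gain = 0.3),
                   t(encode_episodic_chain(pats, gain = 0.3)))
})

test_that("synaptic depression latches the state from one attractor to the next", {
  cfg <- memory_config(leak = 0.2,
                       depression_gain = 0.2, depression_recovery = 0.002)
  pats <- list(A = p4(1), B = p4(2))
  w <- encode_attractors(pats, gain = 0.5) +
    0.2 * (pats$B %o% pats$A) / sum(pats$A) # fast association A -> B
  st <- memory_init(memory_state(4, cfg), pats$A, cfg)
  r <- run_memory(st, association_set(w), cfg, 150)
  expect_identical(visit_order(r$readouts, pats), 1:2)
  # depression stays within [0, 1] throughout a long aggressive run
  cfg2 <- memory_config(leak = 0.1, depression_gain = 2,
                        depression_recovery = 0.5)
  st2 <- memory_init(memory_state(4, cfg2), pats$A, cfg2)
  for (t in 1:500) {
    st2 <- memory_step(st2, 0.5 * pats$A, association_set(w), cfg2)
    expect_true(all(st2$d >= 0 & st2$d <= 1))
  }
})

test_that("folding episodic weights into the semantic matrix at equal delays is exact", {
  pats <- list(p8(1), p8(2), p8(3))
  Ws <- encode_attractors(pats, gain = 0.5)
  We <- encode_episodic_chain(pats, gain = 0.25)
  I <- 0.25 * pats[[1]]
  # dyadic weights, no leak, no depression: bit-for-bit identical
  cfg <- memory_config(tau_fast = 3, tau_slow = 3, leak = 0)
  st1 <- memory_state(8, cfg); st2 <- memory_state(8, cfg)
  a1 <- association_set(Ws, We)
  a2 <- association_set(Ws + We, matrix(0, 8, 8))
  for (t in 1:40) {
    st1 <- memory_step(st1, I, a1, cfg)
    st2 <- memory_step(st2, I, a2, cfg)
    expect_identical(st1$x, st2$x)
  }
  # with depression and leak active the equivalence holds analytically;
  # only summation order differs, so agreement is to float tolerance
  cfgd <- memory_config(tau_fast = 3, tau_slow = 3, leak = 0.2,
                        depression_gain = 0.2, depression_recovery = 0.002)
  st1 <- memory_state(8, cfgd); st2 <- memory_state(8, cfgd)
  for (t in 1:120) {
    st1 <- memory_step(st1, I, a1, cfgd)
    st2 <- memory_step(st2, I, a2, cfgd)
  }
  expect_equal(st1$x, st2$x, tolerance = 1e-12)
  expect_equal(st1$d, st2$d, tolerance = 1e-12)
})

test_that("reset clears activity and history but depression persists", {
  cfg <- memory_config(leak = 0.2, depression_gain = 0.2,
                       depression_recovery = 0.002)
  pats <- list(p4(1), p4(2))
  assoc <- association_set(encode_attractors(pats, gain = 0.5))
  st <- memory_init(memory_state(4, cfg), pats[[1]], cfg)
  st <- run_memory(st, assoc, cfg, 20)$state
  d_before <- st$d
  st <- memory_reset(st)
  expect_identical(st$x, numeric(4))
  expect_identical(st$t, 0L)
  expect_true(all(st$hist == 0))
  expect_identical(st$d, d_before)
  # quiescent after reset with no input
  st0 <- memory_step(st, numeric(4), assoc, cfg)
  expect_identical(st0$x, numeric(4))
  # re-presenting an attribute re-enters its attractor (second pattern is
  # fresh, its connections undepressed)
  r <- run_memory(st, assoc, cfg, 30, input = 0.3 * pats[[2]])
  expect_true(all(r$readouts[30, pats[[2]] > 0] >= 0.99))
})

test_that("readout is the clipped activation and is monotone", {
  cfg <- memory_config()
  st <- memory_state(4, cfg)
  expect_identical(memory_readout(st), numeric(4))
  st$x <- c(-1, 0.25, 0.5, 7)
  expect_identical(memory_readout(st), c(0, 0.25, 0.5, 1))
  st2 <- st; st2$x <- st$x + 0.25
  expect_true(all(memory_readout(st2) >= memory_readout(st)))
  # dimension errors are structural
  expect_error(memory_step(st, numeric(3),
                           association_set(matrix(0, 4, 4)), cfg),
               "mismatch")
  expect_error(encode_attractors(list(c(1, 0), c(1, 0, 0))), "same length")
  expect_error(encode_episodic_chain(list(c(1, 0))), "at least 2")
})
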