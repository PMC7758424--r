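---
title: "Memory-guided evidence accumulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Memory-guided evidence accumulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `accumem`, the choices
made where the design was genuinely open, the calibration of the bundled
presets, and what the simulations do and do not show.

## The model in brief

A trial couples five processes on a common clock (one simulation step is
the time unit; all dynamics are integrated by explicit Euler with
`dt = 1`):

* **Scanning.** Attention is on one object at a time. One of its
  attributes is sampled uniformly and held for `dwell_attr` steps
  (default 20), then re-drawn. The attended attribute's binary feature
  vector, scaled by `input_gain` (default 0.3), is the external input to
  the memory network.
* **Memory.** Feature nodes form a recurrent network with two connection
  classes. Semantic weights act at latency `tau_fast` (default 1 step) and
  implement attractors via Hebbian outer-product encoding; each stored
  pattern is a non-overlapping one-hot block, so encoding is exact.
  Episodic weights act at latency `tau_slow` (default 25 steps) and are
  hetero-associative (pattern k drives pattern k+1), replaying stored
  sequences. Per-connection synaptic depression grows with the signal
  through the connection and recovers slowly, collapsing occupied
  attractors (latching). The node activation is the saturating
  piecewise-linear f(x) = clip(x, 0, 1); the readout is m = f(x).
* **Valuation.** V = v·mᵀ. Scenario statements such as "the value of A is
  0.4" are realised by spreading 0.4 over the nodes of A's pattern (or of
  the terminal pattern of A's episodic chain), so the settled attractor
  reads out the stated value exactly.
* **Accumulation.** One leaky competing accumulator per location. The
  value signal is gated to the attended location; forward excitation
  `alpha` drives the attended accumulator and forward inhibition `beta`
  suppresses the others, feedback excitation `gamma` and lateral feedback
  inhibition `delta` act on the ReLU outputs, `lambda` is the leak and
  `sigma` the per-step Gaussian noise (scaled by sqrt(dt)). A decision
  fires when any accumulator reaches threshold 1 (exact ties are broken
  uniformly at random); the decision layer then resets the bank and locks
  attention on the winner.
* **Attention.** Each step, with total probability `epsilon`, attention
  switches to location i in proportion to s_i + φ·g_iⁿ, where s is binary
  salience, g the accumulators' ReLU output, φ the top-down gain and
  n = 2 a contrast exponent. A shift resets the memory state (activation
  and delay history; depression, being a property of the connections,
  persists). A draw that lands on the currently attended location counts
  as a dwell continuation — no reset, no attribute re-draw.

## Design choices where the dynamics were under-determined

**Leak on the memory state.** The memory equation as stated has no decay
term in x, but without one, activation can only grow (all weights are
nonnegative), attractors can never dissolve, and neither latching nor
sequence hand-over is possible. We therefore expose `leak` (default 0 at
the module level, 0.2 in all generated scenarios): an attended attribute
(`input_gain` 0.3 > leak at readout 1) or a healthy attractor
(recurrent drive 0.5) holds its state, while an unsupported or depressed
state relaxes within a few steps.

**Depression rule.** Only the direction ("grows with the signal through
the connection") is prescribed. We use a Tsodyks-style resource equation,
d′ = gain·s·(1−d) − recovery·d clipped to [0, 1], with the per-connection
signal s = w_ji·f(x_j(t−τ_ji)) summed over both weight matrices. Driving
depression by the *delayed* presynaptic readout (matching each
connection's own latency) makes a two-matrix network with equal latencies
*exactly* equivalent to the single matrix holding the summed weights —
an identity the test suite checks bit-for-bit in a dyadic-weight setting
and to 1e-12 with depression and leak active.

**Inhibitory sign convention.** All four accumulator gains are stored
nonnegative; β and δ enter the update with explicit minus signs, as
pathways through an inhibitory inter-node.

**Accumulator state vs output.** Only the outputs pass through the ReLU;
the state itself may go negative (forward inhibition can push a competitor
below zero) unless `clamp_state` is enabled. This is the default because
it keeps the published update equation literal.

**Discrete-time leak.** A unit Euler step maps the continuous leak onto
the discrete reading x ← (1 − λ·dt)·x + …, i.e. λ_discrete = 1 − λ·dt;
"leakier" always means larger λ here.

## Numerical choices

* Delays are ring buffers of past readouts in whole steps, depth
  `tau_slow`; reads before trial start return zeros.
* Cueing a pattern (`memory_init`) seeds the history only back to the
  fast latency, so semantic support is immediate while episodic drive
  begins `tau_slow` steps after the cue.
* Exact-crossing oracles use dyadic increments (e.g. V = 0.125, so the
  ramp crosses threshold 1 at exactly step 8): repeated addition of a
  non-dyadic increment such as 0.1 lands an epsilon *below* the threshold
  at the nominal crossing step, which would make an "exact step" assertion
  a test of rounding rather than of the dynamics.
* Non-finite states abort a trial with the offending step index; a trial
  that reaches `max_steps` (default 10,000; 20,000 for the delayed-reward
  preset) is a *timeout*, reported separately and excluded from RT
  summaries.
* Degenerate scenes (no salience and no feedback anywhere) are an error,
  not a silent stall.
* Batches seed trial i with `base_seed + i − 1`, so any single trial can
  be re-run in isolation; the compiled and reference engines consume the
  R random stream in the same order and agree bit-for-bit.

## What the scenario generator emulates — and what it does not

`make_scenario()` builds the stimulus worlds used throughout: objects at
distinct locations with binary-salience presence, orthogonal one-hot-block
feature patterns (an `overlap` parameter permits semantically similar
patterns, unused by the presets), optional episodic chains, and a value
map consistent with the stated object values. This captures the
*structure* of the modelled tasks — multi-attribute objects, indirect
valuation, sequence-mediated reward — but not real perception: there is no
image processing, no graded visual salience, no feature noise, and no
learning (all associations are pre-set). Passing tests therefore
demonstrate properties of the decision architecture, not fidelity to any
particular empirical dataset.

## Preset calibration

Quantitative outcomes depend on the interaction of all gains, so the
bundled presets fix one calibrated operating point each; the stimulus
values they encode (0.4/0.6, 0.2/0.8, mirrored 0.2/0.3, 0.9 vs 1.0,
threshold 1, n = 2) are part of the task definitions.

* `two_choice` (and variants): `alpha` 0.01, `sigma` 0.01, `lambda`
  0.003, `epsilon` 0.05. The leak is large enough that the mean drive
  saturates below threshold and crossings are fluctuation-driven: this is
  the regime that yields right-skewed RT distributions with slower, more
  variable errors, while leaving clean monotone responses to `sigma`
  (more noise → choices toward 0.5, faster), `beta` (slower but more
  accurate), `gamma` (faster) and φ (faster, more dwell on the eventual
  choice).
* `delayed_reward` / `delay_race` (`delayed_reward_calibration()`):
  `alpha` 0.001, `sigma` 0.002, `lambda` 0.0005, `epsilon` 0.025,
  `tau_slow` 7, depression off. A small forward gain makes each trial
  integrate over many attention dwells, so the 0.9 vs 1.0 value
  difference — not dwell luck — decides at chain length 0, while each
  episodic transition costs a sizeable fraction of a typical dwell. At
  this operating point the preference for the larger delayed reward
  crosses 0.5 at two episodic transitions. Depression is disabled because
  chain playback is driven by the delayed weights; the attended start
  state is meant to keep re-seeding the sequence.

## Problem sizes

The behavioural suites run 1,000–2,000 trials per condition (2,000 for
the symmetric summation and RT-shape checks; 1,000 per chain length for
the discounting curve with a 1,000-replicate bootstrap; 1,000 per grid
point for the σ, β and φ sweeps), sizes at which three binomial standard
errors are ≈ 0.03–0.05 and every trend assertion has comfortable margin.
Memory-level checks use networks of 4–8 nodes where every attractor and
chain event is individually inspectable.

## Known limitations

* No learning of any kind: values, semantic and episodic structures are
  pre-set inputs.
* Salience is binary; there is no image-based salience and no
  memory-to-perception priming, value-to-memory or value-to-attention
  pathway.
* Arousal modulation of memory-state randomness is stubbed as an optional
  additive-noise hook (default 0) and not studied.
* A single calibration point per preset: the package makes no claim that
  its parameter values are unique in producing these phenomena, only that
  the phenomena are reproducible at the documented settings.
* RTs are in arbitrary simulation steps; no non-decision time is added,
  so comparisons to empirical chronometry are qualitative.
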