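test_that("trials are fully reproducible and engines agree bit-for-bit", {
  for (preset in c("two_choice", "multi_attribute", "delay_race")) {
    scn <- preset_scenario(preset)
    for (seed in c(2, 17, 303)) {
      a <- run_trial(scn, seed = seed, engine = "compiled", traces = TRUE)
      b <- run_trial(scn, seed = seed, engine = "reference", traces = TRUE)
      expect_identical(a$choice, b$choice)
      expect_identical(a$rt, b$rt)
      expect_identical(a$dwell, b$dwell)
      expect_equal(a$acc_trace, b$acc_trace, tolerance = 0,
                   ignore_attr = TRUE)
      expect_equal(a$mem_trace, b$mem_trace, tolerance = 0,
                   ignore_attr = TRUE)
      expect_identical(a$att_trace, b$att_trace)
      # and the same engine twice is identical
      a2 <- run_trial(scn, seed = seed, traces = TRUE)
      expect_identical(unclass(a)[c("choice", "rt", "dwell", "att_trace")],
                       unclass(a2)[c("choice", "rt", "dwell", "att_trace")])
      expect_identical(a$acc_trace, a2$acc_trace)
    }
  }
})

test_that("a single valued object yields the same rt under every seed", {
  scn <- make_scenario(n_objects = 1, values = list(0.5),
                       acc = list(sigma = 0))
  rts <- vapply(1:8, function(s) run_trial(scn, seed = s)$rt, integer(1))
  expect_true(all(rts == rts[1]))
  expect_false(anyNA(rts))
})

test_that("the higher-valued object wins more often", {
  sm <- run_trials(preset_scenario("two_choice"), n = 400, base_seed = 2)
  pB <- sm$summary$p_choice[sm$summary$object == "B"]
  expect_gt(pB, 0.6)
})

test_that("trial batches aggregate decided choices to probability one", {
  scn <- preset_scenario("two_choice")
  sm <- run_trials(scn, n = 50, base_seed = 9)
  expect_equal(sum(sm$summary$p_choice), 1)
  expect_identical(sm$n_decided + sm$n_timeout, 50L)
  # n = 1 reduces to the single trial
  one <- run_trials(scn, n = 1, base_seed = 123)
  tr <- run_trial(scn, seed = 123)
  expect_identical(one$trials$choice, tr$choice)
  expect_identical(one$trials$rt, tr$rt)
  # identical base seed, identical summary
  sm2 <- run_trials(scn, n = 50, base_seed = 9)
  expect_identical(sm$summary, sm2$summary)
  expect_identical(sm$trials, sm2$trials)
})

test_that("timeouts are results, with choice and rt jointly missing", {
  scn <- make_scenario(n_objects = 2, values = list(0, 0),
                       acc = list(sigma = 0), max_steps = 300)
  tr <- run_trial(scn, seed = 1)
  expect_true(is.na(tr$choice) && is.na(tr$rt))
  expect_identical(tr$steps, 300L)
  sm <- run_trials(scn, n = 5, base_seed = 1)
  expect_identical(sm$n_timeout, 5L)
})

test_that("sweeps hold everything fixed except the named parameter", {
  scn <- preset_scenario("two_choice")
  sw <- sweep_parameter(scn, "sigma", c(0.01, 0.05), n = 30, base_seed = 4)
  expect_length(sw$summaries, 2)
  tab <- sweep_table(sw)
  expect_identical(nrow(tab), 4L) # 2 values x 2 alternatives
  expect_error(sweep_parameter(scn, "threshold_bonus", 1, n = 5),
               "unknown sweep parameter")
})

test_that("no discounting parameter exists anywhere in the configuration", {
  scn <- preset_scenario("delayed_reward")
  keys <- unique(c(names(scn), names(scn$mem), names(scn$acc),
                   names(scn$att),
                   names(unlist(as.list(args(make_scenario))))))
  expect_false(any(grepl("discount|gamma_t|horizon", keys,
                         ignore.case = TRUE)))
})

test_that("the delay race reduces to value preference at chain length zero", {
  # both options immediate: the higher value (delayed option's 1.0) wins
  bp_args <- delayed_reward_calibration()
  scn <- do.call(make_scenario,
                 c(list(n_objects = 2, values = list(0.9, 1),
                        chain_lengths = c(0, 0)), bp_args))
  sm <- run_trials(scn, n = 300, base_seed = 6)
  expect_gt(sm$summary$p_choice[2], 0.5)
})

test_that("equal values behind a chain favour the immediate option", {
  scn <- preset_scenario("delay_race") # values 1 and 1, B behind 3 steps
  sm <- run_trials(scn, n = 300, base_seed = 6)
  expect_gt(sm$summary$p_choice[1], 0.5)
})
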