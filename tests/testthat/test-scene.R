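test_that("attribute sampling is uniform and seed-reproducible", {
  ob <- scene_object("A", 0, list(attribute("a1", c(1, 0, 0)),
                                  attribute("a2", c(0, 1, 0)),
                                  attribute("a3", c(0, 0, 1))))
  # single attribute: always that attribute
  ob1 <- scene_object("B", 1, list(attribute("only", c(1, 0, 0))))
  set.seed(1)
  expect_identical(sample_attribute(ob1)$id, "only")

  # uniformity: chi-square goodness of fit on 12,000 draws
  set.seed(42)
  draws <- replicate(12000, sample_attribute(ob)$id)
  expect_gt(stats::chisq.test(table(draws))$p.value, 0.001)

  # two attributes, 10,000 draws: each within 3 binomial SD of 5,000
  ob2 <- scene_object("C", 2, list(attribute("a1", c(1, 0, 0)),
                                   attribute("a2", c(0, 1, 0))))
  set.seed(7)
  d2 <- replicate(10000, sample_attribute(ob2)$id)
  expect_lt(abs(sum(d2 == "a1") - 5000), 3 * sqrt(10000 * 0.25))

  # replayed stream gives the identical sequence
  set.seed(99); s1 <- replicate(50, sample_attribute(ob)$id)
  set.seed(99); s2 <- replicate(50, sample_attribute(ob)$id)
  expect_identical(s1, s2)
})

test_that("scene construction enforces its invariants", {
  expect_error(feature_vector(c(0, 2)), "binary")
  expect_error(scene_object("A", 0, list()), "at least one attribute")
  expect_error(scene_object("A", -1, list(attribute("a", c(1, 0)))),
               ">= 0")
  expect_error(scene_object("A", 0, list(attribute("a", c(1, 0)),
                                         attribute("a", c(0, 1)))),
               "unique")
  a <- scene_object("A", 0, list(attribute("a", c(1, 0))))
  b_same_loc <- scene_object("B", 0, list(attribute("a", c(0, 1))))
  expect_error(scene(list(a, b_same_loc), 2), "unique")
  b_wrong_dim <- scene_object("B", 1, list(attribute("a", c(0, 1, 1))))
  expect_error(scene(list(a, b_wrong_dim), 2), "feature length")
})

test_that("salience vector maps locations and passes values through", {
  a <- scene_object("A", 0, list(attribute("a", c(1, 0))), salience = 1)
  b <- scene_object("B", 1, list(attribute("a", c(0, 1))), salience = 1)
  expect_equal(salience_vector(scene(list(a, b), 2)), c(1, 1))
  # single object at location 0 of 2: empty location gets 0
  b2 <- scene_object("B", 1, list(attribute("a", c(0, 1))), salience = 0)
  expect_equal(salience_vector(scene(list(a, b2), 2)), c(1, 0))
  # graded saliences pass through unchanged
  a3 <- scene_object("A", 0, list(attribute("a", c(1, 0))), salience = 0.3)
  b3 <- scene_object("B", 1, list(attribute("a", c(0, 1))), salience = 0.7)
  expect_equal(salience_vector(scene(list(a3, b3), 2)), c(0.3, 0.7))
})

test_that("generated scenarios realise stated values at the attractors", {
  # two single-attribute objects valued 0.4 / 0.6
  scn <- make_scenario(n_objects = 2, attrs_per_object = 1,
                       values = list(0.4, 0.6))
  pats <- scn$assoc$patterns
  expect_equal(evaluate_value(pats[["A:a1"]], scn$vmap), 0.4)
  expect_equal(evaluate_value(pats[["B:a1"]], scn$vmap), 0.6)

  # mirrored two-attribute values 0.2/0.3 vs 0.3/0.2
  scn2 <- make_scenario(n_objects = 2, attrs_per_object = 2,
                        values = list(c(0.2, 0.3), c(0.3, 0.2)))
  expect_equal(evaluate_value(scn2$assoc$patterns[["A:a1"]], scn2$vmap), 0.2)
  expect_equal(evaluate_value(scn2$assoc$patterns[["A:a2"]], scn2$vmap), 0.3)
  expect_equal(evaluate_value(scn2$assoc$patterns[["B:a1"]], scn2$vmap), 0.3)
  expect_equal(evaluate_value(scn2$assoc$patterns[["B:a2"]], scn2$vmap), 0.2)
})

test_that("episodic-chain scenarios put value only behind the chain", {
  scn <- make_scenario(n_objects = 2, attrs_per_object = 1,
                       values = list(0.5, 1), chain_lengths = c(0, 3))
  pats <- scn$assoc$patterns
  # B's value is reachable only at the chain's terminal pattern
  expect_equal(evaluate_value(pats[["B:a1"]], scn$vmap), 0)
  expect_equal(evaluate_value(pats[["B:chain1"]], scn$vmap), 0)
  expect_equal(evaluate_value(pats[["B:chain2"]], scn$vmap), 0)
  expect_equal(evaluate_value(pats[["B:chain3"]], scn$vmap), 1)
  # episodic weights link successive chain patterns
  We <- scn$assoc$episodic
  drive <- function(from, to) sum(We[pats[[to]] > 0, pats[[from]] > 0])
  expect_gt(drive("B:a1", "B:chain1"), 0)
  expect_gt(drive("B:chain1", "B:chain2"), 0)
  expect_gt(drive("B:chain2", "B:chain3"), 0)
  expect_equal(drive("B:chain3", "B:a1"), 0)
})

test_that("generated scenarios are self-consistent and capacity-checked", {
  scn <- make_scenario(n_objects = 3, attrs_per_object = c(1, 2, 1),
                       values = list(0.1, c(0.2, 0.3), 1),
                       chain_lengths = c(0, 0, 2), block_size = 2)
  expect_silent(validate_scenario(scn))
  # every valued node belongs to a stored pattern
  covered <- Reduce(`+`, scn$assoc$patterns) > 0
  expect_true(all(covered[as.numeric(scn$vmap) != 0]))
  # patterns are orthogonal at overlap 0
  pm <- do.call(cbind, scn$assoc$patterns)
  expect_true(all(crossprod(pm)[lower.tri(diag(ncol(pm)))] == 0))
  # too small a feature space is a capacity error
  expect_error(make_scenario(n_objects = 2, values = list(0.4, 0.6),
                             feature_dim = 1),
               "capacity")
})
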