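test_that("collapsibility weights match their closed forms", {
  spop <- standardization_population()
  w <- collapsibility_weights(spop, "rr_minus")
  expect_equal(unclass(w)[c("men", "women")], c(men = 0.4, women = 0.3))

  # RD weights are the prevalences and sum to one
  for (seed in 1:20) {
    pop <- random_population(1L + (seed %% 9L), seed = seed)
    wrd <- collapsibility_weights(pop, "rd")
    expect_equal(unname(unclass(wrd)), pop$prevalence)
    expect_equal(sum(unclass(wrd)), 1, tolerance = 1e-12)
    # reciprocal-coding duality: inverse codings swap in the treated risks
    expect_equal(unname(unclass(collapsibility_weights(pop, "inv_rr_minus"))),
                 pop$prevalence * pop$risk_treated)
    expect_equal(unname(unclass(collapsibility_weights(pop, "rr_plus"))),
                 pop$prevalence * (1 - pop$risk_untreated))
    expect_equal(unname(unclass(collapsibility_weights(pop, "inv_rr_plus"))),
                 pop$prevalence * (1 - pop$risk_treated))
  }

  expect_error(collapsibility_weights(spop, "or"), class = "collapsr_no_exact_weights")
  # all-zero weights are rejected at construction of the scheme
  dead <- counterfactual_population("a", 1, 0, 0.5)
  expect_error(collapsibility_weights(dead, "rr_minus"),
               class = "collapsr_degenerate_population")
})

test_that("weighted_average matches the worked example and is scale invariant", {
  w <- weight_scheme(c(men = 0.4, women = 0.3))
  vals <- c(men = 0.25, women = 0.6667)
  # printed as 0.428 in the worked example (truncated from 0.42859)
  expect_equal(weighted_average(vals, w), 0.428585714285714, tolerance = 1e-12)
  expect_lt(abs(weighted_average(vals, w) - 0.428), 1e-3)

  expect_equal(weighted_average(c(a = 5, b = 5), weight_scheme(c(a = 0.1, b = 9))), 5)
  expect_equal(weighted_average(vals, weight_scheme(17 * unclass(w))),
               weighted_average(vals, w), tolerance = 1e-12)

  # zero-weight strata are dropped before their values are consulted
  w0 <- weight_scheme(c(a = 0, b = 2))
  expect_equal(weighted_average(c(b = 7), w0), 7)
  expect_error(weighted_average(c(a = 1), weight_scheme(c(a = 0))),
               class = "collapsr_degenerate_population")
  expect_error(weighted_average(c(a = 1), weight_scheme(c(a = 1, b = 1))),
               class = "collapsr_config_error")
})

test_that("exact weights make every RD/RR coding collapsible on random populations", {
  kinds <- c("rd", "rr_minus", "rr_plus", "inv_rr_minus", "inv_rr_plus")
  for (seed in 1:200) {
    pop <- random_population(1L + (seed %% 10L), seed = seed)
    for (kind in kinds) {
      w <- collapsibility_weights(pop, kind)
      expect_true(is_collapsible_causal(pop, kind, w, tol = 1e-10))
    }
  }
})

test_that("the odds ratio fails collapsibility where the RD/RR codings cannot", {
  pop <- or_counterexample_population()
  # prevalence weights do not recover the marginal causal OR
  expect_false(is_collapsible_causal(pop, "or", weight_scheme(c(men = 0.25, women = 0.75)),
                                     tol = 1e-10))
  # equal stratum effects collapse under any positive weights for exact-weight measures
  flat <- counterfactual_population(c("a", "b"), c(0.3, 0.7), c(0.2, 0.5), c(0.3, 0.6))
  expect_equal(causal_stratum_effect(flat, "rd", "a"),
               causal_stratum_effect(flat, "rd", "b"))
  for (w in list(c(a = 1, b = 1), c(a = 0.9, b = 0.1), c(a = 2, b = 5))) {
    expect_true(is_collapsible_causal(flat, "rd", weight_scheme(w), tol = 1e-10))
  }
})

test_that("zero-weight strata with undefined measures are annihilated, not evaluated", {
  # stratum 'a' has undefined RR(-); its weight prevalence * 0 = 0 removes it
  # before evaluation, so the check runs instead of erroring.  With r1 = 0 in
  # that stratum it contributes nothing to the marginal either and the
  # identity still holds exactly.
  pop0 <- counterfactual_population(c("a", "b"), c(0.4, 0.6), c(0, 0.5), c(0, 0.25))
  w0 <- collapsibility_weights(pop0, "rr_minus")
  expect_equal(unname(unclass(w0)), c(0, 0.3))
  expect_true(is_collapsible_causal(pop0, "rr_minus", w0, tol = 1e-10))

  # with r1 > 0 in the annihilated stratum the marginal numerator keeps a
  # term the average cannot see: no error, but collapsibility honestly fails
  pop1 <- counterfactual_population(c("a", "b"), c(0.4, 0.6), c(0, 0.5), c(0.3, 0.25))
  w1 <- collapsibility_weights(pop1, "rr_minus")
  expect_no_error(verdict <- is_collapsible_causal(pop1, "rr_minus", w1, tol = 1e-10))
  expect_false(verdict)
})

test_that("associational and causal collapsibility verdicts agree under constant randomization", {
  kinds <- c("rd", "rr_minus", "rr_plus", "inv_rr_minus", "inv_rr_plus")
  for (seed in 1:100) {
    pop <- random_population(1L + (seed %% 8L), seed = seed)
    e <- collapsr:::with_seed(seed, stats::runif(1, 0.1, 0.9))
    obs <- observe(pop, e)
    for (kind in kinds) {
      w <- collapsibility_weights(pop, kind)
      expect_identical(is_collapsible_assoc(obs, kind, w, tol = 1e-8),
                       is_collapsible_causal(pop, kind, w, tol = 1e-8))
    }
    # and an arbitrary positive weight scheme agrees too (both routes see the
    # same stratum/marginal values when risks coincide)
    warb <- weight_scheme(stats::setNames(seq_len(nrow(pop)), pop$label))
    for (kind in kinds) {
      expect_identical(is_collapsible_assoc(obs, kind, warb, tol = 1e-8),
                       is_collapsible_causal(pop, kind, warb, tol = 1e-8))
    }
  }
})

test_that("confounded data break prevalence-weight collapsibility of the RD", {
  # two strata; exposure depends strongly on V, risks differ across V
  pop <- counterfactual_population(c("a", "b"), c(0.5, 0.5), c(0.1, 0.6), c(0.2, 0.9))
  obs <- observe(pop, c(a = 0.9, b = 0.1))
  w <- weight_scheme(c(a = 0.5, b = 0.5))
  # causal RD is always collapsible under prevalence weights ...
  expect_true(is_collapsible_causal(pop, "rd", w, tol = 1e-10))
  # ... but the associational RD on confounded data is not
  expect_false(is_collapsible_assoc(obs, "rd", w, tol = 1e-6))
  # single-stratum data are trivially collapsible for any kind and weights
  single <- observed_population("only", 10, 90, 30, 70)
  for (kind in effect_measures()) {
    expect_true(is_collapsible_assoc(single, kind, weight_scheme(c(only = 2)), tol = 1e-10))
  }
})

test_that("newman weights reproduce hand arithmetic on the standardization table", {
  obs <- standardization_observed()
  # Pr(V|A=1) = 0.5 in both strata, so RD weights are 0.5/0.5
  expect_equal(unclass(newman_weights(obs, "rd")), c(men = 0.5, women = 0.5))
  # RR weights: Pr(V|A=1) * p0
  expect_equal(unclass(newman_weights(obs, "rr_minus")), c(men = 0.4, women = 0.3))
  # OR weights: Pr(V|A=1) * (1 - p1) * p0/(1 - p0), by direct formula
  expect_equal(unclass(newman_weights(obs, "or")),
               c(men = 0.5 * (400 / 500) * (0.8 / 0.2),
                 women = 0.5 * (300 / 500) * (0.6 / 0.4)))

  single <- observed_population("only", 10, 90, 30, 70)
  w1 <- unclass(newman_weights(single, "rd"))
  expect_equal(unname(w1 / sum(w1)), 1)

  expect_error(newman_weights(observed_population("a", 0, 0, 5, 5), "rd"),
               class = "collapsr_undefined_measure")
  expect_error(newman_weights(observed_population("a", 1, 9, 5, 0), "or"),
               class = "collapsr_undefined_measure")
})

test_that("newman weights collapse the associational RD when exposure is unconfounded", {
  for (seed in 1:50) {
    pop <- random_population(2L + (seed %% 5L), seed = seed)
    obs <- observe(pop, 0.4)  # V not associated with exposure
    expect_true(is_collapsible_assoc(obs, "rd", newman_weights(obs, "rd"), tol = 1e-8))
    expect_true(is_collapsible_assoc(obs, "rr_minus", newman_weights(obs, "rr_minus"),
                                     tol = 1e-8))
  }
})

test_that("newman sufficient conditions are detected from the counts", {
  obs <- standardization_observed()  # e_v = 0.5 in both strata
  expect_true(newman_conditions_hold(obs, "rd"))
  expect_true(newman_conditions_hold(obs, "rr_minus"))
  # but p0 differs (0.8 vs 0.6), so the OR condition fails
  expect_false(newman_conditions_hold(obs, "or"))

  pop <- random_population(4, seed = 12)
  expect_true(newman_conditions_hold(observe(pop, 0.3), "rd"))

  # both conditions violated by construction: p0 = (0.8, 0.6), e = (0.3, 0.7)
  bad <- observed_population(
    c("a", "b"),
    exposed_cases = c(0.3 * 0.5, 0.7 * 0.5), exposed_noncases = c(0.3 * 0.5, 0.7 * 0.5),
    unexposed_cases = c(0.7 * 0.8, 0.3 * 0.6), unexposed_noncases = c(0.7 * 0.2, 0.3 * 0.4)
  )
  expect_false(newman_conditions_hold(bad, "or"))
  expect_false(newman_conditions_hold(bad, "rd"))
})

test_that("the feasibility envelope certifies the odds-ratio impossibility", {
  expect_false(feasibility_envelope(c(3, 3), 2.8286))
  expect_true(feasibility_envelope(c(0.25, 0.6667), 0.428))
  expect_true(feasibility_envelope(5, 5))

  # envelope always contains the marginal for measures with exact weights
  kinds <- c("rd", "rr_minus", "rr_plus", "inv_rr_minus", "inv_rr_plus")
  for (seed in 1:100) {
    pop <- random_population(1L + (seed %% 10L), seed = seed)
    for (kind in kinds) {
      expect_true(feasibility_envelope(causal_stratum_effects(pop, kind),
                                       causal_marginal_effect(pop, kind), tol = 1e-9))
    }
  }
  # while the OR counterexample population escapes it
  pop <- or_counterexample_population()
  expect_false(feasibility_envelope(causal_stratum_effects(pop, "or"),
                                    causal_marginal_effect(pop, "or")))
})
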