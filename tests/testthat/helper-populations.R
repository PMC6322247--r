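# Shared fixtures, all built in code.

# Randomized-trial population with equal stratum odds ratios (3) whose
# marginal causal odds ratio is 2.83: the OR non-collapsibility counterexample.
or_counterexample_population <- function() {
  counterfactual_population(
    label = c("men", "women"),
    prevalence = c(0.25, 0.75),
    risk_untreated = c(0.50, 0.25),
    risk_treated = c(0.75, 0.50)
  )
}

# Counterfactual population behind the 2000-subject standardization example:
# two equal strata, untreated risks 0.8/0.6, treated risks 0.2/0.4.
standardization_population <- function() {
  counterfactual_population(
    label = c("men", "women"),
    prevalence = c(0.5, 0.5),
    risk_untreated = c(0.8, 0.6),
    risk_treated = c(0.2, 0.4)
  )
}

# The corresponding observed table of 2000 subjects, half exposed.
standardization_observed <- function() {
  observed_population(
    label = c("men", "women"),
    exposed_cases = c(100, 200), exposed_noncases = c(400, 300),
    unexposed_cases = c(400, 300), unexposed_noncases = c(100, 200)
  )
}

standardization_csv <- function() {
  system.file("extdata", "standardization_example.csv", package = "collapsr")
}

# Random observed population: random counterfactual population plus a random
# stratum-specific assignment bounded away from 0 and 1.
random_observed <- function(seed, n_strata = NULL) {
  if (is.null(n_strata)) n_strata <- 1L + (seed %% 8L)
  pop <- random_population(n_strata, seed = seed)
  e <- collapsr:::with_seed(seed + 10^6, stats::runif(n_strata, 0.05, 0.95))
  observe(pop, stats::setNames(e, pop$label))
}
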