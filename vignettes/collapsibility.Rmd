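---
title: "Collapsibility of effect measures: models, weights and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapsibility of effect measures: models, weights and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collapsr)
```

## The model

Throughout, the exposure `A` and the outcome `Y` are binary and the baseline
covariate `V` is finite and categorical.  `Y^a` denotes the potential outcome
under exposure level `a`.  A counterfactual population is fully described,
for every purpose this package serves, by the triplet per stratum

* `Pr(V = v)` — the stratum prevalence,
* `r0(v) = Pr(Y^0 = 1 | V = v)` — the counterfactual risk untreated,
* `r1(v) = Pr(Y^1 = 1 | V = v)` — the counterfactual risk treated.

The joint distribution of `(Y^0, Y^1)` is deliberately not represented: every
measure in scope (risk difference, the four risk-ratio codings, odds ratio)
and every weight scheme is a functional of the two marginals, and the joint
is not identifiable even from a randomized trial.  Storing only the marginals
is the minimal sufficient representation.

Two definitions of collapsibility are implemented side by side.  The
*associational* one asks whether a measure computed from the observed joint
distribution of `(A, Y)` satisfies
`Σ_v g(v)·w_v / Σ_v w_v = g(marginal)`; the *causal* one asks the same of a
measure computed from counterfactual risks.  They coincide when there is
neither unconditional confounding nor confounding conditional on `V` — for
instance under a constant randomization probability — and can disagree
otherwise; `is_collapsible_assoc()` and `is_collapsible_causal()` implement
the two checks with identical mechanics.

## The weights

For any population whatsoever:

| measure   | exact weights `w_v`          |
|-----------|------------------------------|
| RD        | `Pr(V=v)`                    |
| RR(−)     | `Pr(V=v)·r0(v)`              |
| RR(+)     | `Pr(V=v)·(1 − r0(v))`        |
| 1/RR(−)   | `Pr(V=v)·r1(v)`              |
| 1/RR(+)   | `Pr(V=v)·(1 − r1(v))`        |
| OR        | none exist                   |

The RR(−) weights are `Pr(V=v | Y^0=1)` up to the constant `Pr(Y^0=1)`,
which cancels in any weighted average; weights are therefore carried
**unnormalized** and normalized only inside `weighted_average()`.  The
reciprocal codings swap `r0` for `r1` exactly where the outcome recoding
swaps the conditioning event — a structural duality the test suite checks on
random populations.

The odds-ratio impossibility is certified by `feasibility_envelope()`: a
non-negative weighted average of a finite set of numbers fills exactly the
closed interval `[min, max]`, so a marginal effect outside that interval
proves no weight scheme exists.  Min/max is used rather than a linear
program because the envelope argument is already complete.

Under no unmeasured confounding given `V`, the RR(−) weights are identified
as Miettinen's `Pr(V=v)·Pr(Y=1 | A=0, V=v)` (`miettinen_weights()`), the
weighted average of stratum risk ratios under them equals the standardized
risk ratio (`standardized_rr()` — an identity that holds on *any* table,
asserted numerically on 1000 random tables), and the SRR equals the marginal
causal risk ratio.  `transport_rr()` applies the same weights built from an
external target population's prevalences and baseline risks;
`unexposed_target_weights()` covers the special case of an entirely
unexposed target, where consistency identifies the weights as the case
distribution `Pr(V=v | Y=1)`.

## Observation semantics

`observe()` maps a counterfactual population plus an assignment mechanism
`Pr(A=1 | V=v)` to the *expected* stratified 2×2 table on a unit grand
total.  Infinite-population semantics are intentional: the identities under
study hold in real arithmetic, and finite multinomial noise would only
obscure whether a failure is structural or sampling error.  Counts are
therefore non-negative reals, and `observed_population()` accepts them as
such.  Because assignment depends only on `V`, consistency gives
`Pr(Y=1 | A=a, V=v) = Pr(Y^a=1 | V=v)` exactly, which the tests verify per
stratum.

`confounded_scenario()` extends the model with a latent covariate `U`:
expected counts are formed within `(v, u)` cells and summed over `u`.  When
assignment or risks vary over `u` within `v`, the observed conditional risks
no longer equal the marginal counterfactual risks and standardization over
`V` alone is biased.  `bias_demo()` reports the true marginal causal risk
ratio (computed from the scenario itself), the SRR of the confounded data,
and the Miettinen-weighted average — the last two are algebraically equal,
so the demonstration shows a *common* bias of both observed-data routes, in
whatever direction and magnitude the scenario induces.  No direction or
magnitude is asserted anywhere: the packaged scenario
(`demo_scenario()`, also shipped as
`inst/extdata/confounded_demo_scenario.yaml`, and synthetic by construction)
merely makes the bias visible against a known truth of 0.5.

## The synthetic generator

`random_population(n_strata, seed)` draws prevalences uniformly on the
probability simplex (normalized standard exponentials) and risks uniformly
on `(0.01, 0.99)`.  No canonical generative family exists for "an arbitrary
covariate"; the uniform-simplex/uniform-risk choice is ours, made once, and
covers the space of populations without favouring any structure.  The risk
bounds keep every measure's denominator away from zero so that property
suites exercise the identities rather than the error paths;
`risk_range = c(0, 1)` opens the full range for deliberate edge-case tests.
The generator emulates populations, not samples: passing tests demonstrate
the algebraic identities and identification results, and say nothing about
finite-sample behaviour, non-binary variables, continuous covariates or
time-varying exposure, which are out of scope.

## Numerical choices

* **Tolerances.** Collapsibility verdicts default to a *relative* tolerance
  of `1e-10`: the identities are exact in real arithmetic, so the slack only
  covers floating-point summation.  Structural identities asserted in tests
  (reciprocal duality, OR = RR(−)/RR(+), SRR = weighted average) use
  `1e-12` relative.  Prevalence sums are required to be within `1e-6` of 1
  absolutely, and are rejected — never silently renormalized — beyond that.
* **Undefined measures.** A vanishing denominator raises a typed
  `collapsr_undefined_measure` error naming the stratum and measure.  No
  continuity corrections are applied anywhere: the package works with exact
  population proportions, where a zero is a zero.
* **Zero-weight strata.** `weighted_average()` drops zero-weight strata
  before their values are evaluated, so a stratum with `r0(v) = 0`
  (undefined RR(−), weight exactly 0) never crashes the average.  Note the
  limit behaviour honestly: if such a stratum has `r1(v) > 0`, it still
  feeds the marginal numerator while being invisible to the average, and the
  collapsibility identity genuinely fails there — the check then returns
  `FALSE` rather than erroring.  The exactness guarantee is for populations
  with `r0` interior, which the generator's default bounds ensure.
* **Determinism.** `random_population()` seeds a local RNG scope and
  restores the caller's state; identical `(n_strata, seed)` yields identical
  populations.  Reports exclude timestamps so that identical inputs give
  byte-identical JSON.
* **Order.** Strata are processed in input order; nothing depends on label
  sort order.

## Problem sizes in the test suite

The worked examples are two-stratum tables and run instantly.  The property
suites use seeded batches sized to probe the identity space thoroughly while
keeping the whole suite under a minute: 1000 random populations (1–10
strata) for the exactness of the five weight schemes and for the
SRR/weighted-average identity, 500 for the agreement of the associational
and causal collapsibility verdicts under constant randomization, 300 for the
identification of the Miettinen weights, and 1000 seeds for generator
validity.

## Known limitations

Binary exposure and outcome only; finite categorical `V`; no variance or
confidence-interval theory (population quantities throughout); no
confounding adjustment beyond stratified standardization (no IP weighting,
no outcome regression); Newman's conditions are implemented as the
*sufficient* conditions they are — a `FALSE` from
`newman_conditions_hold()` does not prove non-collapsibility.  The
exactness of the five weight schemes is proved algebraically for these
measures and checked empirically; no claim is made for other effect
measures.
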