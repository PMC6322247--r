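# Effect measures, causal and associational, stratum-specific and marginal.
#
# Six measures are supported.  The risk ratio is asymmetric in the coding of
# the outcome, so the two codings and their reciprocals are distinct measures
# with distinct collapsibility weights:
#   rd            r1 - r0
#   rr_minus      r1 / r0              (risk ratio of the outcome event)
#   rr_plus       (1 - r1) / (1 - r0)  (risk ratio of the complement)
#   inv_rr_minus  r0 / r1
#   inv_rr_plus   (1 - r0) / (1 - r1)
#   or            [r1 / (1 - r1)] / [r0 / (1 - r0)]

MEASURE_KINDS <- c("rd", "rr_minus", "rr_plus", "inv_rr_minus", "inv_rr_plus", "or")

#' Supported effect-measure kinds
#'
#' Returns the closed set of effect-measure identifiers understood by the
#' package: `"rd"` (risk difference), `"rr_minus"` (risk ratio coded on the
#' outcome event), `"rr_plus"` (risk ratio coded on the complement of the
#' outcome), `"inv_rr_minus"` and `"inv_rr_plus"` (their reciprocals), and
#' `"or"` (odds ratio).
#'
#' @return A character vector of measure identifiers.
#' @export
effect_measures <- function() MEASURE_KINDS

match_kind <- function(kind) match.arg(kind, MEASURE_KINDS)

# r0, r1 scalar risks; returns the measure or raises a typed error.
effect_from_risks <- function(r0, r1, kind, stratum = NULL) {
  switch(kind,
    rd = r1 - r0,
    rr_minus = {
      if (r0 == 0) stop_undefined_measure(kind, stratum, "baseline risk is 0")
      r1 / r0
    },
    rr_plus = {
      if (r0 == 1) stop_undefined_measure(kind, stratum, "baseline risk is 1")
      (1 - r1) / (1 - r0)
    },
    inv_rr_minus = {
      if (r1 == 0) stop_undefined_measure(kind, stratum, "treated risk is 0")
      r0 / r1
    },
    inv_rr_plus = {
      if (r1 == 1) stop_undefined_measure(kind, stratum, "treated risk is 1")
      (1 - r0) / (1 - r1)
    },
    or = {
      if (r1 == 1) stop_undefined_measure(kind, stratum, "treated risk is 1")
      if (r0 == 0) stop_undefined_measure(kind, stratum, "baseline odds are 0")
      if (r0 == 1) stop_undefined_measure(kind, stratum, "baseline risk is 1")
      (r1 / (1 - r1)) / (r0 / (1 - r0))
    }
  )
}

# ---- causal measures -----------------------------------------------------

#' Marginal counterfactual risks
#'
#' Computes the two marginal counterfactual risks of a population by the law
#' of total probability:
#' \eqn{\Pr(Y^{a}=1) = \sum_v \Pr(Y^{a}=1 \mid V=v)\,\Pr(V=v)} for
#' \eqn{a \in \{0, 1\}}.
#'
#' @param pop A [counterfactual_population()].
#' @return A named numeric vector `c(r0 = ..., r1 = ...)`: the marginal risk
#'   under no exposure and under exposure.
#' @examples
#' pop <- counterfactual_population(c("men", "women"), c(0.25, 0.75),
#'                                  c(0.5, 0.25), c(0.75, 0.5))
#' causal_marginal_risks(pop)  # r0 = 0.3125, r1 = 0.5625
#' @export
causal_marginal_risks <- function(pop) {
  stopifnot(inherits(pop, "counterfactual_population"))
  c(r0 = sum(pop$risk_untreated * pop$prevalence),
    r1 = sum(pop$risk_treated * pop$prevalence))
}

#' Stratum-specific and marginal causal effect measures
#'
#' `causal_stratum_effect()` evaluates an effect measure from the
#' counterfactual risks of a single stratum; `causal_stratum_effects()`
#' returns all strata as a named vector; `causal_marginal_effect()` applies
#' the same formula to the marginal counterfactual risks from
#' [causal_marginal_risks()].  A measure whose denominator vanishes raises a
#' `collapsr_undefined_measure` error naming the stratum and measure; no
#' continuity correction is applied.
#'
#' @param pop A [counterfactual_population()].
#' @param kind One of [effect_measures()].
#' @param label A stratum label present in `pop`.
#' @return A numeric scalar (or named vector for `causal_stratum_effects()`).
#' @examples
#' pop <- counterfactual_population(c("men", "women"), c(0.25, 0.75),
#'                                  c(0.5, 0.25), c(0.75, 0.5))
#' causal_stratum_effect(pop, "or", "men")  # 3
#' causal_marginal_effect(pop, "or")        # 2.8286: the OR is not collapsible
#' @export
causal_stratum_effect <- function(pop, kind, label) {
  stopifnot(inherits(pop, "counterfactual_population"))
  kind <- match_kind(kind)
  i <- match(label, pop$label)
  if (is.na(i)) stop_config(sprintf("no stratum labelled '%s'", label))
  effect_from_risks(pop$risk_untreated[i], pop$risk_treated[i], kind, stratum = label)
}

#' @rdname causal_stratum_effect
#' @export
causal_stratum_effects <- function(pop, kind) {
  stopifnot(inherits(pop, "counterfactual_population"))
  kind <- match_kind(kind)
  stats::setNames(
    vapply(seq_len(nrow(pop)), function(i) {
      effect_from_risks(pop$risk_untreated[i], pop$risk_treated[i], kind,
                        stratum = pop$label[i])
    }, numeric(1)),
    pop$label
  )
}

#' @rdname causal_stratum_effect
#' @export
causal_marginal_effect <- function(pop, kind) {
  kind <- match_kind(kind)
  r <- causal_marginal_risks(pop)
  effect_from_risks(r[["r0"]], r[["r1"]], kind)
}

# ---- associational measures ----------------------------------------------

assoc_risks_stratum <- function(obs, i, kind) {
  ne <- obs$exposed_cases[i] + obs$exposed_noncases[i]
  nu <- obs$unexposed_cases[i] + obs$unexposed_noncases[i]
  if (ne <= 0) stop_undefined_measure(kind, obs$label[i], "no exposed individuals")
  if (nu <= 0) stop_undefined_measure(kind, obs$label[i], "no unexposed individuals")
  c(p0 = obs$unexposed_cases[i] / nu, p1 = obs$exposed_cases[i] / ne)
}

#' Stratum-specific and marginal (crude) measures of association
#'
#' Evaluates an effect measure from observed conditional risks:
#' `assoc_stratum_effect()` uses the within-stratum risks
#' \eqn{p_{av} = \Pr(Y=1 \mid A=a, V=v)}; `assoc_stratum_effects()` returns
#' all strata; `assoc_marginal_effect()` pools the counts over strata first
#' and uses the crude risks \eqn{\Pr(Y=1 \mid A=a)}.  An empty exposure arm
#' (or a vanishing measure denominator) raises a typed
#' `collapsr_undefined_measure` error.
#'
#' @param obs An [observed_population()].
#' @param kind One of [effect_measures()].
#' @param label A stratum label present in `obs`.
#' @return A numeric scalar (or named vector for `assoc_stratum_effects()`).
#' @examples
#' obs <- observed_population(c("men", "women"), c(100, 200), c(400, 300),
#'                            c(400, 300), c(100, 200))
#' assoc_stratum_effect(obs, "rr_minus", "women")  # 0.6667
#' assoc_marginal_effect(obs, "rr_minus")          # crude RR 0.4286
#' @export
assoc_stratum_effect <- function(obs, kind, label) {
  stopifnot(inherits(obs, "observed_population"))
  kind <- match_kind(kind)
  i <- match(label, obs$label)
  if (is.na(i)) stop_config(sprintf("no stratum labelled '%s'", label))
  p <- assoc_risks_stratum(obs, i, kind)
  effect_from_risks(p[["p0"]], p[["p1"]], kind, stratum = label)
}

#' @rdname assoc_stratum_effect
#' @export
assoc_stratum_effects <- function(obs, kind) {
  stopifnot(inherits(obs, "observed_population"))
  kind <- match_kind(kind)
  stats::setNames(
    vapply(seq_len(nrow(obs)), function(i) {
      p <- assoc_risks_stratum(obs, i, kind)
      effect_from_risks(p[["p0"]], p[["p1"]], kind, stratum = obs$label[i])
    }, numeric(1)),
    obs$label
  )
}

#' @rdname assoc_stratum_effect
#' @export
assoc_marginal_effect <- function(obs, kind) {
  stopifnot(inherits(obs, "observed_population"))
  kind <- match_kind(kind)
  ne <- sum(obs$exposed_cases) + sum(obs$exposed_noncases)
  nu <- sum(obs$unexposed_cases) + sum(obs$unexposed_noncases)
  if (ne <= 0) stop_undefined_measure(kind, NULL, "no exposed individuals")
  if (nu <= 0) stop_undefined_measure(kind, NULL, "no unexposed individuals")
  effect_from_risks(sum(obs$unexposed_cases) / nu, sum(obs$exposed_cases) / ne, kind)
}
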