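# Collapsibility machinery: weight schemes, weighted averaging, causal and
# associational collapsibility checks, Newman's weights for measures of
# association, and the feasibility-envelope diagnostic for the odds ratio.

#' Construct a weight scheme
#'
#' A weight scheme is a named vector of non-negative, unnormalized per-stratum
#' weights \eqn{w_v}.  Weights are deliberately carried unnormalized —
#' weighted averages divide by \eqn{\sum_v w_v} at evaluation time — which
#' matches how standardization weights such as
#' \eqn{\Pr(V=v)\,\Pr(Y=1 \mid A=0, V=v)} are usually presented.  A scheme may
#' contain zeros (such strata are excluded from averages before their values
#' are evaluated); a scheme that is all zeros only fails when averaged.
#'
#' @param w Named numeric vector of non-negative finite weights with unique
#'   names.
#' @return An object of class `weight_scheme`.
#' @seealso [weighted_average()], [collapsibility_weights()]
#' @export
weight_scheme <- function(w) {
  if (!is.numeric(w) || is.null(names(w)) || any(!nzchar(names(w)))) {
    stop_config("weights must be a named numeric vector")
  }
  if (anyDuplicated(names(w))) stop_config("weight labels must be unique")
  if (anyNA(w) || any(!is.finite(w))) stop_config("weights must be finite")
  if (any(w < 0)) stop_config("weights must be non-negative")
  structure(as.numeric(w), names = names(w), class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("Weight scheme (unnormalized):\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# weights for `labels`, in that order; error if any label missing
weights_for <- function(w, labels) {
  stopifnot(inherits(w, "weight_scheme"))
  missing <- setdiff(labels, names(w))
  if (length(missing)) {
    stop_config(sprintf("weight scheme is missing strata: %s",
                        paste(missing, collapse = ", ")))
  }
  stats::setNames(as.numeric(unclass(w)[labels]), labels)
}

#' Exact collapsibility weights for causal effect measures
#'
#' Returns the per-stratum weights under which the marginal causal effect
#' equals the weighted average of stratum-specific causal effects, for any
#' population:
#'
#' * risk difference: \eqn{w_v = \Pr(V=v)};
#' * risk ratio of the event, RR(−): \eqn{w_v \propto \Pr(V=v \mid Y^{a=0}=1)},
#'   computed via Bayes as \eqn{\Pr(V=v)\,\Pr(Y^{a=0}=1 \mid V=v)};
#' * risk ratio of the complement, RR(+): \eqn{\Pr(V=v)\,\Pr(Y^{a=0}=0 \mid V=v)};
#' * 1/RR(−): \eqn{\Pr(V=v)\,\Pr(Y^{a=1}=1 \mid V=v)};
#' * 1/RR(+): \eqn{\Pr(V=v)\,\Pr(Y^{a=1}=0 \mid V=v)}.
#'
#' The weights involve counterfactual risks and are therefore not identified
#' from observed data in general; see [miettinen_weights()] for the
#' identified version of the RR(−) weights under no unmeasured confounding.
#' No such weights exist for the odds ratio: requesting `kind = "or"` raises
#' a `collapsr_no_exact_weights` error (see [feasibility_envelope()] for the
#' counterexample diagnostic).
#'
#' @param pop A [counterfactual_population()].
#' @param kind One of [effect_measures()] except `"or"`.
#' @return A [weight_scheme()], unnormalized.
#' @examples
#' pop <- counterfactual_population(c("men", "women"), c(0.5, 0.5),
#'                                  c(0.8, 0.6), c(0.2, 0.4))
#' collapsibility_weights(pop, "rr_minus")  # men 0.4, women 0.3
#' @export
collapsibility_weights <- function(pop, kind) {
  stopifnot(inherits(pop, "counterfactual_population"))
  kind <- match_kind(kind)
  if (kind == "or") stop_no_exact_weights()
  w <- switch(kind,
    rd = pop$prevalence,
    rr_minus = pop$prevalence * pop$risk_untreated,
    rr_plus = pop$prevalence * (1 - pop$risk_untreated),
    inv_rr_minus = pop$prevalence * pop$risk_treated,
    inv_rr_plus = pop$prevalence * (1 - pop$risk_treated)
  )
  if (sum(w) <= 0) {
    stop_degenerate_population(sprintf("all '%s' collapsibility weights are zero", kind))
  }
  weight_scheme(stats::setNames(w, pop$label))
}

#' Weighted average of per-stratum values
#'
#' Computes \eqn{\sum_v w_v x_v / \sum_v w_v}.  Strata with zero weight are
#' excluded before their values are consulted, so a value may be missing (or
#' `NA`) wherever its weight is zero — this is what lets the RR(−) weights,
#' which vanish exactly where the stratum risk ratio is undefined, annihilate
#' undefined strata instead of crashing.
#'
#' @param values Named numeric vector of per-stratum values; must cover every
#'   stratum with positive weight.
#' @param w A [weight_scheme()].
#' @return The weighted average, a numeric scalar.
#' @examples
#' weighted_average(c(men = 0.25, women = 0.6667),
#'                  weight_scheme(c(men = 0.4, women = 0.3)))  # 0.428
#' @export
weighted_average <- function(values, w) {
  stopifnot(inherits(w, "weight_scheme"))
  wv <- stats::setNames(as.numeric(unclass(w)), names(w))
  wv <- wv[wv > 0]
  if (length(wv) == 0L) stop_degenerate_population()
  missing <- setdiff(names(wv), names(values))
  if (length(missing)) {
    stop_config(sprintf("values missing for positively weighted strata: %s",
                        paste(missing, collapse = ", ")))
  }
  x <- as.numeric(values[names(wv)])
  if (anyNA(x)) stop_config("values for positively weighted strata must be non-missing")
  sum(wv * x) / sum(wv)
}

# shared relative comparison for the collapsibility verdicts
close_rel <- function(avg, marginal, tol) {
  abs(avg - marginal) <= tol * abs(marginal)
}

#' Causal and associational collapsibility checks
#'
#' `is_collapsible_causal()` tests whether the weighted average of
#' stratum-specific *causal* effects equals the marginal causal effect under
#' the supplied weights; `is_collapsible_assoc()` tests the same property for
#' *associational* effects computed from an observed table (the marginal being
#' the crude effect on pooled counts).  The two notions coincide when there is
#' neither unconditional confounding nor confounding conditional on the
#' stratifying covariate (for instance under a constant randomization
#' probability), and can differ otherwise.
#'
#' Stratum effects are evaluated only where the weight is positive;
#' comparison is relative: the check passes when
#' \eqn{|\bar{x}_w - m| \le tol\,|m|} with \eqn{m} the marginal effect.
#'
#' @param pop A [counterfactual_population()].
#' @param obs An [observed_population()].
#' @param kind One of [effect_measures()].
#' @param w A [weight_scheme()] covering every stratum.
#' @param tol Relative tolerance; the default `1e-10` allows only
#'   floating-point summation error, since the exact-weight identities hold
#'   in real arithmetic.
#' @return `TRUE` or `FALSE`.
#' @examples
#' pop <- random_population(5, seed = 1)
#' w <- collapsibility_weights(pop, "rr_minus")
#' is_collapsible_causal(pop, "rr_minus", w)   # TRUE for any population
#' @export
is_collapsible_causal <- function(pop, kind, w, tol = 1e-10) {
  stopifnot(inherits(pop, "counterfactual_population"))
  kind <- match_kind(kind)
  wv <- weights_for(w, pop$label)
  keep <- pop$label[wv > 0]
  if (!length(keep)) stop_degenerate_population()
  vals <- vapply(keep, function(l) causal_stratum_effect(pop, kind, l), numeric(1))
  avg <- weighted_average(vals, weight_scheme(wv[keep]))
  close_rel(avg, causal_marginal_effect(pop, kind), tol)
}

#' @rdname is_collapsible_causal
#' @export
is_collapsible_assoc <- function(obs, kind, w, tol = 1e-10) {
  stopifnot(inherits(obs, "observed_population"))
  kind <- match_kind(kind)
  wv <- weights_for(w, obs$label)
  keep <- obs$label[wv > 0]
  if (!length(keep)) stop_degenerate_population()
  vals <- vapply(keep, function(l) assoc_stratum_effect(obs, kind, l), numeric(1))
  avg <- weighted_average(vals, weight_scheme(wv[keep]))
  close_rel(avg, assoc_marginal_effect(obs, kind), tol)
}

#' Newman's weights for measures of association
#'
#' Returns the classical weights under which a measure of *association* is
#' collapsible when the corresponding sufficient condition holds:
#'
#' * risk difference: \eqn{w_v = \Pr(V=v \mid A=1)};
#' * risk ratio (event coding): \eqn{\Pr(V=v \mid A=1)\,\Pr(Y=1 \mid A=0, V=v)};
#' * odds ratio: \eqn{\Pr(V=v \mid A=1)\,\Pr(Y=0 \mid A=1, V=v)\,
#'   \frac{\Pr(Y=1 \mid A=0, V=v)}{1-\Pr(Y=1 \mid A=0, V=v)}}.
#'
#' The sufficient conditions are checked by [newman_conditions_hold()]; the
#' weights themselves are computable from any table with nonempty arms.
#'
#' @param obs An [observed_population()]; both exposure arms must be nonempty
#'   in every stratum, and for the odds ratio \eqn{\Pr(Y=1|A=0,V=v) < 1}.
#' @param kind `"rd"`, `"rr_minus"` or `"or"`.
#' @return A [weight_scheme()], unnormalized.
#' @export
newman_weights <- function(obs, kind = c("rd", "rr_minus", "or")) {
  stopifnot(inherits(obs, "observed_population"))
  kind <- match.arg(kind)
  n_exp <- obs$exposed_cases + obs$exposed_noncases
  if (any(n_exp <= 0)) {
    stop_undefined_measure(kind, obs$label[which(n_exp <= 0)[1]], "no exposed individuals")
  }
  pv_a1 <- n_exp / sum(n_exp)  # Pr(V=v | A=1)
  w <- switch(kind,
    rd = pv_a1,
    rr_minus = {
      p0 <- p0_checked(obs, kind)
      pv_a1 * p0
    },
    or = {
      p0 <- p0_checked(obs, kind)
      bad <- which(p0 >= 1)
      if (length(bad)) {
        stop_undefined_measure(kind, obs$label[bad[1]], "baseline risk is 1")
      }
      p1 <- obs$exposed_cases / n_exp
      pv_a1 * (1 - p1) * p0 / (1 - p0)
    }
  )
  weight_scheme(stats::setNames(w, obs$label))
}

p0_checked <- function(obs, kind) {
  n_unexp <- obs$unexposed_cases + obs$unexposed_noncases
  if (any(n_unexp <= 0)) {
    stop_undefined_measure(kind, obs$label[which(n_unexp <= 0)[1]], "no unexposed individuals")
  }
  obs$unexposed_cases / n_unexp
}

#' Check Newman's sufficient conditions for associational collapsibility
#'
#' For the risk difference and risk ratio the sufficient condition is that the
#' covariate is not associated with the outcome in the unexposed
#' (\eqn{p_{0v}} constant over \eqn{v}) *or* not associated with the exposure
#' (\eqn{\Pr(A=1 \mid V=v)} constant over \eqn{v}).  For the odds ratio only
#' the first disjunct is used (constant baseline risk), the classical example
#' of the much more limiting conditions that measure requires.  These
#' conditions are sufficient, not necessary: a `FALSE` verdict does not prove
#' non-collapsibility.
#'
#' @param obs An [observed_population()].
#' @param kind `"rd"`, `"rr_minus"` or `"or"`.
#' @param tol Relative tolerance for the constancy checks.
#' @return `TRUE` or `FALSE`.
#' @export
newman_conditions_hold <- function(obs, kind = c("rd", "rr_minus", "or"), tol = 1e-10) {
  stopifnot(inherits(obs, "observed_population"))
  kind <- match.arg(kind)
  is_const <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) <= 1L) return(TRUE)
    (max(x) - min(x)) <= tol * max(abs(x), .Machine$double.xmin)
  }
  p0_const <- is_const(risk_unexposed(obs))
  if (kind == "or") return(p0_const)
  p0_const || is_const(exposure_prob(obs))
}

#' Feasibility envelope for weighted averages
#'
#' Any average of a finite set of stratum values under non-negative weights
#' lies in the closed interval between the smallest and largest value, and
#' every point of that interval is attainable.  A marginal effect outside the
#' envelope therefore proves that *no* non-negative weight scheme can recover
#' it — the mechanism behind the classic odds-ratio counterexample, where two
#' strata share a causal odds ratio of 3 yet the marginal causal odds ratio is
#' 2.83.
#'
#' @param stratum_values Named or unnamed numeric vector of stratum effects
#'   (at least one).
#' @param marginal The marginal effect to locate.
#' @param tol Absolute slack added to both ends of the envelope.
#' @return `TRUE` if the marginal lies inside `[min - tol, max + tol]`,
#'   otherwise `FALSE` (a certificate that no weights exist).
#' @examples
#' feasibility_envelope(c(3, 3), 2.8286)          # FALSE: impossible
#' feasibility_envelope(c(0.25, 0.6667), 0.428)   # TRUE
#' @export
feasibility_envelope <- function(stratum_values, marginal, tol = 1e-10) {
  stopifnot(is.numeric(stratum_values), length(stratum_values) >= 1L,
            is.numeric(marginal), length(marginal) == 1L)
  min(stratum_values) - tol <= marginal && marginal <= max(stratum_values) + tol
}
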