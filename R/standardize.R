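# Identification of the RR(-) collapsibility weights from observed data,
# the standardized risk ratio, transport to target populations, and the
# unmeasured-confounding bias demonstration.

#' Miettinen's weights from an observed stratified table
#'
#' Computes the identified risk-ratio standardization weights
#' \eqn{w_v = \Pr(V=v)\,\Pr(Y=1 \mid A=0, V=v)} from observed counts.  Under
#' partial exchangeability \eqn{Y^{a=0} \perp A \mid V} (no unmeasured
#' confounding) and consistency, these are proportional to the counterfactual
#' collapsibility weights \eqn{\Pr(V=v \mid Y^{a=0}=1)} of the causal RR(−) —
#' the proportionality constant \eqn{\Pr(Y^{a=0}=1)} is common to all strata
#' and cancels in any weighted average, so it is never needed numerically.
#' That assumption is a property of how the data arose and cannot be verified
#' from the table itself.
#'
#' @param obs An [observed_population()]; the unexposed arm must be nonempty
#'   in every stratum.
#' @return A [weight_scheme()], unnormalized.
#' @examples
#' obs <- observed_population(c("men", "women"), c(100, 200), c(400, 300),
#'                            c(400, 300), c(100, 200))
#' miettinen_weights(obs)  # men 0.4, women 0.3
#' @export
miettinen_weights <- function(obs) {
  stopifnot(inherits(obs, "observed_population"))
  p0 <- p0_checked(obs, "rr_minus")
  weight_scheme(stats::setNames(stratum_prevalence(obs) * p0, obs$label))
}

#' Standardized risk ratio
#'
#' The ratio of the exposed and unexposed risks, each directly standardized to
#' the study covariate distribution:
#' \deqn{SRR = \frac{\sum_v \Pr(Y=1 \mid A=1, V=v)\,\Pr(V=v)}
#'                  {\sum_v \Pr(Y=1 \mid A=0, V=v)\,\Pr(V=v)}.}
#' Under conditional exchangeability given \eqn{V} this equals the marginal
#' causal risk ratio \eqn{\Pr(Y^{a=1}=1)/\Pr(Y^{a=0}=1)}.  It is also,
#' algebraically and on any table, identical to the weighted average of the
#' stratum-specific risk ratios under [miettinen_weights()] — the route
#' computed by [weighted_average_rr()].
#'
#' @param obs An [observed_population()]; both arms must be nonempty in every
#'   stratum and the standardized unexposed risk must be positive.
#' @return The standardized risk ratio, a numeric scalar.
#' @examples
#' obs <- observed_population(c("men", "women"), c(100, 200), c(400, 300),
#'                            c(400, 300), c(100, 200))
#' standardized_rr(obs)     # 0.4286
#' weighted_average_rr(obs) # identical
#' @export
standardized_rr <- function(obs) {
  stopifnot(inherits(obs, "observed_population"))
  ne <- obs$exposed_cases + obs$exposed_noncases
  bad <- which(ne <= 0)
  if (length(bad)) stop_undefined_measure("rr_minus", obs$label[bad[1]], "no exposed individuals")
  p1 <- obs$exposed_cases / ne
  p0 <- p0_checked(obs, "rr_minus")
  prev <- stratum_prevalence(obs)
  denom <- sum(p0 * prev)
  if (denom <= 0) stop_undefined_measure("rr_minus", NULL, "standardized unexposed risk is 0")
  sum(p1 * prev) / denom
}

#' @rdname standardized_rr
#' @export
weighted_average_rr <- function(obs) {
  stopifnot(inherits(obs, "observed_population"))
  w <- miettinen_weights(obs)
  wv <- weights_for(w, obs$label)
  keep <- obs$label[wv > 0]
  if (!length(keep)) stop_degenerate_population("all Miettinen weights are zero")
  vals <- vapply(keep, function(l) assoc_stratum_effect(obs, "rr_minus", l), numeric(1))
  weighted_average(vals, weight_scheme(wv[keep]))
}

#' Construct a target-population summary
#'
#' Holds what is needed to transport stratum-specific risk ratios to an
#' external target population: the target's covariate distribution
#' \eqn{\Pr(V=v)} and its baseline risks \eqn{\Pr(Y=1 \mid A=0, V=v)}.
#'
#' @param label Character vector of unique stratum labels.
#' @param prevalence Target stratum probabilities, summing to 1 within `1e-6`.
#' @param baseline_risk Target baseline risks in `[0, 1]`.
#' @return An object of class `target_population_summary` (a data frame).
#' @seealso [transport_rr()], [read_target_csv()]
#' @export
target_population_summary <- function(label, prevalence, baseline_risk) {
  label <- check_labels(label)
  n <- length(label)
  if (length(prevalence) != n || length(baseline_risk) != n) {
    stop_config("label, prevalence and baseline_risk must have equal length")
  }
  prevalence <- check_prob(prevalence, "prevalence")
  if (abs(sum(prevalence) - 1) > PREV_SUM_TOL) {
    stop_config(sprintf("target prevalences must sum to 1 (got %.8f)", sum(prevalence)))
  }
  out <- data.frame(label = label, prevalence = prevalence,
                    baseline_risk = check_prob(baseline_risk, "baseline_risk"),
                    stringsAsFactors = FALSE)
  class(out) <- c("target_population_summary", "data.frame")
  out
}

#' Transport stratum risk ratios to a target population
#'
#' Standardizes study-population stratum-specific risk ratios to an external
#' target population by averaging them under the target's Miettinen weights
#' \eqn{\Pr(V=v)\,\Pr(Y=1 \mid A=0, V=v)}, both taken from the target.  Valid
#' as a causal marginal risk ratio for the target when the stratum risk
#' ratios transport (no effect-measure modification by unmeasured factors)
#' and confounding is controlled in the study.
#'
#' @param stratum_rrs Named numeric vector of study stratum risk ratios; must
#'   cover every target stratum.
#' @param target A [target_population_summary()].
#' @return The transported risk ratio, a numeric scalar.
#' @examples
#' target <- target_population_summary(c("men", "women"), c(0.3, 0.7), c(0.8, 0.6))
#' transport_rr(c(men = 0.25, women = 0.6667), target)
#' @export
transport_rr <- function(stratum_rrs, target) {
  stopifnot(inherits(target, "target_population_summary"))
  if (is.null(names(stratum_rrs))) stop_config("stratum_rrs must be a named vector")
  missing <- setdiff(target$label, names(stratum_rrs))
  if (length(missing)) {
    stop_config(sprintf("no study risk ratio for target strata: %s",
                        paste(missing, collapse = ", ")))
  }
  w <- target$prevalence * target$baseline_risk
  if (sum(w) <= 0) stop_degenerate_population("all target weights are zero")
  weighted_average(stratum_rrs, weight_scheme(stats::setNames(w, target$label)))
}

#' Standardization weights for an entirely unexposed target
#'
#' When experimental results are standardized to a target population in which
#' everyone is unexposed, consistency gives \eqn{Y^{a=0} = Y} for every
#' individual, so the counterfactual weights \eqn{\Pr(V=v \mid Y^{a=0}=1)}
#' are identified directly as the covariate distribution among the target's
#' observed cases, \eqn{\Pr(V=v \mid Y=1)}.
#'
#' @param target_cases Named numeric vector of case counts per stratum in the
#'   unexposed target; total must be positive.
#' @return A [weight_scheme()] normalized to sum to 1 (the empirical
#'   \eqn{\Pr(V=v \mid Y=1)}); weighted averages are invariant to this
#'   scaling.
#' @examples
#' unexposed_target_weights(c(men = 400, women = 300))  # 4/7, 3/7
#' @export
unexposed_target_weights <- function(target_cases) {
  if (is.null(names(target_cases)) || !is.numeric(target_cases)) {
    stop_config("target_cases must be a named numeric vector")
  }
  if (anyNA(target_cases) || any(target_cases < 0)) {
    stop_config("case counts must be non-negative")
  }
  if (sum(target_cases) <= 0) stop_degenerate_population("no cases in the target population")
  weight_scheme(target_cases / sum(target_cases))
}

#' Demonstrate bias from unmeasured confounding and erroneous weights
#'
#' Given a latent-confounder scenario, computes three quantities: the true
#' marginal causal risk ratio (from the scenario's own counterfactual risks,
#' marginalized over both covariates); the standardized risk ratio obtained by
#' standardizing the confounded observed data over the observed covariate
#' only; and the weighted average of observed stratum risk ratios under the
#' Miettinen weights identified from the same confounded data.  When the
#' assignment mechanism depends on the latent covariate, the identified
#' weights are erroneous and both observed-data routes can deviate from the
#' truth — in either direction and by any amount; the report asserts nothing,
#' it only measures.  When assignment is independent of the latent covariate
#' within strata, all three coincide.
#'
#' @param scn A [confounded_scenario()].
#' @return An object of class `bias_demo_report`: a list with elements
#'   `true_rr`, `srr`, `weighted_avg_rr`, their absolute deviations from the
#'   truth (`srr_bias`, `weighted_avg_bias`), and the factored-out constant
#'   `pr_y0_marginal` \eqn{= \Pr(Y^{a=0}=1)} for transparency.
#' @examples
#' scn <- demo_scenario()
#' bias_demo(scn)
#' @export
bias_demo <- function(scn) {
  stopifnot(inherits(scn, "confounded_scenario"))
  r1 <- sum(scn$prevalence * scn$risk_treated)
  r0 <- sum(scn$prevalence * scn$risk_untreated)
  if (r0 <= 0) stop_undefined_measure("rr_minus", NULL, "true baseline risk is 0")
  obs <- observe_confounded(scn)
  srr <- standardized_rr(obs)
  wavg <- weighted_average_rr(obs)
  out <- list(
    true_rr = r1 / r0,
    srr = srr,
    weighted_avg_rr = wavg,
    srr_bias = abs(srr - r1 / r0),
    weighted_avg_bias = abs(wavg - r1 / r0),
    pr_y0_marginal = r0
  )
  class(out) <- "bias_demo_report"
  out
}

#' @export
print.bias_demo_report <- function(x, digits = 4, ...) {
  cat("Unmeasured-confounding bias demonstration\n")
  cat(sprintf("  true marginal causal RR : %.*f\n", digits, x$true_rr))
  cat(sprintf("  SRR from observed data  : %.*f  (|bias| %.*g)\n",
              digits, x$srr, digits, x$srr_bias))
  cat(sprintf("  weighted-average RR     : %.*f  (|bias| %.*g)\n",
              digits, x$weighted_avg_rr, digits, x$weighted_avg_bias))
  cat(sprintf("  Pr(Y^{a=0}=1) marginal  : %.*f\n", digits, x$pr_y0_marginal))
  invisible(x)
}

#' Packaged confounded demonstration scenario
#'
#' A fixed two-by-two (observed by latent) scenario in which both the exposure
#' assignment and the counterfactual risks depend on the latent covariate
#' within each observed stratum, so that stratified standardization over the
#' observed covariate alone is biased.  All cells share a true stratum risk
#' ratio of 0.5, making the direction and size of the bias easy to read off a
#' [bias_demo()] report.
#'
#' @return A [confounded_scenario()].
#' @export
demo_scenario <- function() {
  confounded_scenario(
    v = c("v1", "v1", "v2", "v2"),
    u = c("u1", "u2", "u1", "u2"),
    prevalence = c(0.25, 0.25, 0.25, 0.25),
    risk_untreated = c(0.2, 0.6, 0.3, 0.7),
    risk_treated = c(0.1, 0.3, 0.15, 0.35),
    assignment = c(0.8, 0.2, 0.7, 0.3)
  )
}
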