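# Data model: counterfactual populations, observed stratified 2x2 tables,
# latent-confounder scenarios, and a seeded synthetic generator.

PROB_TOL <- 1e-9      # slack when checking a single probability lies in [0,1]
PREV_SUM_TOL <- 1e-6  # absolute tolerance for sum(prevalence) == 1

check_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_config(sprintf("%s must be numeric with no missing values", what))
  }
  if (any(x < -PROB_TOL | x > 1 + PROB_TOL)) {
    stop_config(sprintf("%s must lie in [0, 1]", what))
  }
  pmin(pmax(as.numeric(x), 0), 1)
}

check_labels <- function(label) {
  label <- as.character(label)
  if (length(label) < 1L) stop_config("at least one stratum is required")
  if (anyNA(label) || any(!nzchar(label))) stop_config("stratum labels must be non-empty")
  if (anyDuplicated(label)) stop_config("stratum labels must be unique")
  label
}

#' Construct a counterfactual population
#'
#' A counterfactual population summarizes a target population stratified by a
#' finite categorical baseline covariate \eqn{V}.  Each stratum \eqn{v} carries
#' its probability mass \eqn{\Pr(V=v)} and the two marginal counterfactual
#' risks: the risk of the outcome if everyone in the stratum were untreated,
#' \eqn{\Pr(Y^{a=0}=1 \mid V=v)}, and if everyone were treated,
#' \eqn{\Pr(Y^{a=1}=1 \mid V=v)}.  All causal effect measures and
#' collapsibility weights provided by this package are functionals of these
#' marginals only; the joint distribution of the two potential outcomes is
#' never needed and is not represented.
#'
#' @param label Character vector of unique stratum labels.
#' @param prevalence Numeric vector of stratum probabilities; must sum to 1
#'   within an absolute tolerance of `1e-6` (violations are rejected, never
#'   renormalized).
#' @param risk_untreated,risk_treated Numeric vectors of counterfactual risks
#'   in `[0, 1]`.
#'
#' @return An object of class `counterfactual_population`: a data frame with
#'   columns `label`, `prevalence`, `risk_untreated`, `risk_treated`, one row
#'   per stratum in input order.
#'
#' @examples
#' # the randomized-trial population used to show odds-ratio non-collapsibility
#' pop <- counterfactual_population(
#'   label          = c("men", "women"),
#'   prevalence     = c(0.25, 0.75),
#'   risk_untreated = c(0.50, 0.25),
#'   risk_treated   = c(0.75, 0.50)
#' )
#' causal_marginal_risks(pop)
#' @seealso [observe()], [random_population()], [causal_marginal_effect()]
#' @export
counterfactual_population <- function(label, prevalence, risk_untreated, risk_treated) {
  label <- check_labels(label)
  n <- length(label)
  if (length(prevalence) != n || length(risk_untreated) != n || length(risk_treated) != n) {
    stop_config("label, prevalence, risk_untreated and risk_treated must have equal length")
  }
  prevalence <- check_prob(prevalence, "prevalence")
  if (abs(sum(prevalence) - 1) > PREV_SUM_TOL) {
    stop_config(sprintf(
      "stratum prevalences must sum to 1 (got %.8f); renormalize explicitly if intended",
      sum(prevalence)
    ))
  }
  out <- data.frame(
    label = label,
    prevalence = prevalence,
    risk_untreated = check_prob(risk_untreated, "risk_untreated"),
    risk_treated = check_prob(risk_treated, "risk_treated"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("counterfactual_population", "data.frame")
  out
}

#' Construct an observed stratified 2x2 population
#'
#' Holds the counts of a stratified exposure-by-outcome table: for each level
#' of the stratifying covariate \eqn{V}, the exposed cases and non-cases and
#' the unexposed cases and non-cases.  Counts are non-negative reals so that
#' expected (infinite-population) counts produced by [observe()] are
#' representable exactly; no sampling model is attached.
#'
#' @param label Character vector of unique stratum labels.
#' @param exposed_cases,exposed_noncases,unexposed_cases,unexposed_noncases
#'   Non-negative numeric count vectors.  Every stratum total must be
#'   positive.
#'
#' @return An object of class `observed_population`: a data frame with the
#'   five columns above, one row per stratum in input order.
#'
#' @examples
#' obs <- observed_population(
#'   label = c("men", "women"),
#'   exposed_cases = c(100, 200), exposed_noncases = c(400, 300),
#'   unexposed_cases = c(400, 300), unexposed_noncases = c(100, 200)
#' )
#' standardized_rr(obs)
#' @seealso [read_observed_csv()], [assoc_marginal_effect()], [miettinen_weights()]
#' @export
observed_population <- function(label, exposed_cases, exposed_noncases,
                                unexposed_cases, unexposed_noncases) {
  label <- check_labels(label)
  n <- length(label)
  counts <- list(
    exposed_cases = exposed_cases, exposed_noncases = exposed_noncases,
    unexposed_cases = unexposed_cases, unexposed_noncases = unexposed_noncases
  )
  for (nm in names(counts)) {
    x <- counts[[nm]]
    if (length(x) != n || !is.numeric(x) || anyNA(x)) {
      stop_config(sprintf("%s must be numeric of length %d with no missing values", nm, n))
    }
    if (any(x < 0)) stop_config(sprintf("%s must be non-negative", nm))
  }
  total <- exposed_cases + exposed_noncases + unexposed_cases + unexposed_noncases
  if (any(total <= 0)) stop_config("every stratum must have a positive total count")
  out <- data.frame(
    label = label,
    exposed_cases = as.numeric(exposed_cases),
    exposed_noncases = as.numeric(exposed_noncases),
    unexposed_cases = as.numeric(unexposed_cases),
    unexposed_noncases = as.numeric(unexposed_noncases),
    stringsAsFactors = FALSE
  )
  class(out) <- c("observed_population", "data.frame")
  out
}

# ---- derived quantities of an observed population ------------------------

#' Derived per-stratum quantities of an observed population
#'
#' These accessors compute (never store) the derived probabilities of an
#' observed stratified table: the stratum totals, the stratum prevalences
#' \eqn{\Pr(V=v)}, the exposure probabilities \eqn{\Pr(A=1 \mid V=v)}, and the
#' conditional outcome risks \eqn{p_{1v} = \Pr(Y=1 \mid A=1, V=v)} and
#' \eqn{p_{0v} = \Pr(Y=1 \mid A=0, V=v)}.  Risks in an empty exposure arm are
#' returned as `NaN`; effect-measure functions turn those into typed
#' `collapsr_undefined_measure` errors.
#'
#' @param obs An [observed_population()].
#' @return A named numeric vector, one element per stratum.
#' @examples
#' obs <- observed_population("all", 10, 90, 20, 80)
#' risk_exposed(obs)    # 0.1
#' risk_unexposed(obs)  # 0.2
#' @name observed-derived
NULL

#' @rdname observed-derived
#' @export
stratum_totals <- function(obs) {
  stopifnot(inherits(obs, "observed_population"))
  with(obs, stats::setNames(
    exposed_cases + exposed_noncases + unexposed_cases + unexposed_noncases, label
  ))
}

#' @rdname observed-derived
#' @export
stratum_prevalence <- function(obs) {
  tot <- stratum_totals(obs)
  tot / sum(tot)
}

#' @rdname observed-derived
#' @export
exposure_prob <- function(obs) {
  stopifnot(inherits(obs, "observed_population"))
  with(obs, stats::setNames(
    (exposed_cases + exposed_noncases) /
      (exposed_cases + exposed_noncases + unexposed_cases + unexposed_noncases),
    label
  ))
}

#' @rdname observed-derived
#' @export
risk_exposed <- function(obs) {
  stopifnot(inherits(obs, "observed_population"))
  with(obs, stats::setNames(exposed_cases / (exposed_cases + exposed_noncases), label))
}

#' @rdname observed-derived
#' @export
risk_unexposed <- function(obs) {
  stopifnot(inherits(obs, "observed_population"))
  with(obs, stats::setNames(unexposed_cases / (unexposed_cases + unexposed_noncases), label))
}

# ---- confounded scenario -------------------------------------------------

#' Construct a latent-confounder scenario
#'
#' Describes a population jointly stratified by an observed covariate \eqn{V}
#' and a latent covariate \eqn{U}.  Each \eqn{(v, u)} cell carries its joint
#' probability mass, both counterfactual risks, and the exposure assignment
#' probability \eqn{\Pr(A=1 \mid V=v, U=u)}.  When the assignment or the risks
#' vary over \eqn{u} within a level of \eqn{v}, \eqn{U} is an unmeasured
#' confounder and stratified standardization on \eqn{V} alone is biased; the
#' scenario exists to make that bias computable against its own counterfactual
#' truth (see [bias_demo()]).
#'
#' @param v,u Character vectors: observed and latent stratum labels; the
#'   `(v, u)` pairs must be unique.
#' @param prevalence Joint cell probabilities, summing to 1 within `1e-6`.
#' @param risk_untreated,risk_treated Counterfactual risks per cell, in `[0, 1]`.
#' @param assignment Exposure probabilities \eqn{\Pr(A=1 \mid V=v, U=u)} per
#'   cell, in `[0, 1]`.
#'
#' @return An object of class `confounded_scenario`: a data frame with columns
#'   `v`, `u`, `prevalence`, `risk_untreated`, `risk_treated`, `assignment`.
#' @examples
#' scn <- confounded_scenario(
#'   v = c("v1", "v1"), u = c("u1", "u2"),
#'   prevalence = c(0.5, 0.5),
#'   risk_untreated = c(0.2, 0.6), risk_treated = c(0.1, 0.3),
#'   assignment = c(0.8, 0.2)
#' )
#' observe_confounded(scn)
#' @seealso [observe_confounded()], [marginalize_scenario()], [bias_demo()]
#' @export
confounded_scenario <- function(v, u, prevalence, risk_untreated, risk_treated, assignment) {
  v <- as.character(v); u <- as.character(u)
  n <- length(v)
  if (n < 1L) stop_config("a scenario needs at least one (v, u) cell")
  lens <- lengths(list(u, prevalence, risk_untreated, risk_treated, assignment))
  if (any(lens != n)) stop_config("all scenario columns must have equal length")
  if (anyDuplicated(paste(v, u, sep = "\r"))) stop_config("(v, u) cell labels must be unique")
  prevalence <- check_prob(prevalence, "cell prevalence")
  if (abs(sum(prevalence) - 1) > PREV_SUM_TOL) {
    stop_config(sprintf("cell prevalences must sum to 1 (got %.8f)", sum(prevalence)))
  }
  out <- data.frame(
    v = v, u = u, prevalence = prevalence,
    risk_untreated = check_prob(risk_untreated, "risk_untreated"),
    risk_treated = check_prob(risk_treated, "risk_treated"),
    assignment = check_prob(assignment, "assignment"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("confounded_scenario", "data.frame")
  out
}

# ---- observation (expected-count semantics) ------------------------------

#' Generate the observed table implied by a counterfactual population
#'
#' Applies an exposure-assignment mechanism that depends only on the observed
#' covariate \eqn{V} to a counterfactual population, and returns the expected
#' stratified 2x2 table on a unit grand total.  By consistency, the observed
#' conditional risks equal the counterfactual risks:
#' \eqn{\Pr(Y=1 \mid A=a, V=v) = \Pr(Y^{a}=1 \mid V=v)}, which holds here
#' because assignment within a stratum is independent of the potential
#' outcomes by construction.  Counts are expected proportions: there is no
#' sampling noise, and stratum totals equal the stratum prevalences.
#'
#' @param pop A [counterfactual_population()].
#' @param assignment Either a single probability applied to every stratum, or
#'   a named numeric vector mapping each stratum label to
#'   \eqn{\Pr(A=1 \mid V=v)}.
#' @return An [observed_population()] with real-valued expected counts.
#' @examples
#' pop <- counterfactual_population(
#'   c("men", "women"), c(0.5, 0.5), c(0.8, 0.6), c(0.2, 0.4)
#' )
#' obs <- observe(pop, 0.5)
#' # multiply by 2000 to recover a whole-number table of 2000 subjects
#' round(obs$exposed_cases * 2000)
#' @export
observe <- function(pop, assignment) {
  stopifnot(inherits(pop, "counterfactual_population"))
  if (is.null(names(assignment))) {
    if (length(assignment) != 1L) {
      stop_config("assignment must be a single probability or a named vector")
    }
    assignment <- stats::setNames(rep(assignment, nrow(pop)), pop$label)
  }
  missing <- setdiff(pop$label, names(assignment))
  if (length(missing)) {
    stop_config(sprintf(
      "assignment map is missing strata: %s", paste(missing, collapse = ", ")
    ))
  }
  e <- check_prob(assignment[pop$label], "assignment probability")
  observed_population(
    label = pop$label,
    exposed_cases = pop$prevalence * e * pop$risk_treated,
    exposed_noncases = pop$prevalence * e * (1 - pop$risk_treated),
    unexposed_cases = pop$prevalence * (1 - e) * pop$risk_untreated,
    unexposed_noncases = pop$prevalence * (1 - e) * (1 - pop$risk_untreated)
  )
}

#' Generate confounded observed data from a latent-confounder scenario
#'
#' Computes expected counts within each \eqn{(v, u)} cell exactly as
#' [observe()] does, then sums over the latent covariate \eqn{u}, so that the
#' returned table is indexed by the observed covariate \eqn{v} only.  When the
#' assignment probability varies over \eqn{u} within a stratum, the resulting
#' conditional risks \eqn{\Pr(Y=1 \mid A=a, V=v)} no longer equal the
#' stratum's marginal counterfactual risks: \eqn{U} confounds within \eqn{V}.
#'
#' @param scn A [confounded_scenario()].
#' @return An [observed_population()] indexed by the observed labels `v`, in
#'   order of first appearance.
#' @seealso [marginalize_scenario()] for the counterfactual truth of the same
#'   scenario.
#' @export
observe_confounded <- function(scn) {
  stopifnot(inherits(scn, "confounded_scenario"))
  e <- scn$assignment
  cell <- data.frame(
    v = scn$v,
    ec = scn$prevalence * e * scn$risk_treated,
    en = scn$prevalence * e * (1 - scn$risk_treated),
    uc = scn$prevalence * (1 - e) * scn$risk_untreated,
    un = scn$prevalence * (1 - e) * (1 - scn$risk_untreated)
  )
  v_order <- unique(scn$v)
  agg <- lapply(c("ec", "en", "uc", "un"), function(col) {
    vapply(v_order, function(vv) sum(cell[[col]][cell$v == vv]), numeric(1))
  })
  observed_population(
    label = v_order,
    exposed_cases = agg[[1]], exposed_noncases = agg[[2]],
    unexposed_cases = agg[[3]], unexposed_noncases = agg[[4]]
  )
}

#' Marginalize a latent-confounder scenario over the latent covariate
#'
#' Collapses the \eqn{(v, u)} cells of a scenario into a counterfactual
#' population indexed by \eqn{v} alone: stratum prevalences are summed over
#' \eqn{u} and counterfactual risks are prevalence-weighted averages within
#' each \eqn{v}.  This is the population a fully randomized trial on the same
#' individuals would characterize, and supplies the truth against which
#' [bias_demo()] measures bias.
#'
#' @param scn A [confounded_scenario()].
#' @return A [counterfactual_population()] indexed by the observed labels.
#' @export
marginalize_scenario <- function(scn) {
  stopifnot(inherits(scn, "confounded_scenario"))
  v_order <- unique(scn$v)
  prev <- vapply(v_order, function(vv) sum(scn$prevalence[scn$v == vv]), numeric(1))
  wmean <- function(col) {
    vapply(v_order, function(vv) {
      i <- scn$v == vv
      sum(scn[[col]][i] * scn$prevalence[i]) / sum(scn$prevalence[i])
    }, numeric(1))
  }
  counterfactual_population(
    label = v_order, prevalence = prev,
    risk_untreated = wmean("risk_untreated"), risk_treated = wmean("risk_treated")
  )
}

# ---- synthetic generator -------------------------------------------------

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a random counterfactual population
#'
#' Draws a seeded synthetic population for property testing and simulation:
#' stratum prevalences are uniform on the probability simplex (normalized
#' standard exponentials) and counterfactual risks are independent uniforms on
#' `risk_range`.  The default range `(0.01, 0.99)` keeps every risk away from
#' 0 and 1 so that all six effect measures are defined in every stratum; pass
#' `risk_range = c(0, 1)` to exercise degenerate edge cases deliberately.
#'
#' @param n_strata Number of strata (at least 1).
#' @param seed Integer seed; the same `(n_strata, seed)` pair always yields
#'   the identical population, and the caller's RNG state is left untouched.
#' @param risk_range Length-2 numeric: lower and upper bound for the risks.
#' @return A [counterfactual_population()] with labels `s1 ... s<n>`.
#' @examples
#' pop <- random_population(4, seed = 7)
#' sum(pop$prevalence)  # 1
#' @export
random_population <- function(n_strata, seed, risk_range = c(0.01, 0.99)) {
  if (!is.numeric(n_strata) || length(n_strata) != 1L || n_strata < 1) {
    stop("n_strata must be a positive integer")
  }
  n_strata <- as.integer(n_strata)
  stopifnot(length(risk_range) == 2L, risk_range[1] >= 0, risk_range[2] <= 1,
            risk_range[1] <= risk_range[2])
  with_seed(seed, {
    g <- stats::rexp(n_strata)
    prev <- g / sum(g)
    counterfactual_population(
      label = paste0("s", seq_len(n_strata)),
      prevalence = prev,
      risk_untreated = stats::runif(n_strata, risk_range[1], risk_range[2]),
      risk_treated = stats::runif(n_strata, risk_range[1], risk_range[2])
    )
  })
}

# ---- printing ------------------------------------------------------------

#' @export
print.counterfactual_population <- function(x, ...) {
  cat(sprintf("Counterfactual population: %d strata\n", nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
print.observed_population <- function(x, ...) {
  cat(sprintf("Observed stratified 2x2 population: %d strata, grand total %g\n",
              nrow(x), sum(stratum_totals(x))))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' @export
print.confounded_scenario <- function(x, ...) {
  cat(sprintf("Latent-confounder scenario: %d cells over %d observed strata\n",
              nrow(x), length(unique(x$v))))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

# Preserve class when subsetting whole rows.
#' @export
`[.counterfactual_population` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("label", "prevalence", "risk_untreated", "risk_treated")
                                %in% names(out))) {
    class(out) <- c("counterfactual_population", "data.frame")
  }
  out
}
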