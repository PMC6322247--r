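# Typed error conditions.  Every error raised by the package carries the
# class "collapsr_error" plus one specific subclass, so callers (and the CLI)
# can branch on the failure mode instead of matching message text.

collapsr_error <- function(message, class, call = sys.call(-1), ...) {
  structure(
    class = c(class, "collapsr_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

#' @rdname collapsr-conditions
#' @name collapsr-conditions
#' @title Error conditions used by collapsr
#'
#' @description
#' All errors signalled by the package inherit from `collapsr_error` together
#' with one of the specific classes below:
#'
#' * `collapsr_undefined_measure` — an effect measure was requested whose
#'   denominator is zero (for example a risk ratio in a stratum with zero
#'   baseline risk, or an associational measure in a population with an empty
#'   exposure arm).  The condition names the measure and, where relevant, the
#'   stratum.
#' * `collapsr_no_exact_weights` — collapsibility weights were requested for
#'   the odds ratio, for which no generally applicable weights exist.
#' * `collapsr_degenerate_population` — a weighted average was requested under
#'   a weight scheme whose weights are all zero.
#' * `collapsr_config_error` — malformed or inconsistent user input (bad CSV
#'   or config file, assignment map missing a stratum, label mismatch between
#'   a study and a target population).
#'
#' Use `tryCatch(expr, collapsr_undefined_measure = ...)` etc. to handle them.
#' @keywords internal
NULL

stop_undefined_measure <- function(measure, stratum = NULL, reason = "zero denominator") {
  where <- if (is.null(stratum)) "marginally" else sprintf("in stratum '%s'", stratum)
  stop(collapsr_error(
    sprintf("measure '%s' is undefined %s (%s)", measure, where, reason),
    class = "collapsr_undefined_measure",
    measure = measure, stratum = stratum
  ))
}

stop_no_exact_weights <- function() {
  stop(collapsr_error(
    paste0(
      "no exact collapsibility weights exist for the odds ratio: ",
      "a population with equal stratum-specific causal odds ratios can have a ",
      "different marginal causal odds ratio, so no non-negative weight scheme ",
      "can recover the marginal value in general"
    ),
    class = "collapsr_no_exact_weights"
  ))
}

stop_degenerate_population <- function(detail = "all weights are zero") {
  stop(collapsr_error(
    sprintf("degenerate population: %s", detail),
    class = "collapsr_degenerate_population"
  ))
}

stop_config <- function(message) {
  stop(collapsr_error(message, class = "collapsr_config_error"))
}
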