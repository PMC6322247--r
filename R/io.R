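# File formats.  Counterfactual populations and confounder scenarios travel
# as YAML configs (one mapping per stratum/cell); observed tables and target
# summaries travel as plain CSV with fixed headers.

OBSERVED_HEADER <- c("stratum", "exposed_cases", "exposed_noncases",
                     "unexposed_cases", "unexposed_noncases")
TARGET_HEADER <- c("stratum", "prevalence", "baseline_risk")
CASES_HEADER <- c("stratum", "cases")

read_csv_checked <- function(path, header) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  first <- tryCatch(readLines(path, n = 1L, warn = FALSE), error = function(e) character())
  if (length(first) == 0L) stop_config(sprintf("empty file: %s", path))
  got <- trimws(strsplit(first, ",", fixed = TRUE)[[1]])
  if (!identical(got, header)) {
    stop_config(sprintf(
      "%s: line 1: expected header '%s', got '%s'",
      path, paste(header, collapse = ","), paste(got, collapse = ",")
    ))
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c("character",
                    rep("numeric", length(header) - 1L))),
    error = function(e) stop_config(sprintf("%s: %s", path, conditionMessage(e))),
    warning = function(w) stop_config(sprintf("%s: %s", path, conditionMessage(w)))
  )
  if (nrow(df) == 0L) stop_config(sprintf("%s: no data rows", path))
  if (anyNA(df)) {
    bad <- which(!stats::complete.cases(df))[1]
    stop_config(sprintf("%s: line %d: missing or non-numeric value", path, bad + 1L))
  }
  df
}

#' Read and write observed populations as CSV
#'
#' The CSV dialect is UTF-8, comma-separated, with the exact header
#' `stratum,exposed_cases,exposed_noncases,unexposed_cases,unexposed_noncases`
#' and one row per stratum.  Counts may be real-valued (expected counts).
#'
#' @param path File path.
#' @param obs An [observed_population()].
#' @return `read_observed_csv()` returns an [observed_population()];
#'   `write_observed_csv()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' obs <- observed_population(c("men", "women"), c(100, 200), c(400, 300),
#'                            c(400, 300), c(100, 200))
#' write_observed_csv(obs, f)
#' identical(read_observed_csv(f)$exposed_cases, obs$exposed_cases)
#' @export
read_observed_csv <- function(path) {
  df <- read_csv_checked(path, OBSERVED_HEADER)
  observed_population(
    label = df$stratum,
    exposed_cases = df$exposed_cases, exposed_noncases = df$exposed_noncases,
    unexposed_cases = df$unexposed_cases, unexposed_noncases = df$unexposed_noncases
  )
}

#' @rdname read_observed_csv
#' @export
write_observed_csv <- function(obs, path) {
  stopifnot(inherits(obs, "observed_population"))
  num <- function(x) sub("\\.?0+$", "", sprintf("%.17f", x))  # full precision
  lines <- c(
    paste(OBSERVED_HEADER, collapse = ","),
    sprintf("%s,%s,%s,%s,%s", obs$label,
            num(obs$exposed_cases), num(obs$exposed_noncases),
            num(obs$unexposed_cases), num(obs$unexposed_noncases))
  )
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read and write counterfactual-population configs
#'
#' Populations are stored as YAML with a top-level `strata` list; each entry
#' is a mapping with keys `label`, `prevalence`, `risk_untreated`,
#' `risk_treated`.  Confounder scenarios use a top-level `cells` list whose
#' entries add keys `u` (latent stratum label, with `v` replacing `label`) and
#' `assignment`.
#'
#' @param path File path.
#' @param pop A [counterfactual_population()].
#' @param scn A [confounded_scenario()].
#' @return The read functions return the reconstructed object; the write
#'   functions return `path` invisibly.
#' @export
read_population_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_config(sprintf("%s: %s", path, conditionMessage(e))))
  if (is.null(cfg$strata) || !length(cfg$strata)) {
    stop_config(sprintf("%s: config must contain a non-empty 'strata' list", path))
  }
  field <- function(key) {
    vals <- lapply(cfg$strata, `[[`, key)
    if (any(vapply(vals, is.null, logical(1)))) {
      stop_config(sprintf("%s: every stratum needs a '%s' field", path, key))
    }
    unlist(vals)
  }
  counterfactual_population(
    label = as.character(field("label")),
    prevalence = as.numeric(field("prevalence")),
    risk_untreated = as.numeric(field("risk_untreated")),
    risk_treated = as.numeric(field("risk_treated"))
  )
}

#' @rdname read_population_config
#' @export
write_population_config <- function(pop, path) {
  stopifnot(inherits(pop, "counterfactual_population"))
  strata <- lapply(seq_len(nrow(pop)), function(i) list(
    label = pop$label[i], prevalence = pop$prevalence[i],
    risk_untreated = pop$risk_untreated[i], risk_treated = pop$risk_treated[i]
  ))
  yaml::write_yaml(list(strata = strata), path, precision = 17)
  invisible(path)
}

#' @rdname read_population_config
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_config(sprintf("%s: %s", path, conditionMessage(e))))
  if (is.null(cfg$cells) || !length(cfg$cells)) {
    stop_config(sprintf("%s: config must contain a non-empty 'cells' list", path))
  }
  field <- function(key) {
    vals <- lapply(cfg$cells, `[[`, key)
    if (any(vapply(vals, is.null, logical(1)))) {
      stop_config(sprintf("%s: every cell needs a '%s' field", path, key))
    }
    unlist(vals)
  }
  confounded_scenario(
    v = as.character(field("v")), u = as.character(field("u")),
    prevalence = as.numeric(field("prevalence")),
    risk_untreated = as.numeric(field("risk_untreated")),
    risk_treated = as.numeric(field("risk_treated")),
    assignment = as.numeric(field("assignment"))
  )
}

#' @rdname read_population_config
#' @export
write_scenario_config <- function(scn, path) {
  stopifnot(inherits(scn, "confounded_scenario"))
  cells <- lapply(seq_len(nrow(scn)), function(i) list(
    v = scn$v[i], u = scn$u[i], prevalence = scn$prevalence[i],
    risk_untreated = scn$risk_untreated[i], risk_treated = scn$risk_treated[i],
    assignment = scn$assignment[i]
  ))
  yaml::write_yaml(list(cells = cells), path, precision = 17)
  invisible(path)
}

#' Read a target-population summary from CSV
#'
#' Header must be exactly `stratum,prevalence,baseline_risk`.
#' @param path File path.
#' @return A [target_population_summary()].
#' @export
read_target_csv <- function(path) {
  df <- read_csv_checked(path, TARGET_HEADER)
  target_population_summary(df$stratum, df$prevalence, df$baseline_risk)
}

#' Read unexposed-target case counts from CSV
#'
#' Header must be exactly `stratum,cases`.
#' @param path File path.
#' @return A named numeric vector of case counts.
#' @export
read_cases_csv <- function(path) {
  df <- read_csv_checked(path, CASES_HEADER)
  if (anyDuplicated(df$stratum)) stop_config(sprintf("%s: duplicate stratum labels", path))
  stats::setNames(df$cases, df$stratum)
}
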