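#' Completeness of a surveillance source
#'
#' The fraction of the estimated true case population that one source
#' captured: `100 * source_total / n_hat`, rounded half-up to one decimal.
#'
#' @param source_total number of distinct cases the source recorded.
#' @param n_hat estimated total population size (unrounded estimates give
#'   identical one-decimal results for realistic magnitudes).
#' @return completeness percentage to one decimal.
#' @examples
#' completeness(3824, 11588) # 33.0
#' @export
completeness <- function(source_total, n_hat) {
  stopifnot(source_total > 0)
  if (n_hat < source_total)
    stop("estimate below an observed list size is impossible")
  round_half_up(100 * source_total / n_hat, 1)
}

#' Prevalence rate from an estimate and a census denominator
#'
#' @param n_hat estimated number of cases.
#' @param population census denominator (persons at risk).
#' @return prevalence percentage to one decimal.
#' @examples
#' prevalence(11588, 1078729) # 1.1
#' @export
prevalence <- function(n_hat, population) {
  stopifnot(population > 0, n_hat >= 0)
  if (n_hat > population)
    stop("estimated cases exceed the population denominator")
  round_half_up(100 * n_hat / population, 1)
}

#' Sum stratum estimates over an age-restricted subgroup
#'
#' Restricts a stratified fit to the strata whose age class lies entirely
#' at or above a cutoff (for example, a 65-and-over prevalence). The cutoff
#' must fall on a class boundary; otherwise no age-restricted total can be
#' formed from stratum-level estimates and an error asks for a compatible
#' stratification.
#'
#' @param stratum_estimates data frame with columns `age_lo`, `age_hi`
#'   (inclusive class bounds; use `Inf` for an open upper class) and
#'   `estimate`.
#' @param min_age age cutoff in years.
#' @return sum of the estimates over qualifying strata (0 when none
#'   qualify).
#' @export
age_restricted_estimate <- function(stratum_estimates, min_age) {
  need <- c("age_lo", "age_hi", "estimate")
  stopifnot(all(need %in% names(stratum_estimates)))
  lo <- stratum_estimates$age_lo
  hi <- stratum_estimates$age_hi
  splits <- lo < min_age & hi >= min_age
  if (any(splits))
    stop(sprintf(
      "cutoff %d splits stratum [%s, %s]; use a stratification with a class boundary at %d",
      min_age, lo[splits][1], hi[splits][1], min_age))
  sum(stratum_estimates$estimate[lo >= min_age])
}

#' Assemble a prevalence/completeness report
#'
#' @param n_hat population-size estimate used as numerator.
#' @param population census denominator.
#' @param source_totals named numeric vector of per-source list sizes
#'   (completeness computed for each).
#' @param scope `"all_ages"` or `"age_65_plus"` (annotation only).
#' @return list of class `prevalence_report`.
#' @export
prevalence_report <- function(n_hat, population, source_totals,
                              scope = c("all_ages", "age_65_plus")) {
  scope <- match.arg(scope)
  structure(
    list(n_hat = n_hat, population = population,
         prevalence_pct = prevalence(n_hat, population),
         completeness_pct = vapply(source_totals, completeness, 0,
                                   n_hat = n_hat),
         scope = scope),
    class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat(sprintf("Prevalence (%s): %.1f%%  [N = %s / population %s]\n",
              x$scope, x$prevalence_pct,
              format(round_half_up(x$n_hat), big.mark = ","),
              format(x$population, big.mark = ",")))
  for (s in names(x$completeness_pct))
    cat(sprintf("  completeness %s: %.1f%%\n", s, x$completeness_pct[[s]]))
  invisible(x)
}
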