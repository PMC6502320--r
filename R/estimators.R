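#' @name estimators
#' @title Closed-form two-source population-size estimators
#'
#' @description
#' With list sizes \eqn{n_1}, \eqn{n_2} and overlap \eqn{m}, the
#' Lincoln-Petersen estimator of the total population size is
#' \deqn{\hat N = n_1 n_2 / m,}
#' with variance \eqn{n_1 n_2 (n_1-m)(n_2-m)/m^3}. Chapman's nearly
#' unbiased variant is
#' \deqn{\hat N = (n_1+1)(n_2+1)/(m+1) - 1,}
#' with variance \eqn{(n_1+1)(n_2+1)(n_1-m)(n_2-m)/((m+1)^2(m+2))}, and
#' remains defined when the overlap is zero. Both use Wald 95% intervals
#' \eqn{\hat N \pm 1.96\,SE}; reported point estimates, interval bounds and
#' half-widths are rounded half-up to integers, while exact values are kept
#' alongside for downstream arithmetic.
NULL

new_estimate <- function(method, n_hat, se, inputs = NULL) {
  hw <- 1.96 * se
  structure(
    list(method = method,
         n_hat = round_half_up(n_hat),
         se = se,
         half_width = round_half_up(hw),
         ci_low = round_half_up(n_hat - hw),
         ci_high = round_half_up(n_hat + hw),
         n_hat_exact = n_hat,
         inputs = inputs),
    class = "estimate_result")
}

#' @export
print.estimate_result <- function(x, ...) {
  cat(sprintf("%s estimate: N = %s, 95%% CI [%s, %s] (half-width %s)\n",
              x$method, format(x$n_hat, big.mark = ","),
              format(x$ci_low, big.mark = ","),
              format(x$ci_high, big.mark = ","),
              format(x$half_width, big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.estimate_result <- function(x, ...) {
  data.frame(method = x$method, n_hat = x$n_hat, se = x$se,
             half_width = x$half_width, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

#' Lincoln-Petersen estimator
#'
#' @param t a [contingency_table()]; requires overlap `m >= 1`.
#' @return an `estimate_result` with fields `n_hat`, `se`, `half_width`,
#'   `ci_low`, `ci_high` (integers rounded half-up) and `n_hat_exact`.
#' @examples
#' lincoln_petersen(contingency_table(856, 2968, 1738))
#' @rdname estimators
#' @export
lincoln_petersen <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  if (t$m < 1)
    stop("Lincoln-Petersen undefined for zero overlap; use chapman()")
  n_hat <- t$n1 * t$n2 / t$m
  v <- t$n1 * t$n2 * (t$n1 - t$m) * (t$n2 - t$m) / t$m^3
  new_estimate("lincoln_petersen", n_hat, sqrt(v), as.data.frame(t))
}

#' Chapman estimator
#'
#' @rdname estimators
#' @export
chapman <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  n_hat <- (t$n1 + 1) * (t$n2 + 1) / (t$m + 1) - 1
  v <- (t$n1 + 1) * (t$n2 + 1) * (t$n1 - t$m) * (t$n2 - t$m) /
    ((t$m + 1)^2 * (t$m + 2))
  new_estimate("chapman", n_hat, sqrt(v), as.data.frame(t))
}

#' Stratified two-source estimator
#'
#' Applies the base estimator within each stratum and sums: point estimates
#' add, and under independence across strata so do variances. Strata with
#' zero overlap fall back to Chapman (which tolerates `m = 0`) when the base
#' is Lincoln-Petersen; the fallback is reported in a message.
#'
#' @param tables list of per-stratum [contingency_table()] objects.
#' @param base `"lincoln_petersen"` or `"chapman"`.
#' @return an `estimate_result` (method `stratified_lp` or
#'   `stratified_chapman`) with per-stratum results in `$strata`.
#' @export
stratified_estimate <- function(tables,
                                base = c("lincoln_petersen", "chapman")) {
  base <- match.arg(base)
  if (length(tables) == 0) stop("no stratum tables supplied")
  stopifnot(all(vapply(tables, inherits, TRUE, "contingency_table")))
  fits <- lapply(tables, function(t) {
    if (base == "lincoln_petersen" && t$m < 1) {
      if (t$union > 0)
        message(sprintf(
          "stratum '%s' has zero overlap; falling back to Chapman", t$label))
      chapman(t)
    } else if (base == "lincoln_petersen") {
      lincoln_petersen(t)
    } else {
      chapman(t)
    }
  })
  n_hat <- sum(vapply(fits, `[[`, 0, "n_hat_exact"))
  se <- sqrt(sum(vapply(fits, `[[`, 0, "se")^2))
  out <- new_estimate(
    if (base == "lincoln_petersen") "stratified_lp" else "stratified_chapman",
    n_hat, se)
  out$strata <- fits
  out
}

#' Write estimate results to JSON
#'
#' @param estimates an `estimate_result` or list of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  if (inherits(estimates, "estimate_result")) estimates <- list(estimates)
  out <- lapply(estimates, function(e) {
    list(method = e$method, n_hat = e$n_hat, se = e$se,
         half_width = e$half_width, ci_low = e$ci_low, ci_high = e$ci_high,
         inputs = e$inputs)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
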