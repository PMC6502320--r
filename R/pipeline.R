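#' Default analysis configuration
#'
#' Baked-in defaults for a full two-source run: the 3-age-class x gender
#' stratification, 2 MCMC chains with 5,000 burn-in and 25,000 retained
#' iterations, and the Alpes-Maritimes census denominators (1,078,729 total
#' population; 234,459 aged 65 and over, 2010).
#'
#' @param seed integer seed (mandatory: the Bayesian stage is stochastic).
#' @param ... named overrides of any default field.
#' @return configuration list for [run_pipeline()].
#' @export
default_config <- function(seed, ...) {
  cfg <- list(
    source_a = NULL, source_b = NULL,   # CSV paths; NULL = simulate
    scenario = "reference",             # scenario yaml path or "reference"
    age_breaks = c(84, 89),
    use_gender = TRUE,
    mcmc = list(n_chains = 2, n_burn = 5000, n_keep = 25000, thin = 1),
    population = 1078729,
    population_65plus = 234459,
    n_hat_65plus = NULL,  # optional externally supplied 65+ estimates
    strict = FALSE,
    out_dir = NULL,
    seed = seed)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full two-source capture-recapture pipeline
#'
#' Stages: ingest (or simulate) the two case lists, deduplicate, link,
#' stratify, estimate (Lincoln-Petersen, Chapman, stratified, Bayesian Mt),
#' and derive completeness and prevalence. Returns one consolidated report;
#' with `out_dir` set, writes `report.json` plus intermediate artifacts
#' (`tables.json`, `estimates.json`). Identical configurations and seeds
#' produce byte-identical reports.
#'
#' @param config list from [default_config()] (or compatible).
#' @return report list of class `cr_report`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is required")
  scheme <- stratum_scheme(config$age_breaks %||% c(84, 89),
                           config$use_gender %||% TRUE)
  strict <- isTRUE(config$strict)

  # stage: ingest ------------------------------------------------------
  if (!is.null(config$source_a) || !is.null(config$source_b)) {
    if (is.null(config$source_a) || is.null(config$source_b))
      stop("link stage: both source_a and source_b files are required")
    raw_a <- read_case_list(config$source_a)
    raw_b <- read_case_list(config$source_b)
    if (nrow(raw_b) == 0)
      stop("link stage: source B file has no records: ", config$source_b)
    if (nrow(raw_a) == 0)
      stop("link stage: source A file has no records: ", config$source_a)
  } else {
    scn <- if (identical(config$scenario, "reference")) reference_scenario()
           else read_scenario(config$scenario)
    sim <- generate_case_lists(scn, seed = config$seed)
    raw_a <- sim$A
    raw_b <- sim$B
  }
  message(sprintf("[ingest] source A: %d records, source B: %d records",
                  nrow(raw_a), nrow(raw_b)))

  # stage: dedupe ------------------------------------------------------
  a <- dedupe_cases(raw_a, strict = strict)
  b <- dedupe_cases(raw_b, strict = strict)
  message(sprintf("[dedupe] A: %d -> %d (-%d), B: %d -> %d (-%d)",
                  nrow(raw_a), nrow(a), attr(a, "n_removed"),
                  nrow(raw_b), nrow(b), attr(b, "n_removed")))

  # stage: link + stratify --------------------------------------------
  overall <- link_sources(a, b)
  tables <- stratify_sources(a, b, scheme, strict = strict)
  message(sprintf("[link] m=%d, A-only=%d, B-only=%d, union=%d",
                  as.integer(overall$m), as.integer(overall$a_only),
                  as.integer(overall$b_only), as.integer(overall$union)))

  # stage: closed-form estimators --------------------------------------
  lp <- lincoln_petersen(overall)
  ch <- chapman(overall)
  strat <- stratified_estimate(tables, "lincoln_petersen")
  message(sprintf("[estimate] LP=%d, Chapman=%d, stratified=%d",
                  as.integer(lp$n_hat), as.integer(ch$n_hat),
                  as.integer(strat$n_hat)))

  # stage: Bayesian Mt --------------------------------------------------
  mcfg <- config$mcmc %||% list()
  cfg <- mcmc_config(n_chains = mcfg$n_chains %||% 2,
                     n_burn = mcfg$n_burn %||% 5000,
                     n_keep = mcfg$n_keep %||% 25000,
                     thin = mcfg$thin %||% 1,
                     seed = config$seed)
  fit <- fit_mt(tables, cfg, strict = strict)
  post <- fit$summary["N_total", ]
  message(sprintf("[bayes] N mean=%d, median=%d, HPDI=[%d, %d], r-hat=%.3f",
                  as.integer(round_half_up(post$mean)),
                  as.integer(round_half_up(post$median)),
                  as.integer(round_half_up(post$hpdi_low)),
                  as.integer(round_half_up(post$hpdi_high)), post$r_hat))

  # stage: rates --------------------------------------------------------
  totals <- c(A = overall$n1, B = overall$n2)
  rates_for <- function(n_hat) list(
    prevalence_pct = prevalence(n_hat, config$population),
    completeness_A_pct = completeness(totals[["A"]], n_hat),
    completeness_B_pct = completeness(totals[["B"]], n_hat))
  bayes_mean <- round_half_up(post$mean)
  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("dualcapture")),
      seed = config$seed,
      config_hash = fnv1a32(jsonlite::toJSON(
        # hash the analytical inputs only, not where output lands
        config[setdiff(sort(names(config)), "out_dir")],
        auto_unbox = TRUE, digits = NA))),
    observed = list(
      n1 = overall$n1, n2 = overall$n2, m = overall$m,
      union = union_count(overall),
      overlap_pct = overlap_proportion(overall, as_percent = TRUE),
      n_excluded = attr(tables, "n_excluded")),
    estimates = list(
      lincoln_petersen = as.data.frame(lp),
      chapman = as.data.frame(ch),
      stratified_lp = as.data.frame(strat),
      bayes_mt = list(mean = round_half_up(post$mean),
                      median = round_half_up(post$median),
                      hpdi_low = round_half_up(post$hpdi_low),
                      hpdi_high = round_half_up(post$hpdi_high),
                      r_hat = post$r_hat, converged = fit$converged)),
    rates = list(
      lincoln_petersen = rates_for(lp$n_hat_exact),
      chapman = rates_for(ch$n_hat_exact),
      bayes_mt = rates_for(bayes_mean)))
  if (!is.null(config$n_hat_65plus)) {
    report$rates$age_65_plus <- lapply(
      config$n_hat_65plus,
      function(n) list(n_hat = n,
                       prevalence_pct = prevalence(
                         n, config$population_65plus %||% stop(
                           "population_65plus denominator required"))))
  }
  class(report) <- "cr_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tables(c(list(overall), unname(tables)),
                 file.path(config$out_dir, "tables.json"))
    write_estimates(list(lp, ch, strat),
                    file.path(config$out_dir, "estimates.json"))
    jsonlite::write_json(unclass(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.cr_report <- function(x, ...) {
  o <- x$observed
  cat(sprintf("Observed: union %s, overlap %.1f%% (m = %s)\n",
              format(o$union, big.mark = ","), o$overlap_pct,
              format(o$m, big.mark = ",")))
  e <- x$estimates
  cat(sprintf("  Lincoln-Petersen: %s [%s, %s]\n",
              format(e$lincoln_petersen$n_hat, big.mark = ","),
              format(e$lincoln_petersen$ci_low, big.mark = ","),
              format(e$lincoln_petersen$ci_high, big.mark = ",")))
  cat(sprintf("  Chapman:          %s [%s, %s]\n",
              format(e$chapman$n_hat, big.mark = ","),
              format(e$chapman$ci_low, big.mark = ","),
              format(e$chapman$ci_high, big.mark = ",")))
  cat(sprintf("  Stratified LP:    %s [%s, %s]\n",
              format(e$stratified_lp$n_hat, big.mark = ","),
              format(e$stratified_lp$ci_low, big.mark = ","),
              format(e$stratified_lp$ci_high, big.mark = ",")))
  cat(sprintf("  Bayesian Mt:      mean %s, median %s, HPDI [%s, %s]\n",
              format(e$bayes_mt$mean, big.mark = ","),
              format(e$bayes_mt$median, big.mark = ","),
              format(e$bayes_mt$hpdi_low, big.mark = ","),
              format(e$bayes_mt$hpdi_high, big.mark = ",")))
  invisible(x)
}

#' Render the two-by-two capture table with margins
#'
#' Lays out the capture-history counts as source B (rows) by source A
#' (columns) with margins, filling the never-observed cell with the
#' estimate's excess over the observed union (flagged with asterisks, as
#' an estimated rather than observed quantity).
#'
#' @param t a [contingency_table()].
#' @param estimate an `estimate_result` supplying the unobserved cell, or
#'   `NULL` to leave it blank.
#' @return a character matrix with margins; numeric cells as attribute
#'   `values`.
#' @export
render_table1 <- function(t, estimate = NULL) {
  stopifnot(inherits(t, "contingency_table"))
  unobs <- if (!is.null(estimate)) estimate$n_hat - union_count(t) else NA
  fmt <- function(x) format(x, big.mark = ",", trim = TRUE)
  out <- matrix("", 3, 3,
                dimnames = list(c("B yes", "B no", "total"),
                                c("A yes", "A no", "total")))
  out["B yes", ] <- c(fmt(t$m), fmt(t$b_only), fmt(t$n2))
  out["B no", "A yes"] <- fmt(t$a_only)
  out["B no", "A no"] <- if (is.na(unobs)) "(not estimable)"
                         else paste0("*", fmt(unobs), "*")
  out["total", "A yes"] <- fmt(t$n1)
  out["total", "A no"] <- if (is.na(unobs)) "" else fmt(t$b_only + unobs)
  out["total", "total"] <- if (is.na(unobs)) fmt(union_count(t))
                           else paste0("**", fmt(estimate$n_hat), "**")
  attr(out, "values") <- c(m = t$m, a_only = t$a_only, b_only = t$b_only,
                           n1 = t$n1, n2 = t$n2, union = t$union,
                           unobserved = unobs)
  out
}
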