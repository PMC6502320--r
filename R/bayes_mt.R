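#' @name bayes_mt
#' @title Bayesian closed-population Mt model by data augmentation
#'
#' @description
#' Per stratum \eqn{s}, the observed capture histories (both sources, A
#' only, B only) are modelled by augmenting the \eqn{u_s} observed persons
#' to a super-population of \eqn{M_s} potential persons with latent
#' inclusion indicators \eqn{z_i \sim \mathrm{Bernoulli}(\psi_s)} and
#' source-specific capture \eqn{y_{ij} \sim \mathrm{Bernoulli}(z_i
#' p_{s,j})}, \eqn{j \in \{A, B\}}, independent across sources (the Mt
#' assumption: capture probability varies by occasion/source, not by
#' individual within a stratum). Priors are flat: \eqn{p_{s,j} \sim
#' \mathrm{Beta}(1,1)}, \eqn{\psi_s \sim \mathrm{Uniform}(0,1)}. The
#' stratum size is \eqn{N_s = \sum_i z_i} and the total
#' \eqn{N = \sum_s N_s}.
#'
#' Because every complete conditional is conjugate, the sampler is a Gibbs
#' scheme: \eqn{p_{s,j} \mid z \sim \mathrm{Beta}(1 + n_j, 1 + D - n_j)}
#' with \eqn{D = \sum z_i}, \eqn{\psi_s \mid z \sim \mathrm{Beta}(1 + D, 1 +
#' M_s - D)}, and the number of included never-captured persons is a single
#' binomial draw with success probability
#' \eqn{\psi(1-p_A)(1-p_B) / (\psi(1-p_A)(1-p_B) + 1 - \psi)}
#' (never-captured persons are exchangeable). Observed persons have
#' \eqn{z_i = 1} deterministically.
NULL

#' MCMC configuration
#'
#' @param n_chains number of independent chains (at least 2, so convergence
#'   can be diagnosed).
#' @param n_burn iterations discarded per chain.
#' @param n_keep iterations retained per chain (at least 1,000).
#' @param thin keep every `thin`-th retained iteration.
#' @param seed integer seed; every chain and stratum draws from a
#'   deterministically derived substream so runs are jointly reproducible.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_burn = 5000, n_keep = 25000,
                        thin = 1, seed) {
  if (missing(seed) || is.null(seed))
    stop("an explicit seed is required for reproducibility")
  stopifnot(n_chains >= 2, n_keep >= 1000, n_burn >= 0, thin >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_burn = as.integer(n_burn),
                 n_keep = as.integer(n_keep),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# One chain for one stratum. Returns matrix with columns N, pA, pB, psi.
run_mt_chain <- function(m, a_only, b_only, M, cfg, chain, stratum_idx,
                         init_frac) {
  u <- m + a_only + b_only
  n1 <- m + a_only
  n2 <- m + b_only
  n_free <- M - u
  set.seed(derive_seed(cfg$seed, chain, stratum_idx))
  z0 <- round(init_frac * n_free)  # over-dispersed starting points
  n_iter <- cfg$n_burn + cfg$n_keep
  keep_idx <- seq.int(cfg$n_burn + 1L, n_iter, by = cfg$thin)
  out <- matrix(NA_real_, length(keep_idx), 4,
                dimnames = list(NULL, c("N", "pA", "pB", "psi")))
  k <- 0L
  for (it in seq_len(n_iter)) {
    D <- u + z0
    pA <- stats::rbeta(1, 1 + n1, 1 + D - n1)
    pB <- stats::rbeta(1, 1 + n2, 1 + D - n2)
    psi <- stats::rbeta(1, 1 + D, 1 + M - D)
    q <- psi * (1 - pA) * (1 - pB)
    z0 <- stats::rbinom(1, n_free, q / (q + 1 - psi))
    if (it > cfg$n_burn && (it - cfg$n_burn - 1L) %% cfg$thin == 0L) {
      k <- k + 1L
      out[k, ] <- c(u + z0, pA, pB, psi)
    }
  }
  out
}

#' Fit the Bayesian Mt model to capture-history tables
#'
#' @param tables a [contingency_table()] or list of per-stratum tables.
#' @param cfg an [mcmc_config()].
#' @param M_mult augmentation size per stratum as a multiple of the
#'   observed union (default 10); the super-population bound `M_s` must
#'   comfortably exceed the plausible stratum size.
#' @param M optional explicit per-stratum augmentation sizes (recycled).
#' @param strict if `TRUE`, non-convergence (any r-hat above 1.1) raises an
#'   error instead of a warning.
#' @return an object of class `mt_fit`: `$summary` is a data frame with one
#'   row per parameter (posterior mean, median, 95% HPDI bounds, r-hat,
#'   effective draws), `$draws` a named list of chains-by-iterations
#'   matrices, `$converged` a logical.
#' @examples
#' \donttest{
#' t1 <- contingency_table(856, 2968, 1738)
#' fit <- fit_mt(t1, mcmc_config(n_keep = 2000, n_burn = 500, seed = 1))
#' fit$summary
#' }
#' @export
fit_mt <- function(tables, cfg, M_mult = 10, M = NULL, strict = FALSE) {
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1,
            all(vapply(tables, inherits, TRUE, "contingency_table")),
            inherits(cfg, "mcmc_config"))
  nonempty <- vapply(tables, function(t) t$union > 0, TRUE)
  if (!any(nonempty)) stop("all stratum tables are empty")
  tables <- tables[nonempty]
  S <- length(tables)
  unions <- vapply(tables, `[[`, 0, "union")
  M_s <- if (is.null(M)) pmax(ceiling(M_mult * unions), unions + 10)
         else rep_len(M, S)
  if (any(M_s <= unions))
    stop("augmentation size M must exceed the observed union")

  init_frac <- if (cfg$n_chains == 1) 0.5 else
    seq(0.05, 0.95, length.out = cfg$n_chains)
  n_kept <- length(seq.int(cfg$n_burn + 1L, cfg$n_burn + cfg$n_keep,
                           by = cfg$thin))

  # draws[[param]]: n_chains x n_kept matrix
  draws <- list()
  labs <- vapply(tables, `[[`, "", "label")
  for (s in seq_len(S)) {
    t <- tables[[s]]
    per_chain <- lapply(seq_len(cfg$n_chains), function(ch)
      run_mt_chain(t$m, t$a_only, t$b_only, M_s[s], cfg, ch, s,
                   init_frac[ch]))
    for (p in c("N", "pA", "pB", "psi")) {
      key <- sprintf("%s[%s]", p, labs[s])
      draws[[key]] <- do.call(rbind, lapply(per_chain, function(x) x[, p]))
    }
  }
  # accounting identity: N_total draws are the iteration-wise sum of the
  # independent per-stratum chains
  N_keys <- sprintf("N[%s]", labs)
  draws[["N_total"]] <- Reduce(`+`, draws[N_keys])

  # posterior pile-up at the augmentation bound invalidates the fit
  for (s in seq_len(S)) {
    Ns <- draws[[N_keys[s]]]
    if (stats::quantile(Ns, 0.99) >= M_s[s])
      stop(sprintf(
        "posterior for stratum '%s' piles up at M = %d; increase M_mult",
        labs[s], M_s[s]))
  }

  summary_df <- do.call(rbind, lapply(names(draws), function(key) {
    x <- draws[[key]]
    pooled <- as.vector(t(x))
    hp <- hpdi(pooled, 0.95)
    data.frame(parameter = key,
               mean = mean(pooled),
               median = stats::median(pooled),
               hpdi_low = hp[1], hpdi_high = hp[2],
               r_hat = gelman_rubin(x),
               n_eff = effective_draws(x),
               stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- summary_df$parameter
  bad <- !is.na(summary_df$r_hat) & summary_df$r_hat > 1.1
  if (any(bad)) {
    msg <- sprintf("non-convergence: r_hat > 1.1 for %s",
                   paste(summary_df$parameter[bad], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  structure(list(summary = summary_df, draws = draws,
                 tables = tables, M = M_s, config = cfg,
                 converged = !any(bad)),
            class = "mt_fit")
}

#' @export
print.mt_fit <- function(x, ...) {
  s <- x$summary["N_total", ]
  cat(sprintf(
    "Bayesian Mt fit (%d strata, %d chains x %d kept draws)\n",
    length(x$tables), x$config$n_chains, ncol(x$draws$N_total)))
  cat(sprintf(
    "  N total: mean %s, median %s, 95%% HPDI [%s, %s], r-hat %.3f\n",
    format(round_half_up(s$mean), big.mark = ","),
    format(round_half_up(s$median), big.mark = ","),
    format(round_half_up(s$hpdi_low), big.mark = ","),
    format(round_half_up(s$hpdi_high), big.mark = ","), s$r_hat))
  if (!x$converged) cat("  WARNING: chains not converged\n")
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing at least `prob` of the draws:
#' the minimal-width window of `ceiling(prob * n)` consecutive sorted
#' draws; width ties are broken by the lowest lower bound.
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param prob interval mass, in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' hpdi(1:100, 0.95) # c(1, 95)
#' @export
hpdi <- function(draws, prob = 0.95) {
  stopifnot(is.numeric(draws), prob > 0, prob < 1)
  if (length(draws) < 100)
    stop("at least 100 draws are required for an HPDI")
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(prob * n)
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)  # which.min returns the first (lowest) minimizer
  c(x[i], x[i + k - 1])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Between/within-chain variance diagnostic: values near 1 indicate the
#' chains have mixed into the same distribution.
#'
#' @param chains matrix with one row per chain, or list of equal-length
#'   numeric vectors (at least 2 chains of length at least 100).
#' @return the potential scale reduction factor; `NA` (with a warning) when
#'   all chains are constant, which makes the factor undefined.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) {
    lens <- lengths(chains)
    if (length(unique(lens)) != 1) stop("chains must have equal length")
    chains <- do.call(rbind, chains)
  }
  m <- nrow(chains)
  n <- ncol(chains)
  if (is.null(m) || m < 2) stop("at least 2 chains are required")
  if (n < 100) stop("chains must have length >= 100")
  means <- rowMeans(chains)
  vars <- apply(chains, 1, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) {
    warning("all chains constant; r_hat undefined")
    return(NA_real_)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# Effective number of draws, pooled over chains, via AR-model spectral
# density at frequency zero (as in classical MCMC diagnostics).
effective_draws <- function(chains) {
  if (is.list(chains)) chains <- do.call(rbind, chains)
  total <- length(chains)
  ess_one <- function(x) {
    v <- stats::var(x)
    if (v == 0) return(length(x))
    fit <- try(stats::ar(x, aic = TRUE,
                         order.max = min(50, length(x) - 1)), silent = TRUE)
    if (inherits(fit, "try-error")) return(length(x))
    spec0 <- fit$var.pred / (1 - sum(fit$ar))^2
    min(length(x), length(x) * v / spec0)
  }
  e <- sum(apply(chains, 1, ess_one))
  min(total, e)
}
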