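# Shared fixtures and tiny independent oracles, built in code.

# The reference capture-history counts (overlap, A-only, B-only).
table1 <- function() contingency_table(856, 2968, 1738)

# Random case-record lists with distinct person keys drawn from a pool.
rand_records <- function(n, pool, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sample(pool, n)
  case_records(ids,
               age = sample(60:100, n, replace = TRUE),
               gender = sample(c("F", "M"), n, replace = TRUE))
}

# O(n^2) brute-force linkage oracle: pairwise key comparison.
brute_link <- function(a, b) {
  m <- sum(vapply(a$person_id,
                  function(id) any(b$person_id == id), TRUE))
  c(m = m, a_only = nrow(a) - m, b_only = nrow(b) - m)
}

# Independent re-computation of the Lincoln-Petersen point estimate.
lp_point <- function(m, a_only, b_only) {
  (m + a_only) * (m + b_only) / m
}

# A small homogeneous scenario for pipeline-level tests.
small_scenario <- function(N = 2000, pA = 0.4, pB = 0.3, delta = 0,
                           dup_rate = 0) {
  scenario(true_N = N, age_mean = 82, age_sd = 7, pA = pA, pB = pB,
           delta = delta, dup_rate = dup_rate)
}
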