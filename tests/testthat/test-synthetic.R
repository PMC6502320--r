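test_that("degenerate capture probabilities behave exactly", {
  empty <- generate_case_lists(scenario(true_N = 50, pA = 0, pB = 0),
                               seed = 1)
  expect_equal(nrow(empty$A), 0L)
  expect_equal(nrow(empty$B), 0L)
  expect_equal(nrow(empty$truth$person), 50L)

  full <- generate_case_lists(scenario(true_N = 80, pA = 1, pB = 1),
                              seed = 1)
  expect_equal(nrow(full$A), 80L)
  expect_equal(nrow(full$B), 80L)
  t <- link_sources(full$A, full$B)
  expect_equal(t$m, 80)
})

test_that("pattern counts match the independence moments within 3 SD", {
  N <- 10000; pA <- 0.33; pB <- 0.22
  sim <- generate_case_lists(scenario(true_N = N, pA = pA, pB = pB,
                                      delta = 0), seed = 2)
  t <- link_sources(sim$A, sim$B)
  check <- function(obs, p) {
    expect_lt(abs(obs - N * p), 3 * sqrt(N * p * (1 - p)))
  }
  check(t$m, pA * pB)
  check(t$a_only, pA * (1 - pB))
  check(t$b_only, pB * (1 - pA))
})

test_that("delta = 0 recovers independence and delta > 0 inflates overlap
           at preserved marginals", {
  N <- 50000; pA <- 0.4; pB <- 0.3
  s0 <- generate_case_lists(scenario(true_N = N, pA = pA, pB = pB,
                                     delta = 0), seed = 3)
  t0 <- link_sources(s0$A, s0$B)
  expect_lt(abs(t0$m / N - pA * pB), 3 * sqrt(pA * pB / N))

  s2 <- generate_case_lists(scenario(true_N = N, pA = pA, pB = pB,
                                     delta = 3), seed = 3)
  t2 <- link_sources(s2$A, s2$B)
  expect_gt(t2$m, t0$m)
  # marginal list sizes unchanged beyond noise
  expect_lt(abs(t2$n1 - N * pA), 3 * sqrt(N * pA * (1 - pA)))
  expect_lt(abs(t2$n2 - N * pB), 3 * sqrt(N * pB * (1 - pB)))
})

test_that("ground truth accounts for every person and every emitted record", {
  sim <- generate_case_lists(small_scenario(), seed = 4)
  tr <- sim$truth
  expect_equal(sum(table(tr$person$pattern)), tr$scenario$true_N)
  expect_equal(sum(tr$stratum_n), tr$scenario$true_N)
  expect_true(all(sim$A$person_id %in% tr$person$person_id))
  expect_true(all(sim$B$person_id %in% tr$person$person_id))
  # emitted lists tally with per-person patterns
  expect_equal(nrow(sim$A),
               sum(tr$person$pattern %in% c("both", "a_only")))
  expect_equal(nrow(sim$B),
               sum(tr$person$pattern %in% c("both", "b_only")))
})

test_that("same seed writes byte-identical files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_case_lists(generate_case_lists(small_scenario(), seed = 5), d1)
  write_case_lists(generate_case_lists(small_scenario(), seed = 5), d2)
  for (f in c("source_A.csv", "source_B.csv", "truth.json",
              "scenario.yaml")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  write_case_lists(generate_case_lists(small_scenario(), seed = 6), d3)
  expect_false(identical(
    readBin(file.path(d1, "source_A.csv"), "raw", 1e6),
    readBin(file.path(d3, "source_A.csv"), "raw", 1e6)))
})

test_that("scenario round-trips through YAML", {
  scn <- reference_scenario()
  d <- withr::local_tempdir()
  write_case_lists(generate_case_lists(scn, seed = 7), d)
  back <- read_scenario(file.path(d, "scenario.yaml"))
  expect_equal(back$true_N, scn$true_N)
  expect_equal(back$pA, scn$pA, ignore_attr = TRUE)
  expect_equal(back$female_fraction, scn$female_fraction)
})

test_that("duplicate injection is removed by dedupe without changing linkage", {
  scn <- small_scenario(dup_rate = 0.1)
  sim <- generate_case_lists(scn, seed = 8)
  expect_gt(nrow(sim$A), length(unique(sim$A$person_id)))
  a <- dedupe_cases(sim$A)
  b <- dedupe_cases(sim$B)
  t <- link_sources(a, b)
  # linkage identical to the duplicate-free run of the same seed
  scn0 <- small_scenario(dup_rate = 0)
  sim0 <- generate_case_lists(scn0, seed = 8)
  t0 <- link_sources(sim0$A, sim0$B)
  expect_equal(as.data.frame(t), as.data.frame(t0))
})

test_that("reference scenario matches the surveillance marginals it emulates", {
  scn <- reference_scenario()
  stats <- t(vapply(1:60, function(i) {
    sim <- generate_case_lists(scn, seed = 3000 + i)
    c(nA = nrow(sim$A), nB = nrow(sim$B),
      m = link_sources(sim$A, sim$B)$m,
      A_age = mean(sim$A$age), B_age = mean(sim$B$age),
      A_fm = sum(sim$A$gender == "F") / sum(sim$A$gender == "M"),
      B_f = mean(sim$B$gender == "F"))
  }, numeric(7)))
  mu <- colMeans(stats)
  expect_lt(abs(mu["nA"] - 3824) / 3824, 0.03)
  expect_lt(abs(mu["nB"] - 2594) / 2594, 0.03)
  expect_lt(abs(mu["m"] - 856) / 856, 0.05)
  expect_lt(abs(mu["A_age"] - 86.1), 1)      # A-list mean age
  expect_lt(abs(mu["B_age"] - 82.2), 1)      # B-list mean age
  expect_lt(abs(mu["A_fm"] - 3.2) / 3.2, 0.10)  # A-list F/M ratio
  expect_lt(abs(mu["B_f"] - 0.71), 0.03)     # B-list female share
})

test_that("full pipeline on homogeneous data recovers the truth", {
  scn <- scenario(true_N = 5000, pA = 0.4, pB = 0.35, delta = 0)
  lp_ok <- 0L; bayes_ok <- 0L
  for (i in 1:10) {
    sim <- generate_case_lists(scn, seed = 5000 + i)
    t <- link_sources(dedupe_cases(sim$A), dedupe_cases(sim$B))
    lp <- lincoln_petersen(t)
    lp_ok <- lp_ok + (abs(lp$n_hat_exact - 5000) <= 3 * lp$se)
    fit <- fit_mt(t, mcmc_config(n_burn = 500, n_keep = 2000,
                                 seed = 5000 + i))
    s <- fit$summary["N_total", ]
    bayes_ok <- bayes_ok + (s$hpdi_low <= 5000 && 5000 <= s$hpdi_high)
  }
  expect_gte(lp_ok, 9L)
  expect_gte(bayes_ok, 9L)
})
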