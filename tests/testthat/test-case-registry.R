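test_that("dedupe collapses repeat reports and is idempotent", {
  r <- case_records(c("p1", "p1", "p2"), c(80, 80, 85), c("F", "F", "M"))
  d <- dedupe_cases(r)
  expect_equal(d$person_id, c("p1", "p2"))
  expect_equal(attr(d, "n_removed"), 1L)

  empty <- case_records(character(), integer(), character())
  expect_equal(nrow(dedupe_cases(empty)), 0L)

  # 100 records with 17 injected duplicates -> unique-key count (oracle)
  set.seed(41)
  base <- rand_records(83, sprintf("id%04d", 1:500))
  dup_rows <- base[sample(83, 17, replace = TRUE), , drop = FALSE]
  mixed <- rbind(base, dup_rows)[sample(100), ]
  d2 <- dedupe_cases(mixed)
  expect_equal(nrow(d2), length(unique(mixed$person_id)))
  expect_equal(nrow(d2), 83L)
  expect_equal(attr(d2, "n_removed"), 17L)

  # idempotence
  expect_identical(dedupe_cases(d2)$person_id, d2$person_id)
})

test_that("conflicting duplicate demographics warn, and raise in strict mode", {
  r <- case_records(c("p1", "p1"), c(80, 85), c("F", "F"))
  expect_warning(dedupe_cases(r), "conflict")
  expect_error(dedupe_cases(r, strict = TRUE), "conflict")
  # demographics come from the first occurrence
  d <- suppressWarnings(dedupe_cases(r))
  expect_equal(d$age, 80L)
  # a 1-year discrepancy is tolerated silently
  ok <- case_records(c("p2", "p2"), c(80, 81), c("M", "M"))
  expect_silent(dedupe_cases(ok))
})

test_that("linkage counts shared keys exactly", {
  a <- case_records(paste0("p", 1:5), rep(80, 5), rep("F", 5))
  b <- case_records(paste0("p", 4:7), rep(80, 4), rep("F", 4))
  t <- link_sources(a, b)
  expect_equal(c(t$m, t$a_only, t$b_only), c(2, 3, 2))

  fx <- reference_fixture()
  t1 <- link_sources(fx$A, fx$B)
  expect_equal(t1$m, 856)
  expect_equal(t1$a_only, 2968)
  expect_equal(t1$b_only, 1738)
  expect_equal(t1$n1, 3824)
  expect_equal(t1$n2, 2594)
})

test_that("linkage agrees with the brute-force pairwise oracle and is symmetric", {
  pool <- sprintf("q%05d", 1:1200)
  for (seed in 1:4) {
    set.seed(seed)
    a <- rand_records(sample(50:500, 1), pool)
    b <- rand_records(sample(50:500, 1), pool)
    t <- link_sources(a, b)
    expect_equal(c(t$m, t$a_only, t$b_only), unname(brute_link(a, b)),
                 ignore_attr = TRUE)
    # symmetry: swapping sources swaps the "only" cells, preserves m/union
    ts <- link_sources(b, a)
    expect_equal(ts$m, t$m)
    expect_equal(ts$a_only, t$b_only)
    expect_equal(ts$b_only, t$a_only)
    expect_equal(union_count(ts), union_count(t))
  }
})

test_that("age classes use the <=84 / 85-89 / >=90 partition", {
  sch <- stratum_scheme()
  expect_equal(age_class(c(80, 84, 85, 89, 90, 95), sch),
               c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(length(stratum_scheme(c(84, 89), TRUE)$age_labels), 3L)
})

test_that("stratified tables conserve the overall table", {
  sch <- stratum_scheme()
  # single-gender input: 3 of the 6 strata populated
  a <- case_records(paste0("a", 1:30), rep(c(70, 86, 95), 10), "F")
  b <- case_records(paste0("a", 16:40), rep(c(70, 86, 95), c(9, 8, 8)), "F")
  tabs <- stratify_sources(a, b, sch)
  expect_length(tabs, 6L)
  nonempty <- vapply(tabs, function(t) t$union > 0, TRUE)
  expect_equal(sum(nonempty), 3L)
  expect_true(all(grepl("\\.F$", names(tabs)[nonempty])))
  pooled <- pool_tables(tabs)
  overall <- link_sources(a, b)
  expect_equal(c(pooled$m, pooled$a_only, pooled$b_only),
               c(overall$m, overall$a_only, overall$b_only))
})

test_that("stratification matches generator bookkeeping", {
  scn <- reference_scenario()
  sim <- generate_case_lists(scn, seed = 3)
  tabs <- stratify_sources(sim$A, sim$B, scn$scheme)
  for (s in names(tabs)) {
    truth <- sim$truth$stratum_patterns[[s]]
    expect_equal(tabs[[s]]$m, unname(truth["both"]))
    expect_equal(tabs[[s]]$a_only, unname(truth["a_only"]))
    expect_equal(tabs[[s]]$b_only, unname(truth["b_only"]))
  }
  # cell-wise conservation against the overall linkage
  pooled <- pool_tables(tabs)
  overall <- link_sources(sim$A, sim$B)
  expect_equal(as.data.frame(pooled)[, -1], as.data.frame(overall)[, -1])
})

test_that("missing demographics are excluded with a warning, strict raises", {
  a <- data.frame(person_id = c("p1", "p2", "p3"),
                  age = c(80L, NA, 85L), gender = c("F", "M", NA))
  b <- data.frame(person_id = "p9", age = 90L, gender = "M")
  expect_warning(tabs <- stratify_sources(a, b), "2 record\\(s\\) excluded")
  expect_equal(attr(tabs, "n_excluded"), 2L)
  expect_equal(union_count(pool_tables(tabs)), 2)
  expect_error(stratify_sources(a, b, strict = TRUE), "excluded")
})

test_that("union and overlap summaries follow the table arithmetic", {
  expect_equal(union_count(table1()), 5562)
  expect_equal(overlap_proportion(table1(), as_percent = TRUE), 15.4)
  expect_equal(union_count(contingency_table(0, 3, 4)), 7)
  expect_equal(union_count(contingency_table(5, 0, 0)), 5)
  expect_equal(overlap_proportion(contingency_table(5, 0, 0), TRUE), 100.0)
  expect_equal(overlap_proportion(contingency_table(0, 3, 4), TRUE), 0.0)
  expect_error(overlap_proportion(contingency_table(0, 0, 0)), "empty")
})

test_that("case lists round-trip through CSV", {
  fx <- reference_fixture()
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(fx$A, tmp, row.names = FALSE)
  back <- read_case_list(tmp)
  expect_equal(back, fx$A, ignore_attr = TRUE)
  expect_error(read_case_list("no/such/file.csv"), "not found")
})
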