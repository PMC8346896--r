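test_that("rate_table averages per-person window totals by cell", {
  p <- as_panel(rbind(
    data.frame(person_id = "A", cohort = "y", age = 17:24,
               count = c(1L, 1L, 1L, 1L, 1L, 1L, 0L, 0L)),   # 6 arrests
    data.frame(person_id = "B", cohort = "y", age = 17:24,
               count = c(2L, 2L, 2L, 2L, 1L, 1L, 0L, 0L)),   # 10 arrests
    data.frame(person_id = "C", cohort = "o", age = 20:22, count = 1L)))
  asn <- c(A = 1L, B = 1L, C = 1L)
  expect_message(rt <- rate_table(p, asn, c(17, 24)), "excluded 1")
  expect_equal(nrow(rt), 1L)  # C lacks coverage; empty cells are absent
  expect_equal(rt$rate, 8)
  expect_equal(rt$n_persons, 2L)
  expect_error(rate_table(p, asn, c(17, 24), incomplete = "error"),
               "lack full coverage")
})

test_that("offense-specific cells reproduce the generative drug gap", {
  gs <- default_cohort_spec()
  sim <- simulate_panel(gs, 3000, seed = 90)
  panel <- map_cohorts(sim$panel, c("0" = "younger", "9" = "older",
                                    "12" = "older", "15" = "older"))
  rt <- suppressMessages(
    rate_table(panel, sim$groups, c(17, 24), by_offense = TRUE))
  hi <- rt[rt$group == 3L, ]
  expect_equal(nrow(hi), 2L)
  drug_y <- hi$rate_drugs[hi$cohort == "younger"]
  drug_o <- hi$rate_drugs[hi$cohort == "older"]
  expect_gt(drug_o, drug_y)  # older high group carries the drug excess
  expect_gt(hi$rate[hi$cohort == "older"], hi$rate[hi$cohort == "younger"])
})

test_that("percent_excess and cohort_gap do their arithmetic", {
  expect_equal(percent_excess(10.88, 8.07), 34.8, tolerance = 1e-3)
  expect_equal(percent_excess(2, 2), 0)
  expect_equal(percent_excess(3, 2), 50)
  expect_error(percent_excess(1, 0), "positive")
  expect_equal(cohort_gap(0.614, 1.156), 0.542)
  expect_equal(cohort_gap(1, 1), 0)
  expect_equal(cohort_gap(2, 5), -cohort_gap(5, 2))
})

test_that("decompose reproduces hand-computed counterfactuals", {
  d <- decompose(shares_young = c(0.5, 0.5), rates_young = c(0, 2),
                 shares_old = c(0.8, 0.2), rates_old = c(0, 4),
                 target_group = 2L)
  expect_equal(d$actual_young, 1.0)
  expect_equal(d$actual_old, 0.8)
  expect_equal(unname(d$counterfactuals["composition_swap"]), 0.4)
  expect_equal(unname(d$counterfactuals["rate_swap"]), 2.0)
  expect_equal(unname(d$counterfactuals["targeted"]), 2.0)
  expect_equal(unname(d$pct_vs_actual["rate_swap"]), 100)
  same <- decompose(c(0.6, 0.4), c(1, 3), c(0.6, 0.4), c(1, 3))
  expect_equal(same$gap, 0)
  expect_true(all(abs(same$counterfactuals - same$actual_young) < 1e-12))
  expect_error(decompose(c(0.7, 0.7), c(1, 1), c(0.5, 0.5), c(1, 1)),
               "sum to 1")
})

test_that("decompose is invariant to permuting the group axis", {
  sy <- c(0.7, 0.25, 0.05); ry <- c(0.1, 2.5, 8)
  so <- c(0.6, 0.3, 0.1); ro <- c(0.2, 2.4, 11)
  d1 <- decompose(sy, ry, so, ro, target_group = 3L)
  perm <- c(3L, 1L, 2L)
  d2 <- decompose(sy[perm], ry[perm], so[perm], ro[perm],
                  target_group = which(perm == 3L))
  expect_equal(d1$actual_young, d2$actual_young)
  expect_equal(d1$counterfactuals, d2$counterfactuals)
})

test_that("share-weighted rates add up to the pooled cohort mean exactly", {
  for (seed in 1:5) {
    set.seed(seed + 200)
    n <- 30L
    ids <- sprintf("p%02d", seq_len(n))
    p <- as_panel(data.frame(
      person_id = rep(ids, each = 6L), cohort = "c",
      age = rep(15:20, n),
      count = rpois(6L * n, runif(n)[rep(seq_len(n), each = 6L)] * 3)))
    asn <- setNames(sample(1:3, n, replace = TRUE), ids)
    rt <- rate_table(p, asn, c(15, 20))
    shares <- rt$n_persons / sum(rt$n_persons)
    pooled <- sum(p$count) / n
    expect_equal(sum(shares * rt$rate), pooled, tolerance = 1e-12)
  }
})

test_that("permutation test separates, nulls out, and stays seed-stable", {
  # disjoint well-separated cohorts: smallest attainable p
  p_sep <- as_panel(data.frame(
    person_id = sprintf("p%02d", 1:40),
    cohort = rep(c("y", "o"), each = 20L),
    age = 18L, count = rep(c(0L, 5L), each = 20L)))
  asn <- setNames(rep(1L, 40L), sprintf("p%02d", 1:40))
  res <- permutation_test(p_sep, asn, 1L, c(18, 18), n_perm = 999L, seed = 1)
  expect_lte(res$p_value, 0.01)
  expect_equal(abs(res$observed), 5)  # direction: second sorted label minus first

  # identical count multisets across cohorts: p near 1
  p_null <- as_panel(data.frame(
    person_id = sprintf("q%02d", 1:20),
    cohort = rep(c("y", "o"), each = 10L),
    age = 18L, count = rep(c(0L, 0L, 1L, 1L, 2L), 4L)))
  asn0 <- setNames(rep(1L, 20L), sprintf("q%02d", 1:20))
  res0 <- permutation_test(p_null, asn0, 1L, c(18, 18), n_perm = 499L,
                           seed = 2)
  expect_gt(res0$p_value, 0.5)

  # p is seed-invariant in distribution at large n_perm
  set.seed(33)
  p_mid <- as_panel(data.frame(
    person_id = sprintf("r%02d", 1:30),
    cohort = rep(c("y", "o"), each = 15L),
    age = 18L, count = rpois(30L, c(rep(1, 15), rep(1.8, 15)))))
  asn1 <- setNames(rep(1L, 30L), sprintf("r%02d", 1:30))
  pa <- permutation_test(p_mid, asn1, 1L, c(18, 18), n_perm = 10000L,
                         seed = 10)$p_value
  pb <- permutation_test(p_mid, asn1, 1L, c(18, 18), n_perm = 10000L,
                         seed = 11)$p_value
  mc_se <- sqrt(pa * (1 - pa) / 10000)
  expect_lt(abs(pa - pb), 4 * mc_se + 1e-4)

  expect_error(permutation_test(p_sep, asn, 2L, c(18, 18)), "two cohorts")
})
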