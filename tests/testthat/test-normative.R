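test_that("range summaries use the documented interpolation rule", {
  s <- summarize_range(c(0, 0, 0, 4, 8))
  expect_equal(c(s$median, s$q25), c(0, 0))  # zero-inflated sample
  s99 <- summarize_range(1:99)
  expect_equal(unlist(s99[c("median", "q25", "q75", "p5")]),
               c(median = 50, q25 = 25.5, q75 = 74.5, p5 = 5.9))
  one <- summarize_range(7.4)
  expect_equal(unlist(one[-1]), c(median = 7.4, q25 = 7.4, q75 = 7.4, p5 = 7.4))
  expect_error(summarize_range(NA_real_), "non-missing")
})

test_that("range summaries are permutation-invariant and scale-equivariant", {
  set.seed(41)
  for (i in 1:10) {
    x <- rlnorm(sample(3:40, 1), 2, 0.5)
    a <- summarize_range(x)
    expect_equal(summarize_range(sample(x)), a)
    c_ <- runif(1, 0.1, 10)
    scaled <- summarize_range(c_ * x)
    expect_equal(unlist(scaled[-1]), c_ * unlist(a[-1]))
  }
})

test_that("two-group comparisons delegate to exact standard tests", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)
  # exact two-sided rank-sum, n = 3 per arm: 2/20
  shift <- compare_groups(c(1, 2, 3), c(101, 102, 103))
  expect_equal(shift$p_value, 0.1)
  # hypergeometric enumeration oracle for Fisher on (10,0; 0,10)
  m <- matrix(c(10, 0, 0, 10), 2)
  p_oracle <- sum(dhyper(0:10, 10, 10, 10)[dhyper(0:10, 10, 10, 10) <=
                                             dhyper(10, 10, 10, 10) + 1e-12])
  fish <- compare_groups(m, kind = "fisher_exact")
  expect_lt(fish$p_value, 0.001)
  expect_equal(fish$p_value, p_oracle, tolerance = 1e-9)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
  expect_error(compare_groups(matrix(1:6, 2), kind = "fisher_exact"), "2x2")
})

test_that("rank-sum matches a permutation enumeration oracle at small n", {
  x <- c(1.2, 3.4, 5.1)
  y <- c(2.2, 8.9, 9.7)
  obs <- sum(rank(c(x, y))[1:3])
  combos <- combn(6, 3)
  ranks <- rank(c(x, y))
  null_sums <- apply(combos, 2, function(idx) sum(ranks[idx]))
  # two-sided: as or more extreme deviation of the rank sum from its mean
  p_perm <- mean(abs(null_sums - mean(null_sums)) >= abs(obs - mean(null_sums)) - 1e-12)
  expect_equal(compare_groups(x, y)$p_value, p_perm, tolerance = 1e-9)
})

test_that("Kruskal-Wallis delegates with tie correction", {
  ident <- compare_many(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(ident$statistic, 0)
  shifted <- compare_many(list(1:5, 11:15, 21:25))
  expect_lt(shifted$p_value, 0.01)
  expect_error(compare_many(list(1:3, 4:6)), ">= 3")
  withties <- compare_many(list(c(1, 1, 2), c(2, 2, 3), c(3, 3, 4)))
  expect_equal(withties$statistic,
               unname(kruskal.test(list(c(1, 1, 2), c(2, 2, 3), c(3, 3, 4)))$statistic))
})

test_that("range_table stratifies, omits empty strata, and orders groups", {
  co <- generate_cohort(default_spec(), seed = 19)
  msgs <- capture_messages(rt <- range_table(co))
  expect_true(all(rt$q25 <= rt$median & rt$median <= rt$q75))
  expect_true(all(rt$p5 <= rt$q25 + 1e-12))
  # the control group has no under-40 stratum in the study design
  expect_false(any(rt$group == "G1" & rt$age_group == "<40"))
  expect_true(any(grepl("omitting empty stratum", msgs)))
  # neuropathy medians sit below both reference groups for every nerve
  whole <- rt[rt$age_group == "whole" & rt$measure != "srar", ]
  for (m in unique(whole$measure)) {
    g <- setNames(whole$median[whole$measure == m], whole$group[whole$measure == m])
    expect_lte(g[["G3"]], g[["G1"]])
    expect_lte(g[["G3"]], g[["G2"]])
  }
  # single-group cohort yields only that group's rows
  one <- suppressMessages(range_table(dplyr::filter(classify_cohort(co), group == "G3")))
  expect_equal(unique(one$group), "G3")
})
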