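test_that("proportion metrics match hand-checked tables", {
  pm <- proportion_metrics(twobytwo(39, 18, 6, 72))
  expect_equal(round(pm$estimate, 3), c(0.684, 0.923, 0.867, 0.800))
  pm4 <- proportion_metrics(twobytwo(31, 26, 1, 71))
  expect_equal(round(pm4$estimate[3:4], 3), c(0.969, 0.732))
  expect_equal(proportion_metrics(twobytwo(1, 0, 0, 1))$estimate, rep(1, 4))
})

test_that("Clopper-Pearson intervals reproduce frozen values and boundaries", {
  ci <- clopper_pearson_ci(39, 57)
  expect_equal(round(unlist(ci), 3), c(lo = 0.548, hi = 0.801))
  expect_equal(clopper_pearson_ci(0, 10)$lo, 0)
  expect_equal(clopper_pearson_ci(10, 10)$hi, 1)
  expect_equal(round(clopper_pearson_ci(71, 72)$lo, 3), 0.925)
  expect_error(clopper_pearson_ci(5, 4), "successes")
})

test_that("Clopper-Pearson agrees with binom.test and the bisection oracle", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(1:100, 1)
    x <- sample(0:n, 1)
    ci <- unlist(clopper_pearson_ci(x, n))
    expect_equal(unname(ci), unname(binom.test(x, n)$conf.int[1:2]), tolerance = 1e-12)
    expect_equal(unname(ci), unname(cp_oracle(x, n)), tolerance = 1e-9)
  }
})

test_that("dichotomous ROC area and DeLong-variance interval", {
  a <- binary_auc(twobytwo(39, 18, 6, 72))
  expect_equal(round(c(a$estimate, a$lo, a$hi), 3), c(0.804, 0.736, 0.871))
  a3 <- binary_auc(twobytwo(38, 19, 4, 68))
  expect_equal(round(c(a3$estimate, a3$lo, a3$hi), 3), c(0.806, 0.738, 0.873))
  expect_equal(binary_auc(twobytwo(5, 0, 0, 7))$estimate, 1)
  tiny <- binary_auc(twobytwo(1, 0, 3, 4))
  expect_true(is.na(tiny$lo) && is.na(tiny$hi))  # CI undefined, estimate kept
  expect_equal(tiny$estimate, (1 + 4 / 7) / 2)
})

test_that("PPV/NPV are Bayes-consistent and AUC is the two-point trapezoid", {
  set.seed(17)
  for (i in 1:30) {
    counts <- rmultinom(1, size = sample(20:200, 1), prob = runif(4, 0.05, 1))[, 1]
    tb <- twobytwo(counts[1] + 1, counts[2] + 1, counts[3] + 1, counts[4] + 1)
    pm <- proportion_metrics(tb)
    est <- setNames(pm$estimate, pm$metric)
    prev <- (tb$tp + tb$fn) / sum(unlist(tb[c("tp", "fn", "fp", "tn")]))
    expect_equal(est[["ppv"]],
                 est[["sensitivity"]] * prev /
                   (est[["sensitivity"]] * prev + (1 - est[["specificity"]]) * (1 - prev)))
    expect_equal(est[["npv"]],
                 est[["specificity"]] * (1 - prev) /
                   (est[["specificity"]] * (1 - prev) + (1 - est[["sensitivity"]]) * prev))
    # trapezoid area of {(0,0), (1-spec, sens), (1,1)}
    x <- c(0, 1 - est[["specificity"]], 1)
    y <- c(0, est[["sensitivity"]], 1)
    trap <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
    expect_equal(binary_auc(tb)$estimate, trap)
  }
})

test_that("2x2 building respects variant, stratum, and evaluability", {
  co <- generate_cohort(default_spec(), seed = 5)
  tb <- build_2x2(co, index_test("sural"))
  expect_equal(tb$tp + tb$fn, 57L)
  expect_equal(tb$fp + tb$tn, 78L)  # G1 + G2, discordant excluded
  tb_cases <- build_2x2(co, index_test("sural"), variant = "cases_only")
  expect_equal(tb_cases$fp + tb_cases$tn, 37L)  # controls excluded
  # age stratification partitions the whole-cohort counts
  parts <- lapply(age_group_levels(), function(s)
    tryCatch(build_2x2(co, index_test("sural"), stratum = s),
             snapdx_degenerate = function(e) e$counts))
  totals <- Reduce(`+`, lapply(parts, function(p) unlist(p)[c("tp", "fn", "fp", "tn")]))
  expect_equal(unname(totals), unname(unlist(tb)[c("tp", "fn", "fp", "tn")]))
  # all-missing test -> degenerate error carrying counts
  co_na <- dplyr::mutate(co, sural_r = NA_real_, sural_l = NA_real_)
  expect_error(build_2x2(co_na, index_test("sural")), class = "snapdx_degenerate")
})

test_that("accuracy_table assembles rows and skips degenerate strata", {
  co <- generate_cohort(default_spec(), seed = 5)
  msgs <- capture_messages(acc <- accuracy_table(co))
  expect_s3_class(acc, "snap_accuracy")
  expect_true(all(c("sens", "sens_lo", "auc_hi") %in% names(acc)))
  whole <- acc[acc$stratum == "whole", ]
  expect_equal(nrow(whole), 7L)
  expect_true(all(whole$sens >= whole$sens_lo & whole$sens <= whole$sens_hi))
  # CPNSI threshold sweep: sens non-increasing, spec non-decreasing in k
  sweep <- whole[grepl("cpnsi", whole$test), ]
  expect_true(all(diff(sweep$sens) <= 0))
  expect_true(all(diff(sweep$spec) >= 0))
})

test_that("reconstruct_counts inverts printed percentages uniquely", {
  expect_equal(unlist(reconstruct_counts(57, 78, 68.4, 92.3)),
               c(tp = 39L, fn = 18L, fp = 6L, tn = 72L))
  expect_equal(unlist(reconstruct_counts(57, 72, 66.7, 94.4)),
               c(tp = 38L, fn = 19L, fp = 4L, tn = 68L))
  expect_equal(unlist(reconstruct_counts(10, 10, 100, 100)),
               c(tp = 10L, fn = 0L, fp = 0L, tn = 10L))
  expect_error(reconstruct_counts(3, 10, 40.0, 50.0), "no integer")
  expect_error(reconstruct_counts(5000, 10, 50.0, 50.0), "ambiguous")
})

test_that("reconstruct_counts matches the interval-membership oracle", {
  set.seed(23)
  for (i in 1:30) {
    n1 <- sample(5:120, 1); n0 <- sample(5:120, 1)
    tp <- sample(0:n1, 1); tn <- sample(0:n0, 1)
    sens_pct <- floor(1000 * tp / n1 + 0.5) / 10  # a printable value
    spec_pct <- floor(1000 * tn / n0 + 0.5) / 10
    cand_tp <- which(rounds_to(100 * (0:n1) / n1, sens_pct)) - 1L
    cand_tn <- which(rounds_to(100 * (0:n0) / n0, spec_pct)) - 1L
    if (length(cand_tp) == 1L && length(cand_tn) == 1L) {
      tb <- reconstruct_counts(n1, n0, sens_pct, spec_pct)
      expect_equal(c(tb$tp, tb$tn), c(cand_tp, cand_tn))
    } else {
      expect_error(reconstruct_counts(n1, n0, sens_pct, spec_pct), "ambiguous")
    }
  }
})
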