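test_that("zero-inflated log-normal fits match the stated closed forms", {
  m <- fit_zero_inflated_lognormal(11.9, 9.15, 15.25)
  expect_equal(m$zero_mass, 0)
  expect_equal(m$log_mu, log(11.9))
  expect_equal(m$log_sigma_low, log(11.9 / 9.15) / qnorm(0.75))
  expect_equal(m$log_sigma_high, log(15.25 / 11.9) / qnorm(0.75))
  # overall log-spread is the printed-IQR form
  expect_equal(m$log_sigma, log(15.25 / 9.15) / (2 * qnorm(0.75)))
  expect_equal(round(m$log_sigma, 3), 0.379)
  # all three quantiles are matched exactly, symmetric or not
  skewed <- fit_zero_inflated_lognormal(16.35, 6.5, 26.2)
  expect_equal(zil_quantile(skewed, c(0.25, 0.5, 0.75)), c(6.5, 16.35, 26.2))

  # zero lower quartile: zero mass in (0.25, 0.5), printed quantiles matched
  z <- fit_zero_inflated_lognormal(4.05, 0, 8.95)
  expect_gt(z$zero_mass, 0.25)
  expect_lt(z$zero_mass, 0.5)
  expect_equal(zil_quantile(z, 0.25), 0)
  expect_equal(zil_quantile(z, 0.5), 4.05)
  expect_equal(zil_quantile(z, 0.75), 8.95)

  # zero median: zero mass in (0.5, 0.75), q75 matched
  z0 <- fit_zero_inflated_lognormal(0, 0, 5.3)
  expect_gt(z0$zero_mass, 0.5)
  expect_lt(z0$zero_mass, 0.75)
  expect_equal(zil_quantile(z0, 0.5), 0)
  expect_equal(zil_quantile(z0, 0.75), 5.3)

  # degenerate triplet hits the sigma floor rather than zero spread
  d <- fit_zero_inflated_lognormal(6.65, 6.65, 6.65)
  expect_equal(d$log_sigma, 0.05)
  expect_error(fit_zero_inflated_lognormal(5, 6, 7), "q25 <= median")
  expect_error(fit_zero_inflated_lognormal(0, 0, 0), "q75 > 0")
})

test_that("fitted models reproduce their triplet in Monte-Carlo draws", {
  set.seed(77)
  triplets <- list(c(11.9, 9.15, 15.25), c(4.05, 0, 8.95), c(0, 0, 5.3))
  for (tr in triplets) {
    m <- fit_zero_inflated_lognormal(tr[1], tr[2], tr[3])
    draws <- snapdx:::zil_draw(m, 2e5)
    q <- quantile(draws, c(0.5, 0.25, 0.75), names = FALSE)
    for (j in 1:3) {
      if (tr[j] == 0) expect_equal(q[j], 0)
      else expect_lt(abs(q[j] - tr[j]) / tr[j], 0.02)
    }
  }
})

test_that("generation is deterministic and honours the spec", {
  spec <- default_spec()
  a <- generate_cohort(spec, seed = 42)
  b <- generate_cohort(spec, seed = 42)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, f1); write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical CSV
  expect_false(identical(a$sural_r, generate_cohort(spec, seed = 43)$sural_r))
  expect_equal(nrow(a), 141L)
  expect_equal(nrow(generate_cohort(spec, seed = 1, scale = 2)), 282L)

  no_miss <- default_spec(missingness = c(sural = 0, sps = 0, srs = 0))
  full <- generate_cohort(no_miss, seed = 3)
  expect_false(anyNA(full[, c("sural_r", "sural_l", "sps_r", "sps_l",
                              "srs_r", "srs_l")]))

  expect_error(generate_cohort(spec, seed = NULL), "seed")
  broken <- spec; broken$age_weights$G3 <- list(`<40` = 0.5)
  expect_error(generate_cohort(broken, seed = 1), "sum to 1")
})

test_that("generated scores respect the group-defining inequalities", {
  co <- generate_cohort(default_spec(), seed = 13)
  g <- assign_group(co$has_dm, co$uens, co$mnsi)
  expect_true(all(co$uens[g %in% c("G1", "G2", "discordant")] < 5))
  expect_true(all(co$uens[g == "G3"] >= 5))
  expect_true(all(co$mnsi[g == "discordant"] > 7.5))
  expect_true(all(co$mnsi[g == "G2"] <= 7.5))
  expect_true(all(co$uens <= 42))
})

test_that("default spec embeds calibrated per-stratum models", {
  spec <- default_spec()
  # a stratum with a positive lower quartile carries no zero mass
  m <- amplitude_model(spec, "G1", "40-49", "sna")
  expect_equal(m$zero_mass, 0)
  # pooled draws from the whole-group neuropathy sural model recover the
  # published median
  g3 <- amplitude_model(spec, "G3", "whole", "sna")
  set.seed(8)
  draws <- snapdx:::zil_draw(g3, 1e5)
  expect_lt(abs(median(draws) - 4.05), 0.5)
})

test_that("specs round-trip through YAML serialisation", {
  spec <- default_spec()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_spec(spec, path)
  back <- read_spec(path)
  expect_equal(unclass(spec), unclass(back), tolerance = 1e-9)
})

test_that("the full pipeline on a scaled cohort shows the expected structure", {
  co <- generate_cohort(default_spec(), seed = 2, scale = 10)
  acc <- suppressMessages(accuracy_table(co, strata = "whole"))
  sweep <- acc[grepl("cpnsi", acc$test), ]
  expect_true(all(diff(sweep$sens) <= 0))
  expect_true(all(diff(sweep$spec) >= 0))
  expect_gt(acc$spec[acc$test == "sural<5.1"], sweep$spec[sweep$test == "cpnsi>=1"])
})
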