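test_that("simulate entry point writes the cohort and its resolved spec", {
  out <- withr::local_tempfile(fileext = ".csv")
  suppressMessages(run_simulate(out, seed = 42))
  expect_true(file.exists(out))
  expect_true(file.exists(paste0(out, ".spec.yaml")))
  expect_equal(nrow(read_cohort(out)), 141L)
  expect_error(run_simulate(withr::local_tempfile(), seed = NULL), "seed")
})

test_that("analyze entry point emits every report and logs exclusions", {
  co <- generate_cohort(default_spec(), seed = 6)
  dir <- withr::local_tempdir()
  msgs <- capture_messages(paths <- run_analyze(cohort = co, out_dir = dir))
  expect_true(any(grepl("excluded", msgs)))
  for (f in c("participants", "ranges", "accuracy_primary",
              "accuracy_cases_only", "accuracy_all")) {
    expect_true(file.exists(file.path(dir, paste0(f, ".csv"))), info = f)
  }
  expect_true(file.exists(file.path(dir, "accuracy_primary.md")))
  # the CSV numbers are the unrounded accuracy_table values
  acc_file <- readr::read_csv(file.path(dir, "accuracy_primary.csv"),
                              show_col_types = FALSE)
  acc_mem <- suppressMessages(accuracy_table(co))
  expect_equal(acc_file$sens, acc_mem$sens, tolerance = 1e-12)
  # markdown cells are half-up renderings of the same values
  md <- readLines(file.path(dir, "accuracy_primary.md"))
  sural_whole <- acc_mem[acc_mem$test == "sural<5.1" & acc_mem$stratum == "whole", ]
  expect_true(any(grepl(sprintf("%.1f%%", floor(1000 * sural_whole$sens + 0.5) / 10), md, fixed = TRUE)))
  expect_error(run_analyze(cohort = co[0, ], out_dir = dir), "empty")
})

test_that("validate entry point reports status and violations", {
  good <- withr::local_tempfile(fileext = ".csv")
  write_cohort(make_toy_cohort(), good)
  res <- suppressMessages(run_validate(good))
  expect_true(res$ok)
  expect_equal(res$n_records, 3L)

  bad <- withr::local_tempfile(fileext = ".csv")
  write_cohort(make_toy_cohort(), bad)
  lines <- readLines(bad)
  lines[2] <- sub("^c1,45", "c1,80", lines[2])
  writeLines(lines, bad)
  res_bad <- suppressMessages(run_validate(bad))
  expect_false(res_bad$ok)
  expect_true(any(res_bad$violations$id == "c1" &
                    grepl("age", res_bad$violations$rule)))

  empty <- withr::local_tempfile(fileext = ".csv")
  write_cohort(make_toy_cohort()[0, ], empty)
  expect_false(suppressMessages(run_validate(empty))$ok)
})

test_that("participants table summarises each group", {
  co <- generate_cohort(default_spec(), seed = 6)
  pt <- participants_table(co)
  expect_setequal(pt$group, c("G1", "G2", "G3", "discordant"))
  expect_equal(pt$n[pt$group == "G3"], 57L)
  g3 <- pt[pt$group == "G3", ]
  expect_gte(g3$uens_median, 5)
  expect_equal(sum(pt[pt$group == "G1", paste0("age_", c("lt40", "40_49", "50_59", "60_75"))]),
               41L)
})

test_that("tidy, glance and autoplot work on accuracy tables", {
  co <- generate_cohort(default_spec(), seed = 6)
  acc <- suppressMessages(accuracy_table(co, strata = "whole"))
  td <- tidy(acc)
  expect_setequal(unique(td$metric), c("sens", "spec", "ppv", "npv", "auc"))
  expect_equal(nrow(td), 5L * nrow(acc))
  expect_true(all(td$conf.low <= td$estimate + 1e-12, na.rm = TRUE))
  gl <- glance(acc)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$variant, "primary")
  p <- autoplot(acc)
  expect_s3_class(p, "ggplot")
  p2 <- plot_range_table(suppressMessages(range_table(co)))
  expect_s3_class(p2, "ggplot")
})
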