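# Pipeline entry points: simulate, analyze, validate. A thin command-line
# wrapper over these lives in inst/cli/snapdx.R.

#' Simulate a cohort and write it next to its resolved specification
#'
#' @param out Output CSV path; the resolved spec is written alongside as
#'   `<out>.spec.yaml`.
#' @param seed Integer seed (required).
#' @param scale Group-size multiplier.
#' @param spec Synthetic specification, default [default_spec()].
#' @return The cohort tibble, invisibly.
#' @export
run_simulate <- function(out, seed, scale = 1, spec = default_spec()) {
  if (missing(seed) || is.null(seed) || is.na(seed)) abort("a seed is required")
  cohort <- generate_cohort(spec, seed = seed, scale = scale)
  write_cohort(cohort, out)
  write_spec(spec, paste0(out, ".spec.yaml"))
  inform(paste0("wrote ", nrow(cohort), " records to ", out))
  invisible(cohort)
}

#' Participant-characteristics table
#'
#' One row per study group: size, median (IQR) age, diabetes duration,
#' UENS and MNSI, male and burning-feet counts, and the age-group
#' distribution.
#'
#' @param cohort Cohort tibble.
#' @param variant Analysis variant controlling group labels.
#' @return Tibble, one row per non-empty group label.
#' @export
participants_table <- function(cohort, variant = "primary") {
  df <- classify_cohort(cohort, variant = variant)
  med_iqr <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(tibble(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(median = q[2], q25 = q[1], q75 = q[3])
  }
  df |>
    dplyr::filter(.data$group %in% c("G1", "G2", "G3", "discordant")) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      ag <- table(factor(d$age_group, levels = age_group_levels()))
      dplyr::bind_cols(
        tibble(n = nrow(d)),
        setNames(med_iqr(d$age), c("age_median", "age_q25", "age_q75")),
        tibble(male_n = sum(d$sex == "male"),
               male_pct = 100 * mean(d$sex == "male")),
        setNames(med_iqr(d$dm_duration), c("dur_median", "dur_q25", "dur_q75")),
        setNames(med_iqr(d$uens), c("uens_median", "uens_q25", "uens_q75")),
        setNames(med_iqr(d$mnsi), c("mnsi_median", "mnsi_q25", "mnsi_q75")),
        tibble(burning_n = sum(d$burning_feet, na.rm = TRUE)),
        as_tibble(setNames(as.list(as.integer(ag)),
                           paste0("age_", c("lt40", "40_49", "50_59", "60_75"))))
      )
    }) |>
    dplyr::ungroup()
}

format_accuracy_md <- function(acc) {
  tibble(
    test = acc$test, stratum = acc$stratum,
    ROC = fmt_est_ci(acc$auc, acc$auc_lo, acc$auc_hi, pct = FALSE),
    sensitivity = fmt_est_ci(acc$sens, acc$sens_lo, acc$sens_hi),
    specificity = fmt_est_ci(acc$spec, acc$spec_lo, acc$spec_hi),
    PPV = fmt_est_ci(acc$ppv, acc$ppv_lo, acc$ppv_hi),
    NPV = fmt_est_ci(acc$npv, acc$npv_lo, acc$npv_hi)
  )
}

format_ranges_md <- function(rng) {
  tibble(
    measure = rng$measure, group = rng$group, age_group = rng$age_group,
    n = rng$n,
    `median (IQR)/5% LLN` = paste0(
      format(round_half_up(rng$median, 2), trim = TRUE), " (",
      format(round_half_up(rng$q25, 2), trim = TRUE), "-",
      format(round_half_up(rng$q75, 2), trim = TRUE), ")/",
      format(round_half_up(rng$p5, 2), trim = TRUE))
  )
}

#' Run the full analysis and write report files
#'
#' Reads (or accepts) a cohort, then writes to `out_dir`: the participant
#' characteristics table, the normative-range table, the accuracy table
#' under the primary comparator (controls plus diabetes-without-neuropathy
#' as the non-diseased class), the accuracy table under the cases-only
#' comparator (controls excluded), and a machine-readable CSV of every
#' accuracy row. Each table is written as CSV and as a markdown rendering
#' with half-up display rounding (percentages to 1 d.p., ROC areas to
#' 3 d.p.); internal computation is never rounded. Exclusion counts are
#' logged.
#'
#' @param input Path to a cohort CSV (or pass `cohort`).
#' @param cohort A cohort tibble, alternative to `input`.
#' @param out_dir Output directory, created if needed.
#' @param variant Variant for group labelling (`"primary"` or
#'   `"include_discordant"`; both accuracy comparators are always emitted).
#' @param confidence Interval coverage level.
#' @param quantile_type Quantile rule for the range table.
#' @param side_policy Side-combination rule for single-measure tests.
#' @param ... Cutoff overrides passed to [accuracy_table()].
#' @return Named list of written file paths, invisibly.
#' @export
run_analyze <- function(input = NULL, cohort = NULL, out_dir,
                        variant = "primary", confidence = 0.95,
                        quantile_type = 7, side_policy = "average", ...) {
  if (is.null(cohort)) {
    if (is.null(input)) abort("provide input (a CSV path) or cohort (a tibble)")
    cohort <- read_cohort(input, strict = TRUE)
  }
  if (!nrow(cohort)) abort("cohort is empty")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  label_variant <- match_variant(variant)
  if (label_variant == "cases_only") label_variant <- "primary"

  cls <- classify_cohort(cohort, variant = label_variant)
  inform(paste0("group labels: ",
                paste(names(table(cls$group)), as.integer(table(cls$group)),
                      sep = "=", collapse = ", ")))
  n_excl <- sum(cls$group %in% c("discordant", "ineligible"))
  inform(paste0(n_excl, " participant(s) excluded from the ", label_variant,
                " analysis"))

  paths <- list()
  emit <- function(df, md_df, name) {
    csv <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(df, csv, progress = FALSE)
    md <- file.path(out_dir, paste0(name, ".md"))
    writeLines(md_table(md_df), md)
    paths[[name]] <<- csv
  }

  pt <- participants_table(cohort, variant = label_variant)
  emit(pt, pt, "participants")

  rng <- range_table(cohort, variant = label_variant,
                     quantile_type = quantile_type, side_policy = side_policy)
  emit(rng, format_ranges_md(rng), "ranges")

  acc_primary <- accuracy_table(cohort, variant = label_variant,
                                confidence = confidence,
                                side_policy = side_policy, ...)
  emit(acc_primary, format_accuracy_md(acc_primary), "accuracy_primary")

  acc_cases <- accuracy_table(cohort, variant = "cases_only",
                              confidence = confidence,
                              side_policy = side_policy, ...)
  emit(acc_cases, format_accuracy_md(acc_cases), "accuracy_cases_only")

  all_rows <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(acc_primary), comparator = label_variant),
    dplyr::mutate(as_tibble(acc_cases), comparator = "cases_only")
  )
  readr::write_csv(all_rows, file.path(out_dir, "accuracy_all.csv"),
                   progress = FALSE)
  paths$accuracy_all <- file.path(out_dir, "accuracy_all.csv")
  invisible(paths)
}

#' Validate a cohort file and summarise violations
#'
#' Runs strict validation rules over the file without stopping at the
#' first failure and prints a per-rule summary.
#'
#' @param input Path to a cohort CSV.
#' @return List with `ok` (logical), `n_records`, and a `violations`
#'   tibble (`id`, `rule`), invisibly; `ok` maps to the CLI exit status.
#' @export
run_validate <- function(input) {
  parsed <- tryCatch(suppressWarnings(read_cohort(input, strict = FALSE)),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    inform(paste0("unreadable cohort: ", conditionMessage(parsed)))
    return(invisible(list(ok = FALSE, n_records = 0L,
                          violations = tibble(id = NA_character_,
                                              rule = conditionMessage(parsed)))))
  }
  # re-read without dropping to enumerate every violation
  raw <- suppressWarnings(readr::read_csv(
    input,
    col_types = readr::cols(id = readr::col_character(),
                            sex = readr::col_character(),
                            has_dm = readr::col_logical(),
                            burning_feet = readr::col_logical(),
                            age = readr::col_integer(),
                            uens = readr::col_integer(),
                            .default = readr::col_double()),
    na = c("", "NA"), progress = FALSE))
  viol <- cohort_violations(raw)
  ok <- nrow(viol) == 0L && nrow(raw) > 0L
  if (nrow(raw) == 0L) {
    viol <- tibble(id = NA_character_, rule = "empty cohort")
  }
  if (ok) {
    inform(paste0("cohort valid: ", nrow(raw), " records"))
  } else {
    counts <- dplyr::count(viol, .data$rule)
    inform(paste0("cohort invalid: ",
                  paste(counts$rule, counts$n, sep = " x", collapse = "; ")))
  }
  invisible(list(ok = ok, n_records = nrow(raw), violations = viol))
}
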