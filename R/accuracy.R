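#' A 2x2 diagnostic table
#'
#' Counts of test-positive/negative participants among reference-positive
#' (diseased) and reference-negative (non-diseased) participants.
#'
#' @param tp,fn,fp,tn Non-negative integer counts: true positives, false
#'   negatives, false positives, true negatives.
#' @return Object of class `twobytwo`.
#' @export
#' @examples
#' twobytwo(39, 18, 6, 72)
twobytwo <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("tp, fn, fp, tn must be non-negative integers")
  }
  structure(as.list(setNames(as.integer(counts), names(counts))),
            class = "twobytwo")
}

#' @export
print.twobytwo <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(c("diseased", "non-diseased"),
                              c("test+", "test-")))
  print(m)
  invisible(x)
}

#' Build a 2x2 table for one test, variant and stratum
#'
#' Cross-tabulates an index test against the clinical reference standard
#' (UENS-defined neuropathy) over participants whose reference status is
#' non-excluded under the variant, whose age group matches the stratum, and
#' whose test result is evaluable (non-missing). A stratum with no evaluable
#' diseased or no evaluable non-diseased participants raises a degenerate-
#' table error (condition class `snapdx_degenerate`) carrying the counts.
#'
#' @param cohort Cohort tibble.
#' @param test An [index_test()] object.
#' @param variant Analysis variant (see [assign_group()]).
#' @param stratum `"whole"` or one of `age_group_levels()`.
#' @param ... Passed to [apply_test()] (side policy, CPNSI cutoffs).
#' @inheritParams assign_group
#' @return A [twobytwo()] object.
#' @export
build_2x2 <- function(cohort, test, variant = "primary", stratum = "whole",
                      uens_cutoff = 5, mnsi_cutoff = 7.5, ...) {
  variant <- match_variant(variant)
  stratum <- rlang::arg_match0(stratum, c("whole", age_group_levels()))
  df <- if (all(c("group", "age_group", "ref_status") %in% names(cohort))) {
    cohort
  } else {
    classify_cohort(cohort, variant = variant,
                    uens_cutoff = uens_cutoff, mnsi_cutoff = mnsi_cutoff)
  }
  df$.result <- apply_test(df, test, ...)
  keep <- df$ref_status != "excluded" & !is.na(df$.result)
  if (stratum != "whole") keep <- keep & df$age_group == stratum
  df <- df[keep, ]
  pos <- df$ref_status == "positive"
  tp <- sum(pos & df$.result); fn <- sum(pos & !df$.result)
  fp <- sum(!pos & df$.result); tn <- sum(!pos & !df$.result)
  if (tp + fn == 0L || fp + tn == 0L) {
    abort(
      sprintf("degenerate 2x2 table for %s in stratum %s: %d evaluable diseased, %d evaluable non-diseased",
              test$label, stratum, tp + fn, fp + tn),
      class = "snapdx_degenerate",
      counts = c(tp = tp, fn = fn, fp = fp, tn = tn)
    )
  }
  twobytwo(tp, fn, fp, tn)
}

#' Sensitivity, specificity and predictive values of a 2x2 table
#'
#' @param table A [twobytwo()] object.
#' @return Tibble with one row per metric (`sensitivity`, `specificity`,
#'   `ppv`, `npv`): the binomial numerator (`successes`), denominator
#'   (`trials`) and point estimate. A predictive value with a zero
#'   denominator is undefined (`NA`).
#' @export
#' @examples
#' proportion_metrics(twobytwo(39, 18, 6, 72))
proportion_metrics <- function(table) {
  stopifnot(inherits(table, "twobytwo"))
  with(table, {
    if (tp + fn == 0L || fp + tn == 0L) abort("degenerate table: empty diseased or non-diseased margin")
    tibble(
      metric = c("sensitivity", "specificity", "ppv", "npv"),
      successes = c(tp, tn, tp, tn),
      trials = c(tp + fn, fp + tn, tp + fp, tn + fn),
      estimate = ifelse(c(tp + fn, fp + tn, tp + fp, tn + fn) == 0,
                        NA_real_, c(tp, tn, tp, tn) / c(tp + fn, fp + tn, tp + fp, tn + fn))
    )
  })
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Computed by beta-quantile inversion: the lower bound is the
#' `alpha/2` quantile of `Beta(x, n - x + 1)` (0 when `x = 0`) and the upper
#' bound the `1 - alpha/2` quantile of `Beta(x + 1, n - x)` (1 when
#' `x = n`).
#'
#' @param successes,trials Integer vectors, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param confidence Coverage level in (0, 1), default 0.95.
#' @return Tibble with columns `lo` and `hi`.
#' @export
#' @examples
#' clopper_pearson_ci(39, 57)
clopper_pearson_ci <- function(successes, trials, confidence = 0.95) {
  if (anyNA(successes) || anyNA(trials) ||
      any(trials < 1) || any(successes < 0) || any(successes > trials)) {
    abort("require 0 <= successes <= trials, trials >= 1")
  }
  stopifnot(confidence > 0, confidence < 1)
  a <- (1 - confidence) / 2
  lo <- ifelse(successes == 0, 0, qbeta(a, successes, trials - successes + 1))
  hi <- ifelse(successes == trials, 1, qbeta(1 - a, successes + 1, trials - successes))
  tibble(lo = lo, hi = hi)
}

#' ROC area of a dichotomous test, with a DeLong-variance interval
#'
#' For a single-cutoff (dichotomous) test the empirical ROC has one interior
#' point, so the trapezoid area is `(sensitivity + specificity) / 2`. The
#' confidence interval is Wald-normal with the DeLong variance of that
#' statistic for a binary marker,
#' `V = sens(1-sens) / (4 (n1 - 1)) + spec(1-spec) / (4 (n0 - 1))`,
#' using sample-variance (n - 1) denominators; `n1`, `n0` are the diseased
#' and non-diseased counts. Bounds are truncated to `[0, 1]`. With fewer
#' than two participants in either margin the interval is undefined and
#' only the estimate is returned.
#'
#' @param table A [twobytwo()] object.
#' @param confidence Coverage level, default 0.95.
#' @return One-row tibble: `estimate`, `lo`, `hi`, `method`.
#' @export
#' @examples
#' binary_auc(twobytwo(39, 18, 6, 72))
binary_auc <- function(table, confidence = 0.95) {
  stopifnot(inherits(table, "twobytwo"))
  n1 <- table$tp + table$fn
  n0 <- table$fp + table$tn
  if (n1 == 0L || n0 == 0L) abort("degenerate table: empty diseased or non-diseased margin")
  sens <- table$tp / n1
  spec <- table$tn / n0
  est <- (sens + spec) / 2
  if (n1 < 2L || n0 < 2L) {
    return(tibble(estimate = est, lo = NA_real_, hi = NA_real_, method = "delong_wald"))
  }
  v <- sens * (1 - sens) / (4 * (n1 - 1)) + spec * (1 - spec) / (4 * (n0 - 1))
  z <- qnorm(1 - (1 - confidence) / 2)
  tibble(
    estimate = est,
    lo = max(0, est - z * sqrt(v)),
    hi = min(1, est + z * sqrt(v)),
    method = "delong_wald"
  )
}

# One accuracy row (wide) from a twobytwo; shared by accuracy_row() and the
# reconstructed-count workflows.
accuracy_from_table <- function(table, confidence = 0.95,
                                test_label = NA_character_,
                                stratum = NA_character_) {
  pm <- proportion_metrics(table)
  ci <- clopper_pearson_ci(pm$successes, pmax(pm$trials, 1L), confidence)
  ci$lo[pm$trials == 0] <- NA_real_
  ci$hi[pm$trials == 0] <- NA_real_
  roc <- binary_auc(table, confidence)
  wide <- setNames(
    as.list(c(rbind(pm$estimate, ci$lo, ci$hi))),
    paste0(rep(pm$metric, each = 3), c("", "_lo", "_hi"))
  )
  names(wide) <- sub("^sensitivity", "sens", names(wide))
  names(wide) <- sub("^specificity", "spec", names(wide))
  dplyr::bind_cols(
    tibble(test = test_label, stratum = stratum,
           tp = table$tp, fn = table$fn, fp = table$fp, tn = table$tn),
    as_tibble(wide),
    tibble(auc = roc$estimate, auc_lo = roc$lo, auc_hi = roc$hi)
  )
}

#' One accuracy-table row: a test evaluated in a stratum
#'
#' Builds the 2x2 table and assembles the five estimates: sensitivity,
#' specificity, PPV and NPV with exact Clopper-Pearson intervals (each on
#' its own numerator/denominator) and the dichotomous ROC area with its
#' DeLong-variance interval.
#'
#' @inheritParams build_2x2
#' @param confidence Coverage level for every interval.
#' @return One-row tibble with the counts and `estimate`/`_lo`/`_hi`
#'   triplets for `sens`, `spec`, `ppv`, `npv`, `auc`.
#' @export
accuracy_row <- function(cohort, test, variant = "primary", stratum = "whole",
                         confidence = 0.95, ...) {
  tab <- build_2x2(cohort, test, variant = variant, stratum = stratum, ...)
  accuracy_from_table(tab, confidence, test_label = test$label, stratum = stratum)
}

#' Full accuracy table over a test battery and age strata
#'
#' Evaluates every test in every stratum under one analysis variant,
#' assembling the analogue of a published diagnostic-accuracy table (one
#' row per test x stratum). Degenerate strata (no evaluable diseased or
#' non-diseased participants) are skipped with a message rather than
#' failing the whole table.
#'
#' @inheritParams build_2x2
#' @param tests List of [index_test()] objects, default [index_tests()].
#' @param strata Character vector of strata: `"whole"` and/or age-group
#'   labels. Default: whole cohort plus every age group.
#' @param confidence Coverage level for all intervals.
#' @return A tibble of class `snap_accuracy` with attributes `variant` and
#'   `confidence`; supports [generics::tidy()], [generics::glance()] and
#'   [ggplot2::autoplot()].
#' @export
accuracy_table <- function(cohort, tests = index_tests(), variant = "primary",
                           strata = c("whole", age_group_levels()),
                           confidence = 0.95, uens_cutoff = 5,
                           mnsi_cutoff = 7.5, ...) {
  variant <- match_variant(variant)
  classified <- classify_cohort(cohort, variant = variant,
                                uens_cutoff = uens_cutoff, mnsi_cutoff = mnsi_cutoff)
  grid <- tidyr::expand_grid(test = tests, stratum = strata)
  rows <- purrr::pmap(grid, function(test, stratum) {
    tryCatch(
      accuracy_row(classified, test, variant = variant, stratum = stratum,
                   confidence = confidence, ...),
      snapdx_degenerate = function(e) {
        inform(paste0("skipping ", test$label, " in stratum ", stratum, ": ",
                      conditionMessage(e)))
        NULL
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("snap_accuracy", class(out)),
            variant = variant, confidence = confidence)
}

#' Reconstruct integer 2x2 counts from printed accuracy percentages
#'
#' Given the diseased and non-diseased group sizes and a sensitivity and
#' specificity printed at fixed decimal precision, finds the unique integer
#' true-positive and true-negative counts whose proportions round (half
#' away from zero) to the printed values. Errors if no integer is
#' consistent, or if several are (listing the candidates).
#'
#' @param n_diseased,n_nondiseased Group sizes.
#' @param sens_pct,spec_pct Printed sensitivity and specificity, percent.
#' @param digits Printed decimal places (default 1).
#' @return A [twobytwo()] object.
#' @export
#' @examples
#' reconstruct_counts(57, 78, 68.4, 92.3)
reconstruct_counts <- function(n_diseased, n_nondiseased, sens_pct, spec_pct,
                               digits = 1) {
  stopifnot(sens_pct >= 0, sens_pct <= 100, spec_pct >= 0, spec_pct <= 100,
            n_diseased >= 1, n_nondiseased >= 1)
  find_unique <- function(pct, n, what) {
    k <- 0:n
    hit <- k[round_half_up(100 * k / n, digits) == round_half_up(pct, digits)]
    if (length(hit) == 0L) {
      abort(sprintf("no integer count out of %d rounds to %s%% for %s", n, pct, what))
    }
    if (length(hit) > 1L) {
      abort(sprintf("ambiguous %s: candidates %s out of %d all round to %s%%",
                    what, paste(hit, collapse = ", "), n, pct))
    }
    hit
  }
  tp <- find_unique(sens_pct, n_diseased, "sensitivity")
  tn <- find_unique(spec_pct, n_nondiseased, "specificity")
  twobytwo(tp, n_diseased - tp, n_nondiseased - tn, tn)
}
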