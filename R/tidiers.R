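#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an accuracy table into long metric form
#'
#' @param x A `snap_accuracy` table (see [accuracy_table()]).
#' @param ... Unused.
#' @return Tibble with one row per test, stratum and metric
#'   (`sens`, `spec`, `ppv`, `npv`, `auc`): `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.snap_accuracy <- function(x, ...) {
  df <- as_tibble(x)
  purrr::map_dfr(c("sens", "spec", "ppv", "npv", "auc"), function(m) {
    tibble(
      test = df$test, stratum = df$stratum, metric = m,
      estimate = df[[m]],
      conf.low = df[[paste0(m, "_lo")]],
      conf.high = df[[paste0(m, "_hi")]]
    )
  }) |>
    dplyr::arrange(.data$test, .data$stratum)
}

#' One-row summary of an accuracy table
#'
#' @param x A `snap_accuracy` table.
#' @param ... Unused.
#' @return Tibble: analysis variant, confidence level, numbers of tests,
#'   strata and rows, and total evaluable diseased/non-diseased counts in
#'   the whole-cohort rows.
#' @export
glance.snap_accuracy <- function(x, ...) {
  df <- as_tibble(x)
  whole <- df[df$stratum == "whole", ]
  tibble(
    variant = attr(x, "variant") %||% NA_character_,
    confidence = attr(x, "confidence") %||% NA_real_,
    n_tests = dplyr::n_distinct(df$test),
    n_strata = dplyr::n_distinct(df$stratum),
    n_rows = nrow(df),
    max_diseased = if (nrow(whole)) max(whole$tp + whole$fn) else NA_integer_,
    max_nondiseased = if (nrow(whole)) max(whole$fp + whole$tn) else NA_integer_
  )
}
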