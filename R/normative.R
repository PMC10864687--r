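#' Summarise an amplitude sample: median, quartiles and 5% lower limit
#'
#' Quantiles use linear interpolation between order statistics at position
#' `p (n - 1) + 1` (`stats::quantile` type 7, the common scientific-
#' computing default); the interpolation rule is configurable because the
#' 5th percentile at very small n is estimator-sensitive. Missing values
#' are excluded.
#'
#' @param values Numeric vector with at least one non-missing value.
#' @param quantile_type Interpolation rule passed to [stats::quantile()]
#'   (default 7).
#' @return One-row tibble: `n`, `median`, `q25`, `q75`, `p5` (the 5% lower
#'   limit of normal when the sample is a reference stratum).
#' @export
#' @examples
#' summarize_range(c(0, 0, 0, 4, 8))
summarize_range <- function(values, quantile_type = 7) {
  x <- values[!is.na(values)]
  if (length(x) == 0L) abort("summarize_range requires at least one non-missing value")
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75), type = quantile_type, names = FALSE)
  tibble(n = length(x), median = q[3], q25 = q[2], q75 = q[4], p5 = q[1])
}

#' Normative-range table by group and age group
#'
#' Summarises the side-averaged sural (`sna`), superficial peroneal
#' (`spsa`) and superficial radial (`srsa`) amplitudes and the
#' sural-to-radial ratio (`srar`) for each study group, in the whole cohort
#' and within each age-group stratum. Strata with no evaluable data are
#' omitted with a message. In a reference (non-neuropathy) stratum, `p5` is
#' the 5% lower limit of normal and `q25` the 25% LLN.
#'
#' @param cohort Cohort tibble.
#' @param variant Analysis variant controlling group labels.
#' @param quantile_type Quantile interpolation rule (see
#'   [summarize_range()]).
#' @param side_policy Side-combination rule (see [apply_test()]).
#' @return Tibble: `group`, `age_group` (`"whole"` or a stratum), `measure`,
#'   `n`, `median`, `q25`, `q75`, `p5`.
#' @export
range_table <- function(cohort, variant = "primary", quantile_type = 7,
                        side_policy = "average") {
  df <- classify_cohort(cohort, variant = variant)
  df <- score_cohort(df, side_policy = side_policy)
  df <- df[df$group %in% c("G1", "G2", "G3"), ]
  measures <- c("sna", "spsa", "srsa", "srar")
  strata <- c("whole", age_group_levels())
  grid <- tidyr::expand_grid(group = c("G1", "G2", "G3"),
                             age_group = strata, measure = measures)
  rows <- purrr::pmap(grid, function(group, age_group, measure) {
    sel <- df$group == group
    if (age_group != "whole") sel <- sel & df$age_group == age_group
    x <- df[[measure]][sel]
    if (all(is.na(x))) {
      inform(paste0("omitting empty stratum: ", group, " / ", age_group, " / ", measure))
      return(NULL)
    }
    dplyr::bind_cols(tibble(group = group, age_group = age_group, measure = measure),
                     summarize_range(x, quantile_type))
  })
  dplyr::bind_rows(rows)
}

#' Two-group comparison p-value
#'
#' Rank-sum (Mann-Whitney U, via [stats::wilcox.test()]) for two value
#' samples, or Fisher's exact test for a 2x2 count table. Two-sided.
#'
#' @param x Numeric sample (rank_sum) or a 2x2 integer matrix
#'   (fisher_exact).
#' @param y Second numeric sample (rank_sum only).
#' @param kind `"rank_sum"` or `"fisher_exact"`.
#' @return One-row tibble: `method`, `statistic` (rank-sum W, `NA` for
#'   Fisher) and `p_value`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(101, 102, 103))
#' compare_groups(matrix(c(10, 0, 0, 10), 2), kind = "fisher_exact")
compare_groups <- function(x, y = NULL, kind = c("rank_sum", "fisher_exact")) {
  kind <- match.arg(kind)
  if (kind == "rank_sum") {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) abort("rank_sum requires two non-empty samples")
    ht <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
    tibble(method = "rank_sum", statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    if (!is.matrix(x) || !all(dim(x) == c(2L, 2L)) || any(x < 0)) {
      abort("fisher_exact requires a 2x2 matrix of non-negative counts")
    }
    ht <- fisher.test(x, alternative = "two.sided")
    tibble(method = "fisher_exact", statistic = NA_real_, p_value = ht$p.value)
  }
}

#' Multi-group comparison (Kruskal-Wallis)
#'
#' Tie-corrected Kruskal-Wallis rank test across three or more samples,
#' with the chi-square reference distribution.
#'
#' @param groups List of at least three non-empty numeric vectors.
#' @param kind Only `"kruskal_wallis"`.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' compare_many(list(1:5, 11:15, 21:25))
compare_many <- function(groups, kind = "kruskal_wallis") {
  kind <- rlang::arg_match0(kind, "kruskal_wallis")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3L || any(lengths(groups) == 0L)) {
    abort("kruskal_wallis requires >= 3 non-empty groups")
  }
  ht <- kruskal.test(groups)
  tibble(method = "kruskal_wallis", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value)
}
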