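#' Average an amplitude over body sides
#'
#' Arithmetic mean of the left and right measurements; if only one side was
#' measured that side is used; if both are missing the result is missing.
#' An amplitude of 0 (absent response) participates in the average.
#'
#' @param left,right Numeric vectors of amplitudes in microvolts (or a
#'   dimensionless ratio); non-negative where present.
#' @return Numeric vector of side-averaged values.
#' @export
#' @examples
#' side_average(c(10, NA, 0), c(14, 8, 0))
side_average <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    abort("amplitudes must be non-negative")
  }
  out <- rowMeans(cbind(left, right), na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

# Lower (worse) of the measured sides; alternative side policy.
side_worst <- function(left, right) {
  if (any(left < 0, na.rm = TRUE) || any(right < 0, na.rm = TRUE)) {
    abort("amplitudes must be non-negative")
  }
  out <- pmin(left, right, na.rm = TRUE)
  out
}

combine_sides <- function(left, right, side_policy = c("average", "worst_side")) {
  side_policy <- match.arg(side_policy)
  if (side_policy == "average") side_average(left, right) else side_worst(left, right)
}

#' Sural-to-radial amplitude ratio (SRAR)
#'
#' Divides the sural amplitude by the superficial radial amplitude. The
#' ratio is undefined (missing) when the radial amplitude is 0 or either
#' input is missing; an absent sural response over a measurable radial gives
#' a ratio of 0.
#'
#' @param sna,srsa Numeric vectors: sural and superficial radial sensory
#'   amplitudes (microvolts), typically side-averaged.
#' @return Numeric vector of ratios.
#' @export
#' @examples
#' compute_srar(c(7.5, 0, 5), c(37.5, 20, 0))
compute_srar <- function(sna, srsa) {
  ifelse(is.na(sna) | is.na(srsa) | srsa == 0, NA_real_, sna / srsa)
}

#' Dichotomise a value at a diagnostic cutoff
#'
#' Strict less-than: a value equal to the cutoff is test-negative. Missing
#' values propagate.
#'
#' @param value Numeric vector (amplitude or ratio).
#' @param cutoff Positive scalar in the same units.
#' @return Logical vector (`TRUE` = test positive), `NA` where missing.
#' @export
single_nerve_positive <- function(value, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff > 0)
  value < cutoff
}

#' Combined polyneuropathy sensory index (CPNSI)
#'
#' The CPNSI (also written CSPNI) awards one point per nerve potential below
#' its 25%-lower-limit-of-normal cutoff: right and left sural below
#' `sural_cutoff` (default 8.5 uV), right and left superficial peroneal
#' below `sps_cutoff` (default 4.5 uV) -- four points maximum. All
#' comparisons are strictly less-than, so a value equal to its cutoff scores
#' no point. If any of the four potentials is missing the score is missing
#' (listwise: such participants drop out of CPNSI-based tables).
#'
#' @param cohort Cohort tibble with `sural_r`, `sural_l`, `sps_r`, `sps_l`.
#' @param sural_cutoff,sps_cutoff Per-nerve point thresholds in microvolts.
#' @return Integer vector of scores 0--4, `NA` where incomplete.
#' @export
#' @examples
#' compute_cpnsi(tibble::tibble(sural_r = 8, sural_l = 9, sps_r = 4, sps_l = 5))
compute_cpnsi <- function(cohort, sural_cutoff = 8.5, sps_cutoff = 4.5) {
  pts <- (cohort$sural_r < sural_cutoff) + (cohort$sural_l < sural_cutoff) +
    (cohort$sps_r < sps_cutoff) + (cohort$sps_l < sps_cutoff)
  as.integer(pts)
}

#' Define an index test
#'
#' The diagnostic battery comprises three single-measure cutoffs and the
#' CPNSI threshold family: side-combined sural amplitude below 5.1 uV,
#' side-combined superficial peroneal amplitude below 4.5 uV,
#' sural-to-radial ratio below 0.2, and CPNSI at or above `k` points
#' (`k` in 1--4).
#'
#' @param name One of `"sural"`, `"sps"`, `"srar"`, `"cpnsi"`.
#' @param k CPNSI positivity threshold (required iff `name = "cpnsi"`).
#' @param cutoff Override of the default cutoff for the single-measure tests.
#' @return An object of class `snap_test`.
#' @export
#' @examples
#' index_test("cpnsi", k = 3)
index_test <- function(name = c("sural", "sps", "srar", "cpnsi"), k = NULL,
                       cutoff = NULL) {
  name <- match.arg(name)
  if (name == "cpnsi") {
    if (is.null(k) || !k %in% 1:4) abort("cpnsi test requires k in 1..4")
    if (!is.null(cutoff)) abort("cutoff does not apply to the cpnsi test; see compute_cpnsi()")
    label <- paste0("cpnsi>=", k)
  } else {
    if (!is.null(k)) abort("k applies only to the cpnsi test")
    cutoff <- cutoff %||% c(sural = 5.1, sps = 4.5, srar = 0.2)[[name]]
    label <- paste0(name, "<", format(cutoff))
  }
  structure(list(name = name, k = k, cutoff = cutoff, label = label),
            class = "snap_test")
}

#' @export
print.snap_test <- function(x, ...) {
  cat("<snap_test> ", x$label, "\n", sep = "")
  invisible(x)
}

#' The standard test battery
#'
#' @param ks CPNSI thresholds to include (default 1--4).
#' @return Named list of [index_test()] objects: sural, SPS, SRAR and one
#'   CPNSI test per threshold.
#' @export
index_tests <- function(ks = 1:4) {
  tests <- c(
    list(index_test("sural"), index_test("sps"), index_test("srar")),
    lapply(ks, function(k) index_test("cpnsi", k = k))
  )
  setNames(tests, vapply(tests, `[[`, "", "label"))
}

#' Apply an index test to every participant
#'
#' Dispatches on the test definition: single-measure tests use the
#' side-combined amplitude (or the SRAR of side-combined amplitudes);
#' CPNSI tests are positive when the score reaches `k`. Missingness
#' propagates (a missing score or measure gives a missing result).
#'
#' @param cohort Cohort tibble.
#' @param test A [index_test()] object.
#' @param side_policy How to combine left/right for the single-measure
#'   tests: `"average"` (default) or `"worst_side"` (lower amplitude).
#' @param cpnsi_sural_cutoff,cpnsi_sps_cutoff CPNSI per-nerve thresholds.
#' @return Logical vector, `NA` where the test is not evaluable.
#' @export
apply_test <- function(cohort, test, side_policy = "average",
                       cpnsi_sural_cutoff = 8.5, cpnsi_sps_cutoff = 4.5) {
  if (!inherits(test, "snap_test")) abort("test must be an index_test() object")
  switch(test$name,
    sural = single_nerve_positive(
      combine_sides(cohort$sural_l, cohort$sural_r, side_policy), test$cutoff),
    sps = single_nerve_positive(
      combine_sides(cohort$sps_l, cohort$sps_r, side_policy), test$cutoff),
    srar = single_nerve_positive(
      compute_srar(combine_sides(cohort$sural_l, cohort$sural_r, side_policy),
                   combine_sides(cohort$srs_l, cohort$srs_r, side_policy)),
      test$cutoff),
    cpnsi = compute_cpnsi(cohort, cpnsi_sural_cutoff, cpnsi_sps_cutoff) >= test$k
  )
}

#' Score a cohort: append derived measures
#'
#' Adds side-combined amplitudes (`sna`, `spsa`, `srsa`), the
#' sural-to-radial ratio (`srar`) and the CPNSI score (`cpnsi`).
#'
#' @inheritParams apply_test
#' @param sural_cutoff,sps_cutoff CPNSI per-nerve thresholds (microvolts).
#' @return The cohort with five derived columns appended.
#' @export
score_cohort <- function(cohort, side_policy = "average",
                         sural_cutoff = 8.5, sps_cutoff = 4.5) {
  dplyr::mutate(
    cohort,
    sna = combine_sides(.data$sural_l, .data$sural_r, side_policy),
    spsa = combine_sides(.data$sps_l, .data$sps_r, side_policy),
    srsa = combine_sides(.data$srs_l, .data$srs_r, side_policy),
    srar = compute_srar(.data$sna, .data$srsa),
    cpnsi = compute_cpnsi(cohort, sural_cutoff, sps_cutoff)
  )
}
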