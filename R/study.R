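# Published study inputs used to calibrate the simulator and to rebuild the
# reported accuracy rows from their printed marginals. These are inputs to
# the pipeline (group sizes, normative median/IQR triplets, printed
# sensitivity/specificity), not results: every metric downstream is
# recomputed.

#' Study group sizes
#'
#' Cohort composition of the source study: 41 controls (G1), 37 with
#' diabetes and no clinical neuropathy (G2), 57 with clinical diabetic
#' neuropathy (G3), plus 6 scale-discordant participants (diabetes, UENS
#' below 5 but MNSI above 7.5) excluded from the primary analysis.
#'
#' @return Named integer vector `c(G1, G2, G3, discordant)`.
#' @export
study_group_sizes <- function() {
  c(G1 = 41L, G2 = 37L, G3 = 57L, discordant = 6L)
}

#' Study age-group composition per group
#'
#' Counts of participants per age-group stratum within each study group
#' (ascending age convention). The discordant participants' distribution is
#' not published; the G2 distribution is reused for them.
#'
#' @return Tibble: `group`, `age_group`, `n`.
#' @export
study_age_counts <- function() {
  tibble(
    group = rep(c("G1", "G2", "G3"), each = 4L),
    age_group = rep(age_group_levels(), 3L),
    n = c(0L, 18L, 20L, 3L,
          10L, 11L, 15L, 1L,
          2L, 10L, 28L, 17L)
  )
}

#' Published normative amplitude triplets (median, q25, q75)
#'
#' Side-averaged amplitude summaries per group and age-group stratum for
#' the sural (`sna`), superficial peroneal (`spsa`) and superficial radial
#' (`srsa`) nerves, in microvolts, plus the sural-to-radial ratio
#' (`srar`, dimensionless). `age_group = "whole"` rows are whole-group
#' summaries. The control group has no under-40 participants, so those
#' strata are absent.
#'
#' @return Tibble: `measure`, `group`, `age_group`, `median`, `q25`, `q75`.
#' @export
study_range_targets <- function() {
  tribble_rows <- list(
    # measure, group, age_group, median, q25, q75
    list("sna", "G1", "whole", 11.9, 9.15, 15.25),
    list("sna", "G1", "40-49", 13.38, 9.95, 17.35),
    list("sna", "G1", "50-59", 12.2, 8.68, 14.63),
    list("sna", "G1", "60-75", 7.55, 7.5, 11.6),
    list("sna", "G2", "whole", 10.5, 8.55, 15.75),
    list("sna", "G2", "<40", 15.25, 10.1, 21.8),
    list("sna", "G2", "40-49", 11, 8.5, 15.4),
    list("sna", "G2", "50-59", 8.85, 8.5, 14.2),
    list("sna", "G2", "60-75", 6.65, 6.65, 6.65),
    list("sna", "G3", "whole", 4.05, 0, 8.95),
    list("sna", "G3", "<40", 8.18, 0, 16.35),
    list("sna", "G3", "40-49", 2.03, 0, 7.9),
    list("sna", "G3", "50-59", 4.37, 0, 9.57),
    list("sna", "G3", "60-75", 0, 0, 8.75),
    list("spsa", "G1", "whole", 7.95, 6.25, 10),
    list("spsa", "G1", "40-49", 8.4, 6.65, 10),
    list("spsa", "G1", "50-59", 7.7, 5.7, 9.95),
    list("spsa", "G1", "60-75", 5.07, 0.83, 9.3),
    list("spsa", "G2", "whole", 5.5, 4.25, 10.5),
    list("spsa", "G2", "<40", 8.7, 4.65, 10.6),
    list("spsa", "G2", "40-49", 6.65, 4.6, 9.4),
    list("spsa", "G2", "50-59", 5.05, 3.55, 13.5),
    list("spsa", "G2", "60-75", 5.15, 5.15, 5.15),
    list("spsa", "G3", "whole", 0, 0, 4.3),
    list("spsa", "G3", "<40", 1.87, 0, 3.75),
    list("spsa", "G3", "40-49", 3.18, 0, 4),
    list("spsa", "G3", "50-59", 1.55, 0, 4.33),
    list("spsa", "G3", "60-75", 0, 0, 5.3),
    list("srsa", "G1", "whole", 29.8, 26.3, 37.55),
    list("srsa", "G1", "40-49", 30.4, 26.3, 40.45),
    list("srsa", "G1", "50-59", 28.6, 25.95, 32.05),
    list("srsa", "G1", "60-75", 37.5, 37.5, 37.5),
    list("srsa", "G2", "whole", 28, 24, 39.4),
    list("srsa", "G2", "<40", 32.3, 26.9, 42.75),
    list("srsa", "G2", "40-49", 27.55, 25.45, 32.05),
    list("srsa", "G2", "50-59", 25.7, 18.05, 40.9),
    list("srsa", "G2", "60-75", 24.9, 24.9, 24.9),
    list("srsa", "G3", "whole", 18.1, 10.85, 26.55),
    list("srsa", "G3", "<40", 16.35, 6.5, 26.2),
    list("srsa", "G3", "40-49", 19.27, 10.2, 33.15),
    list("srsa", "G3", "50-59", 18.7, 11.3, 27.6),
    list("srsa", "G3", "60-75", 13.45, 10.85, 20.85),
    list("srar", "G1", "whole", 0.39, 0.33, 0.51),
    list("srar", "G1", "40-49", 0.43, 0.35, 0.55),
    list("srar", "G1", "50-59", 0.41, 0.29, 0.51),
    list("srar", "G1", "60-75", 0.2, 0.2, 0.2),
    list("srar", "G2", "whole", 0.36, 0.3, 0.47),
    list("srar", "G2", "<40", 0.36, 0.32, 0.74),
    list("srar", "G2", "40-49", 0.35, 0.28, 0.5),
    list("srar", "G2", "50-59", 0.41, 0.31, 0.46),
    list("srar", "G2", "60-75", 0.27, 0.27, 0.27),
    list("srar", "G3", "whole", 0.21, 0, 0.41),
    list("srar", "G3", "<40", 0.31, 0, 0.62),
    list("srar", "G3", "40-49", 0.11, 0, 0.32),
    list("srar", "G3", "50-59", 0.22, 0, 0.46),
    list("srar", "G3", "60-75", 0.15, 0, 0.41)
  )
  purrr::map_dfr(tribble_rows, function(r) {
    tibble(measure = r[[1]], group = r[[2]], age_group = r[[3]],
           median = r[[4]], q25 = r[[5]], q75 = r[[6]])
  })
}

#' Published whole-cohort accuracy marginals
#'
#' The group sizes and printed sensitivity/specificity of the whole-cohort
#' accuracy rows whose integer 2x2 tables are uniquely recoverable (see
#' [reconstruct_counts()]): the single-sural and single-SPS cutoffs and the
#' CPNSI threshold family under the primary comparator (controls plus
#' diabetes-without-neuropathy), and the sural cutoff under the cases-only
#' comparator. The sural-to-radial ratio rows are omitted: their evaluable
#' denominators were never printed, so no unique table exists.
#'
#' @return Tibble: `test`, `comparator`, `n_diseased`, `n_nondiseased`,
#'   `sens_pct`, `spec_pct`.
#' @export
study_accuracy_inputs <- function() {
  tibble(
    test = c("sural<5.1", "sps<4.5", "cpnsi>=1", "cpnsi>=2", "cpnsi>=3",
             "cpnsi>=4", "sural<5.1"),
    comparator = c(rep("primary", 6L), "cases_only"),
    n_diseased = rep(57L, 7L),
    n_nondiseased = c(78L, 72L, 72L, 72L, 72L, 72L, 37L),
    sens_pct = c(68.4, 86.0, 91.2, 80.7, 66.7, 54.4, 68.4),
    spec_pct = c(92.3, 58.3, 41.7, 72.2, 94.4, 98.6, 86.5)
  )
}

# Group-level descriptive parameters (medians/IQRs and proportions) used by
# the simulator: age medians are implied by the age-group mix; these cover
# diabetes duration, MNSI, sex and burning feet.
study_group_descriptives <- function() {
  tibble(
    group = c("G1", "G2", "G3", "discordant"),
    male_prop = c(0.463, 0.487, 0.5614, 0.5),
    burning_prop = c(0.073, 0.324, 0.667, 0.324),
    dur_median = c(NA, 5.5, 15, 5.5),
    dur_q25 = c(NA, 2, 10, 2),
    dur_q75 = c(NA, 12.5, 21.5, 12.5),
    mnsi_median = c(0, 2, 10.5, 9),
    mnsi_q25 = c(0, 1, 8, 8.2),
    mnsi_q75 = c(1.5, 5, 13, 10.5)
  )
}
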