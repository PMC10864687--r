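#' Assign study groups from diabetes status and neuropathy-scale scores
#'
#' Implements the group definitions: G1, control participants without
#' diabetes and UENS < `uens_cutoff`; G2, diabetes without clinical
#' neuropathy (UENS < cutoff, MNSI at or below `mnsi_cutoff`); G3, clinical
#' diabetic neuropathy (UENS at or above the cutoff, regardless of MNSI).
#' Participants with diabetes whose UENS is below the cutoff but whose MNSI
#' exceeds `mnsi_cutoff` are scale-discordant: they are labelled
#' `"discordant"` and excluded under the `primary` and `cases_only` variants,
#' and folded into G2 under `include_discordant`. Non-diabetic participants
#' with UENS at or above the cutoff fall outside the study design and are
#' labelled `"ineligible"`, never silently pooled.
#'
#' @param has_dm Logical vector, diabetes status.
#' @param uens Integer vector, Utah Early Neuropathy Scale score (0--42).
#'   The clinical reference standard: may not be missing.
#' @param mnsi Numeric vector, combined Michigan Neuropathy Screening
#'   Instrument score. Consulted only for participants with diabetes and
#'   UENS below the cutoff; may not be missing there.
#' @param variant One of `"primary"`, `"include_discordant"`,
#'   `"cases_only"`. The label set differs only for discordant records
#'   (under `include_discordant` they become G2); `cases_only` changes the
#'   comparator, not the labels (see [reference_positive()]).
#' @param uens_cutoff UENS threshold defining clinical neuropathy
#'   (default 5; the comparison is `>=`).
#' @param mnsi_cutoff MNSI discordance threshold (default 7.5; the
#'   comparison is strictly `>`).
#' @return Factor with levels `G1`, `G2`, `G3`, `discordant`, `ineligible`.
#' @export
#' @examples
#' assign_group(has_dm = c(FALSE, TRUE, TRUE, TRUE),
#'              uens = c(0L, 10L, 2L, 2L),
#'              mnsi = c(0, 11, 3, 9))
assign_group <- function(has_dm, uens, mnsi, variant = "primary",
                         uens_cutoff = 5, mnsi_cutoff = 7.5) {
  variant <- match_variant(variant)
  n <- length(has_dm)
  stopifnot(length(uens) == n, length(mnsi) == n)
  if (anyNA(uens)) {
    abort("uens (the clinical reference standard) may not be missing")
  }
  consults_mnsi <- has_dm & uens < uens_cutoff
  if (anyNA(mnsi[consults_mnsi])) {
    abort("mnsi may not be missing for participants with diabetes and UENS below the cutoff")
  }
  label <- dplyr::case_when(
    !has_dm & uens < uens_cutoff ~ "G1",
    !has_dm ~ "ineligible",
    uens >= uens_cutoff ~ "G3",
    mnsi <= mnsi_cutoff ~ "G2",
    variant == "include_discordant" ~ "G2",
    .default = "discordant"
  )
  factor(label, levels = group_levels)
}

#' Flag scale-discordant participants
#'
#' A record is discordant when it has diabetes, UENS below the neuropathy
#' cutoff, but MNSI above the discordance threshold. The set of discordant
#' records is the same under every analysis variant; only their destination
#' label changes.
#'
#' @inheritParams assign_group
#' @return Logical vector.
#' @export
is_discordant <- function(has_dm, uens, mnsi, uens_cutoff = 5, mnsi_cutoff = 7.5) {
  if (anyNA(uens)) abort("uens may not be missing")
  out <- has_dm & uens < uens_cutoff & !is.na(mnsi) & mnsi > mnsi_cutoff
  out
}

#' Assign the age-group stratum
#'
#' Partitions the 18--75 year inclusion range into `<40`, `40-49`, `50-59`
#' and `60-75` (all bounds inclusive on the labelled decade).
#'
#' @param age Integer vector of ages in years, each within 18--75.
#' @return Factor with levels `age_group_levels()`.
#' @export
#' @examples
#' assign_age_group(c(25, 40, 54, 75))
assign_age_group <- function(age) {
  if (anyNA(age) || any(age < 18 | age > 75)) {
    abort("age must be within [18, 75] and non-missing")
  }
  cut(age, breaks = c(18, 40, 50, 60, 76), labels = age_group_levels(),
      right = FALSE, include.lowest = TRUE)
}

#' Reference-standard status of each group under an analysis variant
#'
#' G3 is reference-positive under every variant. Under `primary` and
#' `include_discordant` the reference-negative class is G1 together with G2;
#' under `cases_only` the comparator is G2 alone and control participants
#' are excluded. Discordant and ineligible labels are always excluded.
#'
#' @param group Factor or character of group labels (see [assign_group()]).
#' @param variant Analysis variant.
#' @return Character vector: `"positive"`, `"negative"` or `"excluded"`.
#' @export
reference_positive <- function(group, variant = "primary") {
  variant <- match_variant(variant)
  group <- as.character(group)
  dplyr::case_when(
    group == "G3" ~ "positive",
    group == "G2" ~ "negative",
    group == "G1" & variant != "cases_only" ~ "negative",
    .default = "excluded"
  )
}

#' Classify a cohort: add group, age-group and reference-status columns
#'
#' Convenience wrapper applying [assign_group()], [assign_age_group()] and
#' [reference_positive()] across a cohort tibble.
#'
#' @param cohort Cohort tibble (see [read_cohort()]).
#' @inheritParams assign_group
#' @return The cohort with `group`, `age_group` and `ref_status` columns
#'   appended.
#' @export
classify_cohort <- function(cohort, variant = "primary",
                            uens_cutoff = 5, mnsi_cutoff = 7.5) {
  variant <- match_variant(variant)
  dplyr::mutate(
    cohort,
    group = assign_group(.data$has_dm, .data$uens, .data$mnsi, variant = variant,
                         uens_cutoff = uens_cutoff, mnsi_cutoff = mnsi_cutoff),
    age_group = assign_age_group(.data$age),
    ref_status = reference_positive(.data$group, variant = variant)
  )
}
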