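#' Read a participant cohort from CSV
#'
#' Reads participant-level data in the canonical schema: one row per subject
#' with demographics (`id`, `age`, `sex`), diabetes status (`has_dm`,
#' `dm_duration`), neuropathy-scale scores (`uens`, `mnsi`, `burning_feet`)
#' and six bilateral sensory amplitudes in microvolts (`sural_r`, `sural_l`,
#' `sps_r`, `sps_l`, `srs_r`, `srs_l`). Empty cells are read as missing; an
#' amplitude of 0 encodes an elicited-but-absent response and is distinct
#' from a missing (not performed) measurement.
#'
#' @param path Path to a CSV file with a header row naming every schema
#'   column (any order; extra or absent columns are an error). Booleans are
#'   written `true`/`false`; `TRUE`/`FALSE` are also accepted.
#' @param strict If `TRUE` (default) any invariant violation aborts with a
#'   message naming the rule and the offending ids; if `FALSE` offending
#'   records are dropped with a warning giving the count.
#' @return A validated cohort tibble in canonical column order, carrying the
#'   file path as its `provenance` attribute.
#' @seealso [write_cohort()], [validate_cohort()]
#' @export
read_cohort <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  missing_cols <- setdiff(cohort_columns, header)
  extra_cols <- setdiff(header, cohort_columns)
  if (length(missing_cols) || length(extra_cols)) {
    abort(paste0(
      "cohort header does not match schema",
      if (length(missing_cols)) paste0("; missing: ", paste(missing_cols, collapse = ", ")),
      if (length(extra_cols)) paste0("; unexpected: ", paste(extra_cols, collapse = ", "))
    ))
  }
  spec <- readr::cols(
    id = readr::col_character(),
    age = readr::col_integer(),
    sex = readr::col_character(),
    has_dm = readr::col_logical(),
    dm_duration = readr::col_double(),
    uens = readr::col_integer(),
    mnsi = readr::col_double(),
    burning_feet = readr::col_logical(),
    .default = readr::col_double()
  )
  df <- readr::read_csv(path, col_types = spec, na = c("", "NA"), progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort(sprintf(
      "malformed cohort file %s: line %d, column %d (%s)",
      path, p$row + 1L, p$col, p$expected
    ))
  }
  df <- df[, cohort_columns]
  out <- validate_cohort(df, strict = strict)
  attr(out, "provenance") <- path
  out
}

#' Write a cohort to CSV
#'
#' Writes the canonical column order with empty cells for missing values and
#' lowercase `true`/`false` booleans, so that `read_cohort(write_cohort(x))`
#' reproduces every field value, missingness pattern and record order.
#'
#' @param cohort A cohort tibble (validated; see [validate_cohort()]).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort, strict = TRUE)
  out <- dplyr::mutate(
    cohort,
    dplyr::across(dplyr::where(is.logical), ~ ifelse(is.na(.x), NA_character_, ifelse(.x, "true", "false")))
  )
  readr::write_csv(out[, cohort_columns], path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a cohort against the participant-record invariants
#'
#' Checks: unique non-missing ids; age within the 18--75 inclusion range;
#' `sex` in `male`/`female`; UENS an integer in 0--42; MNSI non-negative;
#' amplitudes non-negative; `dm_duration` non-negative and absent (or 0) when
#' `has_dm` is false. Validation is total: every record is either accepted or
#' attributed to a specific named rule.
#'
#' @param cohort A data frame with the canonical columns.
#' @param strict If `TRUE`, abort on the first violated rule naming the
#'   offending ids; if `FALSE`, drop offending records with a warning.
#' @return The validated cohort as a tibble (offenders removed when
#'   `strict = FALSE`).
#' @export
validate_cohort <- function(cohort, strict = TRUE) {
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  df <- as_tibble(cohort)

  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    if (strict) abort(paste0("duplicate participant id: ", paste(unique(dup), collapse = ", ")))
    warn(paste0("dropping ", length(dup), " record(s) with duplicate id"))
    df <- df[!duplicated(df$id), ]
  }

  rules <- list(
    "missing id" = is.na(df$id) | df$id == "",
    "age outside [18, 75]" = is.na(df$age) | df$age < 18 | df$age > 75,
    "sex not male/female" = is.na(df$sex) | !df$sex %in% c("male", "female"),
    "has_dm missing" = is.na(df$has_dm),
    "uens outside [0, 42]" = !is.na(df$uens) & (df$uens < 0 | df$uens > 42),
    "mnsi negative" = !is.na(df$mnsi) & df$mnsi < 0,
    "dm_duration negative" = !is.na(df$dm_duration) & df$dm_duration < 0,
    "dm_duration present without diabetes" =
      !is.na(df$has_dm) & !df$has_dm & !is.na(df$dm_duration) & df$dm_duration > 0,
    "negative amplitude" =
      Reduce(`|`, lapply(df[amplitude_columns], function(x) !is.na(x) & x < 0))
  )

  bad <- rep(FALSE, nrow(df))
  for (rule in names(rules)) {
    hit <- rules[[rule]]
    if (any(hit)) {
      if (strict) {
        abort(paste0(
          "cohort validation failed: ", rule, " (id: ",
          paste(head(df$id[hit], 5L), collapse = ", "), ")"
        ))
      }
      bad <- bad | hit
    }
  }
  if (!strict && any(bad)) {
    warn(paste0("dropping ", sum(bad), " invalid record(s)"))
    df <- df[!bad, ]
  }
  df
}

# Enumerate violations without stopping; used by run_validate().
cohort_violations <- function(cohort) {
  df <- as_tibble(cohort)
  out <- list()
  dup <- unique(df$id[duplicated(df$id)])
  if (length(dup)) out[[length(out) + 1L]] <- tibble(id = dup, rule = "duplicate id")
  checks <- list(
    "missing id" = is.na(df$id) | df$id == "",
    "age outside [18, 75]" = is.na(df$age) | df$age < 18 | df$age > 75,
    "sex not male/female" = is.na(df$sex) | !df$sex %in% c("male", "female"),
    "has_dm missing" = is.na(df$has_dm),
    "uens outside [0, 42]" = !is.na(df$uens) & (df$uens < 0 | df$uens > 42),
    "mnsi negative" = !is.na(df$mnsi) & df$mnsi < 0,
    "dm_duration negative" = !is.na(df$dm_duration) & df$dm_duration < 0,
    "dm_duration present without diabetes" =
      !is.na(df$has_dm) & !df$has_dm & !is.na(df$dm_duration) & df$dm_duration > 0,
    "negative amplitude" =
      Reduce(`|`, lapply(df[amplitude_columns], function(x) !is.na(x) & x < 0))
  )
  for (rule in names(checks)) {
    hit <- checks[[rule]]
    if (any(hit)) out[[length(out) + 1L]] <- tibble(id = df$id[hit], rule = rule)
  }
  if (length(out)) dplyr::bind_rows(out) else tibble(id = character(), rule = character())
}
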