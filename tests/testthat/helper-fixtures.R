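# In-code fixtures: a minimal hand-built cohort and a participant-record
# builder. All larger fixtures come from generate_cohort().

make_record <- function(id = "p1", age = 50L, sex = "male", has_dm = FALSE,
                        dm_duration = NA_real_, uens = 0L, mnsi = 0,
                        burning_feet = FALSE,
                        sural_r = 12, sural_l = 11, sps_r = 8, sps_l = 7,
                        srs_r = 30, srs_l = 28) {
  tibble::tibble(
    id = id, age = age, sex = sex, has_dm = has_dm,
    dm_duration = dm_duration, uens = uens, mnsi = mnsi,
    burning_feet = burning_feet,
    sural_r = sural_r, sural_l = sural_l, sps_r = sps_r, sps_l = sps_l,
    srs_r = srs_r, srs_l = srs_l
  )
}

# Three-group toy cohort: one healthy control, one diabetic without
# neuropathy, one with clinical neuropathy (absent distal responses).
make_toy_cohort <- function() {
  dplyr::bind_rows(
    make_record("c1", age = 45, has_dm = FALSE, uens = 0L, mnsi = 1),
    make_record("d1", age = 55, sex = "female", has_dm = TRUE,
                dm_duration = 5, uens = 2L, mnsi = 3,
                sural_r = 10, sural_l = 9, sps_r = 6, sps_l = 5),
    make_record("n1", age = 62, has_dm = TRUE, dm_duration = 15, uens = 10L,
                mnsi = 11, burning_feet = TRUE,
                sural_r = 0, sural_l = 2, sps_r = 0, sps_l = 0,
                srs_r = 15, srs_l = 12)
  )
}

# Half-up rounding oracle used by reconstruct_counts tests: x (percent)
# rounds to target at `digits` iff it falls in [target - h, target + h)
# with h half of the printed resolution.
rounds_to <- function(x, target, digits = 1) {
  h <- 0.5 * 10^(-digits)
  x >= target - h & x < target + h
}

# Independent Clopper-Pearson oracle: invert the binomial tail CDF by
# bisection (no beta quantiles).
cp_oracle <- function(x, n, conf = 0.95) {
  a <- (1 - conf) / 2
  bisect <- function(f, lower, upper, tol = 1e-12) {
    for (i in 1:60) {
      mid <- (lower + upper) / 2
      if (f(mid) > 0) upper <- mid else lower <- mid
      if (upper - lower < tol) break
    }
    (lower + upper) / 2
  }
  lo <- if (x == 0) 0 else bisect(function(p) (1 - pbinom(x - 1, n, p)) - a, 0, 1)
  hi <- if (x == n) 1 else bisect(function(p) a - pbinom(x, n, p), 0, 1)
  c(lo = lo, hi = hi)
}

# Printed whole-cohort accuracy rows used as frozen expected values in the
# reproduction tests: percentages at 1 d.p., ROC areas at 3 d.p.
printed_accuracy_rows <- function() {
  tibble::tribble(
    ~test,       ~comparator,  ~roc,  ~sens, ~spec, ~ppv,  ~npv,
    "sural<5.1", "primary",    0.804, 68.4,  92.3,  86.7,  80.0,
    "sps<4.5",   "primary",    0.721, 86.0,  58.3,  62.0,  84.0,
    "cpnsi>=1",  "primary",    0.664, 91.2,  41.7,  55.3,  85.7,
    "cpnsi>=2",  "primary",    0.765, 80.7,  72.2,  69.7,  82.5,
    "cpnsi>=3",  "primary",    0.806, 66.7,  94.4,  90.5,  78.2,
    "cpnsi>=4",  "primary",    0.765, 54.4,  98.6,  96.9,  73.2,
    "sural<5.1", "cases_only", 0.775, 68.4,  86.5,  88.6,  64.0
  )
}
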