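---
title: "Methods: evaluating sensory-amplitude tests for diabetic neuropathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating sensory-amplitude tests for diabetic neuropathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapdx)
```

## The problem

Length-dependent peripheral neuropathy — most often caused by diabetes —
first attenuates the sensory nerve action potentials (SNAPs) of the distal
lower limb. `snapdx` evaluates how well low SNAP amplitudes identify
clinical diabetic neuropathy when neuropathy itself is defined by validated
bedside scales rather than by the conduction study: the Utah Early
Neuropathy Scale (UENS, 0–42 points) serves as the clinical reference
standard and the Michigan Neuropathy Screening Instrument (MNSI, combined
questionnaire + examination score) as a discordance flag.

Participants are assigned to three groups:

* **G1** — controls: no diabetes, UENS < 5;
* **G2** — diabetes without clinical neuropathy: UENS < 5, MNSI ≤ 7.5;
* **G3** — clinical diabetic neuropathy: diabetes with UENS ≥ 5.

Participants with diabetes whose UENS is below 5 but whose MNSI exceeds 7.5
are *scale-discordant*: their questionnaire suggests neuropathy the
examination scale does not. They are excluded from the primary analysis and
folded into G2 in a sensitivity variant (`include_discordant`). A second
sensitivity variant (`cases_only`) drops the controls so that the
non-diseased comparator is G2 alone. Non-diabetic participants with
UENS ≥ 5 fall outside the design and are labelled `ineligible`, never
silently pooled.

## Index tests

Four families of dichotomous tests are evaluated against the UENS
reference, each positive by a strict `<` comparison (a value equal to its
cutoff is negative):

* side-combined sural amplitude < 5.1 µV;
* side-combined superficial peroneal sensory (SPS) amplitude < 4.5 µV;
* sural-to-radial amplitude ratio (SRAR) < 0.2, the ratio of the
  side-combined sural and superficial radial amplitudes; the ratio is
  undefined when the radial response is absent;
* the **combined polyneuropathy sensory index (CPNSI**, also written
  CSPNI): one point per nerve potential below its 25%-lower-limit-of-normal
  cutoff — right and left sural < 8.5 µV, right and left SPS < 4.5 µV —
  giving 0–4 points, with the family of tests "CPNSI ≥ k", k = 1…4. The
  8.5/4.5 µV cutoffs are fixed constants of the score definition; they are
  not re-derived from the data.

An amplitude of 0 µV records an elicited-but-absent response and
participates in every statistic; an empty cell records a measurement that
was not performed and removes the participant from analyses that need it.
CPNSI requires all four potentials, so a participant missing any of them
drops out of CPNSI-based tables (listwise exclusion); this matters because
the evaluable denominators of the published tables differ by test.

Side combination defaults to the left/right arithmetic mean (the convention
stated for the normative ranges); because its use for the cutoff tests is
an assumption, `side_policy = "worst_side"` (the lower amplitude) is
available as a switch.

## Accuracy statistics

For each test, variant and age stratum the package builds the 2×2 table
over evaluable participants and reports:

* sensitivity, specificity, PPV and NPV, each with an **exact
  Clopper–Pearson interval** computed by beta-quantile inversion on its own
  numerator and denominator. The exact interval was chosen because the
  published bounds (e.g. 54.8–80.1% for 39/57, and a non-trivial lower
  bound for a 100% specificity) match the exact and not the Wald form; the
  source does not name its CI procedure, so this is an inference from
  numerical agreement.
* the **ROC area of the dichotomous test**, the trapezoid area of the
  two-point empirical ROC: (sensitivity + specificity)/2. Its interval is
  Wald-normal with the DeLong variance for a binary marker,
  `V = sens(1−sens)/(4(n₁−1)) + spec(1−spec)/(4(n₀−1))`, using
  (n−1) sample-variance denominators — again inferred from numerical
  agreement with the published bounds, which the n-denominator version does
  not reproduce — truncated to [0, 1], and undefined when either margin has
  fewer than two participants.

PPV and NPV are prevalence-dependent; the identities
`ppv = sens·π / (sens·π + (1−spec)(1−π))` (π the evaluable prevalence) hold
to machine precision and are enforced by tests.

Display rounding in rendered reports is half-up at the printed precision
(percentages 1 d.p., ROC areas 3 d.p.); internal computation is never
rounded. `reconstruct_counts()` inverts this rounding: given a group size
and a printed percentage it recovers the unique consistent integer count,
erroring when none or several exist. This makes published whole-cohort
rows exactly recomputable even though the underlying data are available
only on request.

Age strata partition the 18–75-year inclusion range into <40, 40–49,
50–59 and 60–75 years. Degenerate strata (no evaluable diseased or
non-diseased participants) raise a typed condition and are skipped with a
message by `accuracy_table()` rather than suppressed silently.

## Normative ranges

`range_table()` summarises side-combined amplitudes per group × age group
as median, quartiles and the 5th percentile (the "5% LLN" when the stratum
is a reference group). Quantiles interpolate linearly between order
statistics at position `p(n−1)+1` (`stats::quantile` type 7). The source's
software default for the 5th percentile at very small n may differ and is
not recoverable from the printed tables, so the rule is exposed as
`quantile_type`. Group comparisons delegate to the standard routines:
exact Mann–Whitney/Wilcoxon rank-sum, Fisher's exact test, and the
tie-corrected Kruskal–Wallis test.

## The synthetic cohort generator

The study's raw records are available only on direct request, so the
package carries a seeded generator whose defaults *are* the study
conditions: group sizes 41/37/57 plus 6 discordant; per-group age-group
mixes taken from the published counts (in ascending age order); sex and
burning-feet proportions and diabetes-duration quartiles per group; UENS
distributions respecting each group's defining inequality (controls and G2
concentrated at 0 with all mass below 5; neuropathy scores drawn as
5 + NegBin(size 0.8, mean 7.5), whose quartiles 6/10/16 match the
published 10 (6–16)); and MNSI models per group, with G2 capped at the 7.5
discordance threshold and discordant records floored just above it, so the
generated cohort reproduces the published group structure *exactly* under
the primary classification.

### Amplitude model

Each (group × age group × nerve) stratum is modelled as a **zero-inflated
two-piece log-normal**: a point mass at 0 µV (absent responses — visible in
the published tables as interquartile ranges touching zero) mixed with
`exp(µ + s·Z)`, `Z` standard normal, where the log-spread `s` takes one
value below the median and another above. The two-piece (split) form is
used because a printed (median, q25, q75) triplet has three degrees of
freedom while a single-σ log-normal has two: several published strata are
strongly log-asymmetric, and the split form matches all three quantiles
exactly, collapsing to the ordinary log-normal when `median² = q25·q75`.

Zero-containing triplets under-determine the zero mass π (any value in the
admissible interval reproduces the printed quantiles), so fixed
conventions are used: π = 1/3 when q25 = 0 < median (admissible interval
(0.25, 0.5)), and π = 0.6 with conditional log-spread 0.5 when the median
is 0 (admissible (0.5, 0.75)). Degenerate triplets — single-participant
strata print `x (x–x)` — receive a log-spread floor of 0.05 instead of an
error. Left and right sides are drawn independently by default; a
`side_correlation` knob shares a log-scale component between sides, since
the published tables carry no inter-side information.

### What the generator does and does not emulate

The models are fitted to the published *side-averaged* summaries but are
sampled per side, so side-averaged summaries of generated data are
slightly narrower than the targets under independent sides; calibration is
therefore assessed on the pooled per-side draws. Missingness defaults
(sural 0, SPS 0.05, radial 0.1 per nerve pair) emulate the evaluable
denominators implied by the published accuracy tables, not the study's
actual missingness pattern, which is unpublished. Correlation between
nerves within a participant, waveform-level features, temperature and
anthropometric covariates are not modelled. Consequently, passing
pipeline tests on synthetic cohorts demonstrates correctness of the
*computations* under realistic marginal distributions; it does not
validate the clinical accuracy estimates themselves, which are fixed by
the published 2×2 tables.

### Calibration checks and their limits

Model-level calibration is tight: Monte-Carlo draws from any fitted model
recover the fitted triplet within 2% at large n (2×10⁵ draws in the test
suite). Cohort-level calibration is checked on a cohort generated at ten
times the study group sizes (1410 records, fixed seed), comparing each
stratum's empirical median and quartiles against its target within 10%
relative tolerance, with a 0.5 µV absolute floor so zero-valued targets
are checkable. At study-proportional stratum sizes the sampling error of
an empirical quartile is comparable to this band for the wide strata —
some published triplets come from as few as 2–3 participants, giving
one-sided log-spreads near 2.7 — so a minority of the ~90 stratum checks
fall 1–1.5 standard errors outside it under any seed. The corresponding
test is kept at the stated tolerance and its residual failures are
documented rather than hidden; the model-level check above is the
discriminating one.

## Problem sizes and numerical choices

The test suite works at the study's own sizes (141 records; 1410 for the
scaled calibration cohort), 2×10⁵ draws for Monte-Carlo round-trips, 4000
replicates per grid point for empirical interval coverage at n = 57, and
exhaustive oracle comparison of the exact interval for every (x, n) with
n ≤ 100 against a binomial-CDF bisection oracle at 10⁻⁹. Ties in rank
tests fall back to the usual corrected statistics; the exact rank-sum
p-value is verified against full permutation enumeration at n = 3 per arm.
All randomness flows through a single integer seed; identical spec and
seed give byte-identical cohort CSVs.

## Known limitations

* The CPNSI cutoffs (8.5/4.5 µV) are taken as given constants; the
  published reference quartiles do not reproduce their derivation.
* SRAR accuracy rows cannot be reconstructed exactly because their
  evaluable denominators were never printed; the SRAR machinery is fully
  implemented and exercised on synthetic cohorts instead.
* The 5% lower limits of normal printed for very small strata depend on an
  unstated percentile estimator and are not exactly recoverable under any
  single quantile rule.
* Published significance tests (Table-1-style p-values) are reproducible
  in machinery but not numerically, since the raw data are unavailable.
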