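---
title: "Comparing accelerometer cut-points for preschool physical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing accelerometer cut-points for preschool physical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelcut)
```

## The problem

Free-living physical activity in 3–5-year-olds is usually measured with a
hip-worn tri-axial accelerometer that aggregates filtered acceleration into
dimensionless *activity counts* per epoch. Short epochs (5 s here) are
preferred at this age because preschool activity is spontaneous and
intermittent: bouts of vigorous movement last seconds, not minutes.
Published *cut-points* — thresholds on the counts-per-minute (cpm) scale —
convert counts into time in sedentary behaviour (SB), light activity, and
moderate-to-vigorous activity (MVPA), and hence into compliance with the
≥ 60 min/day MVPA guideline. Because the available preschool calibration
studies (Pate, Butte, Johansson) used different criterion measures,
settings and samples, their thresholds differ several-fold, and the choice
of cut-point — and of signal axis (vertical vs vector magnitude) — can move
a cohort's "percent active" anywhere from 0 % to near 100 %. `accelcut`
implements the complete comparison pipeline, plus a synthetic cohort
generator so that every stage is testable against known ground truth.

## Pipeline and assumptions

`cutpoint_analysis()` is the single entry point. Its stages, each also
available as an exported function:

1. **Non-wear detection** (`detect_nonwear`): every maximal run of
   consecutive zero counts lasting ≥ 20 min is treated as the device being
   off. The threshold is inclusive ("20 or more"), the zero test uses the
   vertical axis (the axis all three vertical-axis cut-point sets are
   calibrated on; `axis = "all"` is available), and runs are evaluated
   within calendar days — a run crossing midnight is split at the boundary
   and each part judged on its own. We interpret the run length in
   *minutes* (240 five-second epochs), following the wear-time literature
   this rule descends from; a literal 20-*epoch* reading (100 s) would
   discard ordinary quiet sitting and is selectable for sensitivity
   analysis via `min_zero_run_minutes = 20/12`.
2. **Valid-day screening** (`valid_days`, `filter_children`): a day is valid
   with ≥ 10 h (600 min, inclusive) of wear after non-wear removal; a child
   is retained with ≥ 1 valid weekday and ≥ 1 valid weekend day. The source
   protocol states the 10-h rule but not a per-period day minimum; (1, 1)
   is our configurable default, chosen as the weakest rule that makes
   weekday and weekend summaries defined for every retained child. Days are
   calendar days in the recording's local clock; no sleep-window exclusion
   is applied.
3. **Classification** (`classify_series`): cpm thresholds are rescaled to
   the analysis epoch by `epoch_len_s / 60` and compared by
   cross-multiplication (`count × 60 < threshold × epoch_len_s`), i.e.
   exact rational arithmetic — at 5 s the Pate sedentary bound is 800/12
   counts per epoch, and no rounding ever shifts a boundary epoch. The
   boundary convention mirrors the published inequalities: sedentary
   strictly below the SB bound, MVPA at or above the MVPA bound, light in
   the half-open band between. Moderate and vigorous are not separated
   (the sets publish no internal boundary).
4. **Aggregation** (`day_summary`, `period_summary`): minutes per intensity
   are exact epoch counts × epoch/60, so `sb + light + mvpa = wear` holds
   identically. Period means (weekday = Mon–Fri, weekend = Sat–Sun,
   total = all valid days, not the mean of the two period means) are
   unweighted over valid days. A child is *active* in a period when the
   **mean** daily MVPA is ≥ 60 min (inclusive at exactly 60.0). A
   mean-based rule — rather than "every day ≥ 60 min" — is the only reading
   under which the same child can coherently be active on weekdays and
   inactive at the weekend, as the guideline-compliance tables require.
5. **Description and agreement** (`cohort_tables`, `agreement_matrix`):
   mean ± t-based 95 % CI per sex × period × set; counts/percent active
   with a Pearson chi-square sex comparison *without* continuity
   correction (the uncorrected statistic is what reproduces printed
   p-values of this table family at 3 decimals; with Yates' correction it
   does not); percent agreement and Cohen's kappa with the standard
   qualitative bands.

Because the vertical-axis thresholds are strictly ordered
(SB: 239 < 580 < 800; MVPA: 1680 < 2120 < 3480), identical input data force
`mvpa(pate) ≥ mvpa(butte) ≥ mvpa(johansson)` and a nesting of the active
sets (active-under-Butte ⇒ active-under-Pate). These orderings survive
aggregation and appear in the pate–butte crosstab as an empty
first-inactive/second-active cell; the test suite asserts them across
simulated cohorts.

## Agreement statistics and 2×2 reconstruction

For two active/inactive labelings with cell counts `a, b, c, d`
(`n = a+b+c+d`), percent agreement is `100(a+d)/n` and Cohen's kappa
`(p_o − p_e)/(1 − p_e)` with `p_o = (a+d)/n`,
`p_e = ((a+b)(a+c) + (c+d)(b+d))/n²`. Two degenerate conventions matter in
this application, where one cut-point set routinely classifies *every*
child inactive:

* a constant classifier forces `p_o = p_e`, so kappa is computed as exactly
  0 (never a 0/0 floating artefact);
* if all mass sits in one cell, `p_e = 1`; kappa is 1 when observed
  agreement is also perfect, else 0, with a warning.

Published reports often print only each classifier's active totals and the
raw agreement. `reconstruct_2x2()` rebuilds the full table: with agreement
count `A = round(pct·n/100)`, `a = (first + second + A − n)/2`, remaining
cells from the marginals; a brute-force scan over all feasible `a` verifies
existence and uniqueness (the solution is algebraically unique whenever it
exists, and round-trips any table — the suite checks this exhaustively for
all tables with n ≤ 12). Kappa is *reported truncated* (not rounded) to 3
decimals via `truncate3()`: reconstructed values such as 0.2656/0.3679/0.4718
match their printed counterparts 0.265/0.367/0.471 only under truncation.
One printed agreement (82.42 % of 74) is not expressible as an integer
count (61/74 = 82.43 %); the nearest-integer rule absorbs it.

The a-priori sample size for a two-sided paired t-test
(`paired_t_sample_size`) searches the smallest n whose power — computed
from the noncentral t distribution with df = n − 1 and noncentrality
`dz·√n`, rejecting at `t(1 − α/2, n − 1)` — reaches the target; at
dz = 0.5, α = 0.05, power 0.95 it returns n = 54 with critical t ≈ 2.006.
Similarity letters for the three cut-point means use all pairwise paired
t-tests with Bonferroni multiplication (×3, capped at 1) and join sets
connected by non-significant differences (connected components — the
compact-letter-display convention), lettered in descending-mean order. The
omnibus repeated-measures model with sphericity correction is deliberately
out of scope; only the descriptive means/CIs and the pairwise procedure are
provided.

## The synthetic cohort generator

Raw preschool cohorts are rarely shareable, so `simulate_cohort()` provides
the test bed. Activity is a semi-Markov sequence over four states:
sleep/non-wear (21:00–07:00, exact zeros on all axes), and — during the
waking window — sedentary, light and MVPA bouts with exponential dwell
times truncated to whole epochs (means 5, 2 and 1.2 min: short, frequent
bouts). Per-epoch counts are gamma draws scaled to each state's cpm band
(sedentary 150 cpm with 35 % zero-inflation, light 1050 cpm, MVPA
2650 cpm, shape 1.5: non-negative and right-skewed like device counts).
Bout selection is modulated by a sinusoidal diurnal profile (MVPA peaking
mid-afternoon), a `sex_effect` multiplier on the MVPA bout rate for boys
(default 1.15), and a `weekend_effect` multiplier on sedentary dwell time
(default 1.2). One day in four contains an additional daytime non-wear run
of 25–60 min. The vector magnitude is synthesised as
`vertical × vm_ratio × lognormal noise` (vm_ratio 2.2, the approximate
published ratio of cohort-mean VM to vertical cpm, sdlog 0.15), floored at
the vertical count and decomposed into two integer horizontal axes, so the
stored vm is always the true Euclidean norm and `vm ≥ vertical` holds per
construction. Recordings start on a Monday by default (configurable), so a
7-day protocol splits deterministically into 5 weekdays + 2 weekend days.

Each child's stream is seeded from `(seed, child_index)`, making children
individually reproducible and the whole cohort bit-identical under an
identical configuration; simulation never disturbs the caller's RNG state.
Sex is drawn per child at `prop_male` (default 74/134) and age uniformly
in [3, 5].

The defaults are calibrated so the cohort-mean vertical-axis cpm over worn
time sits near 535 cpm, the magnitude reported for hip-worn preschool
recordings; across 12 seeds of 15-child/7-day cohorts the per-seed means
ranged 515–546 cpm. That anchor, the VM ratio, and the qualitative
orderings (most children active under Pate, none under Johansson, more
sedentary time at weekends, boys slightly more active) are the only
features tied to published numbers. No distributional information about
real counts is published, so the state parameters are free choices; the
generator makes no attempt to reproduce any published mean minutes table,
and passing tests demonstrate correctness of the *pipeline*, not realism
of autocorrelation structure, weather/season effects, or device artefacts
(spikes, low-frequency extension), which it does not emulate.

## Numerical and testing choices

* Counts are integers; thresholds are exact rationals; minute totals are
  exact multiples of `epoch_len_s/60`; boundary tests in the suite sit
  directly on the published inequalities (799/800/1680 at 60 s, 66/67 and
  139/140 counts per 5-s epoch).
* Timestamps are epoch-start, half-open `[t, t + epoch)`, UTC-parsed; day
  assignment at midnight is therefore unambiguous.
* Monte-Carlo suites run at deliberately small problem sizes — e.g. 20
  seeds × 6 children × 3 days for the cpm anchor (a ± 15 % band), 20
  two-child cohorts for the ordering/nesting invariants, 10 seeds for
  bout-rate monotonicity — sizes at which each property is already stable,
  keeping the whole suite around a minute.
* The noncentral-t power routine is cross-checked against an independent
  Monte-Carlo of simulated paired t-tests at n = 34 (nominal power 0.80).

## Known limitations

* Only the text CSV epoch dialect is read; binary ActiGraph formats (AGD,
  GT3X) and ActiLife filter emulation are out of scope.
* Kappa is reported without a standard error or significance test (the
  table family this reproduces prints stars without stating a method).
* Anthropometry (BMI categorisation) and intra-class correlation are not
  implemented; the former needs external age/sex reference tables.
* The generator's weekday/weekend and sex contrasts are directional, not
  magnitude-calibrated; do not use it to benchmark effect-size recovery.
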