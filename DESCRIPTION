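Package: accelcut
Title: Accelerometer Cut-Point Comparison for Preschooler Physical Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes epoch-level accelerometer activity counts from young
    children: non-wear detection by consecutive-zero runs, valid-day screening,
    intensity classification (sedentary / light / moderate-to-vigorous) under
    the published Pate, Butte and Johansson cut-point sets on the vertical axis
    and vector magnitude, daily and period summaries, >=60 min/day MVPA
    guideline compliance, and inter-cut-point agreement (percent agreement,
    Cohen's kappa with qualitative banding, and exact reconstruction of 2x2
    tables from published marginals). Includes a seed-reproducible synthetic
    cohort generator of week-long tri-axial recordings with diurnal structure,
    intermittent activity bouts and non-wear runs, plus the auxiliary
    statistics used in cut-point comparison studies (chi-square sex
    comparisons, a-priori paired-t sample size from the noncentral t
    distribution, Bonferroni-corrected pairwise comparisons with compact
    letter display).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
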