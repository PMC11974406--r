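# densitraj

Longitudinal consistency analysis for paired BI-RADS breast-density
assessments.

## The problem

Mammographic breast density is reported on the ordinal BI-RADS scale —
a (almost entirely fatty), b (scattered fibroglandular), c (heterogeneously
dense), d (extremely dense) — and drives supplemental-screening and risk
decisions. True density changes slowly: over a ~5-year screening window a
woman's category should mostly stay constant or drift down slightly. When a
woman's recorded density goes **up and then down** (or down and then up)
across consecutive screens, that *bi-directional* trajectory is far more
likely to reflect assessment variability (different radiologists, or the
same radiologist on a different day) than biology.

`densitraj` operationalises this idea for cohorts where every examination
carries two paired assessments — an AI density model and the interpreting
radiologist. For each woman with ≥ 3 exams it classifies the ordered
density sequence of each rater into one of four longitudinal patterns using
the signs of consecutive-pair differences \(d_i = \mathrm{sign}(x_{i+1} - x_i)\):

| pattern | definition |
|---|---|
| constant | no \(d_i \neq 0\) |
| ascending | some \(d_i > 0\), none \(< 0\) |
| descending | some \(d_i < 0\), none \(> 0\) |
| bi-directional | both signs present |

in both the 4-category and the binary (non-dense {a,b} vs dense {c,d})
context. Rater differences in the frequency of a pattern are tested with
the McNemar paired-proportion test on per-woman indicators (exact binomial
\(p = \min(1,\, 2\,P[X \le \min(b,c)]\), \(X \sim \mathrm{Bin}(b{+}c, \tfrac12)\))
for few discordant pairs, continuity-corrected chi-square otherwise), and
exam-level category distributions are compared with the Stuart–Maxwell
marginal-homogeneity test \(d^\top V^- d \sim \chi^2_{k-1}\). The analysis is
repeated in four overlapping subgroups that suppress specific nuisance
sources: post-menopausal women (first-exam age > 55), stable image-based
BMI (< 5% change between consecutive exams, with an OLS image-feature BMI
proxy for missing BMI), same radiologist throughout, and fellowship-trained
radiologists throughout.

Because screening cohorts of this kind cannot be shared, the package also
ships a seeded synthetic-cohort generator: each woman carries a latent
continuous density with a small negative annual drift and a BMI coupling;
thresholds cut the latent scale into the four categories; the radiologist
observes the latent value with a per-reader bias plus per-exam noise, the
AI with smaller noise and no bias. Every stage of the pipeline runs on its
output.

## Worked example

```r
library(densitraj)

cohort <- simulate_cohort(sim_config(n_women = 5000, seed = 1))
compare_pattern_proportions(cohort, "four_category", "constant")
#> # A tibble: 1 × 13
#>   trait    context           n  ai_n reader_n ai_pct reader_pct diff_pp     b     c statistic p_value method
#>   <chr>    <chr>         <int> <int>    <int>  <dbl>      <dbl>   <dbl> <int> <int>     <dbl>   <dbl> <chr>
#> 1 constant four_category  5000  4066     2892   81.3       57.8    23.5  1356   182      895.       0 chi2_cc
```

The AI labels 81.3% of women `constant` against the radiologists' 57.8% — a
23.5-percentage-point gap carried by the discordant pairs (`b` = 1356 women
constant under the AI only, `c` = 182 the reverse), overwhelmingly
significant under McNemar. The same call with `trait = "bi-directional"`
shows the mirror image (the AI produces ~11 points fewer bi-directional
patterns). `run_density_analysis(cohort)` repeats this for every subgroup,
context and trait and returns tidy tibbles; `write_report_bundle()` writes
the CSV/JSON report, and `plot_pattern_proportions()` /
`plot_paired_patterns()` / `plot_transitions()` draw the standard figures.

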