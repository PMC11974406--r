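---
title: "Longitudinal consistency of paired breast-density assessments: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal consistency of paired breast-density assessments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(densitraj)
```

## The question and the model

BI-RADS breast density is an ordinal, four-level assessment (a < b < c < d)
made at every screening mammogram. Over a five-year window, true
fibroglandular density changes slowly and, if anything, declines — so a
woman's sequence of assessments should mostly be constant, occasionally
monotone. A sequence that both rises and falls ("bi-directional") is a
signature of assessment variability rather than biology. Comparing how
often two paired raters — an AI model and the interpreting radiologists,
both assessing the *same* examinations — produce constant versus
bi-directional trajectories is therefore a direct, clinically interpretable
measure of longitudinal consistency.

`classify_pattern()` reduces a sequence of length ≥ 3 to one of four labels
from the signs of consecutive-pair differences. Two edge semantics are
deliberate and worth stating:

* **"constant" means literally all equal.** The four labels must partition
  all sequences; any looser reading of constant ("mostly unchanged") would
  need an arbitrary tolerance.
* **Plateaus do not break a monotone run** (b, b, c is ascending): only an
  actual sign change creates bi-directionality. Consecutive-pair
  differences, not a first-versus-last comparison, are used because
  bi-directionality is invisible to the endpoints.

Binary (non-dense {a, b} vs dense {c, d}) patterns are computed on the
binarized sequence itself, not by collapsing the 4-category label: the two
contexts are separate analyses, and binarization can only merge changes,
never create them (an ascending 4-category sequence is constant or
ascending in binary — a property the test suite checks exhaustively).

## Paired testing

Per-woman pattern indicators are compared with the McNemar test, which uses
only discordant pairs: `b` women carry the trait under the AI only, `c`
under the radiologist only. The exact two-sided binomial version is the
default below 25 discordant pairs, the continuity-corrected chi-square
above (the conventional switch point); both are available explicitly, since
different statistical stacks default differently and the choice is
immaterial at cohort scale. With no discordant pairs the p-value is 1 by
convention.

Exam-level category distributions of the two raters are paired, so their
equality is tested with the Stuart–Maxwell marginal-homogeneity statistic
(quadratic form in the first k−1 marginal differences, chi-square on k−1
df) rather than an unpaired chi-square. The implementation uses a
Moore–Penrose inverse: a perfectly concordant table has a singular
covariance but zero marginal differences and correctly reports statistic 0,
p = 1, while tables whose marginal differences fall outside the covariance
range raise an explicit singular-covariance error rather than returning
NaN. For k = 2 the statistic reduces to the McNemar chi-square without
continuity correction, which the tests verify to 1e-12.

Reported percentages are rounded to one decimal, and headline differences
are **differences of the rounded percentages** — the arithmetic that
reporting conventions actually produce (81.0 − 56.8 = 24.2 even when the
unrounded difference is 24.3). Raw proportions are retained at full
precision in the JSON output. No multiplicity correction is applied across
traits, contexts and subgroups, matching standard practice for this kind of
descriptive comparison; at the sample sizes involved it would change
nothing.

## Subgroups

Four overlapping woman-level filters re-run the whole analysis under
conditions that suppress one nuisance source each: first-exam age strictly
over 55 (menopause proxy), BMI change below 5% between **every pair of
consecutive exams** (the stricter reading of "stable", rather than
first-versus-last), all exams read by one radiologist, and all exams read
by fellowship-trained radiologists. The "all exams" requirement in the last
two is an assumption: a longitudinal pattern is only attributable to a
condition if the entire sequence was produced under it. Filters drop whole
women, are idempotent, and commute.

Where measured BMI is missing, an image-based proxy — OLS of BMI on
compressed breast thickness (mm) and breast-fat fraction, predictions
clamped to (10, 80) kg/m² — can fill it before the stable-BMI filter. The
proxy's coefficients load from JSON so a differently calibrated estimator
can be substituted without code changes; the default linear form is the
package's own choice of a minimal, monotone, auditable estimator.

## The synthetic cohort generator

`simulate_cohort()` emulates the statistical structure of a multi-site
screening cohort; it is the package's test bed and demonstration data, and
its defaults *are* the study conditions:

| parameter | default | source of the value |
|---|---|---|
| `n_women` | 61 177 | cohort size of the motivating study |
| `exam_count_probs` | 0.607/0.288/0.0525/0.0525 | reported 3/4/"5 or 6" mix; the 5-vs-6 split is even because nothing constrains it |
| `age_mean`, `age_sd` | 55.6, 10.3 yr (truncated 35–90) | reported cohort characteristics |
| `bmi_mean`, `bmi_sd` | 28.3, 4.9 kg/m² (truncated 15–60) | reported cohort characteristics |
| `target_marginal` | 9.0/45.1/38.1/7.7 % | radiologists' reported category distribution |
| `annual_drift` | −0.02 latent units/yr | small negative, reflecting the slow density decline reported over 5-year windows; magnitude is a free choice |
| `bmi_coupling` | −0.05 latent units per kg/m² | weight gain dilutes relative fibroglandular density; magnitude is a free choice |
| `reader_noise_sd` / `ai_noise_sd` | 0.32 / 0.15 latent units | calibrated once so the full-cohort constant fractions land near the reported ~57% (radiologists) and ~81% (AI); the ordering (radiologist noisier) is the study's central premise |
| `reader_bias_sd` | 0.15 | between-reader systematic differences, literature-plausible |
| `reader_persistence` | 0.65 | yields ~35% of women with a single reader, matching the reported same-radiologist subgroup size |
| `fellowship_prob` | 0.36 | reported fraction of fellowship-trained radiologists |

Each woman's latent density starts standard normal and evolves as
\(z_{t+1} = z_t + \mathrm{drift}\cdot\Delta t + \mathrm{coupling}\cdot\Delta BMI\).
Noise acts in latent space (shift, then threshold), which guarantees
ordinal, adjacent-category-heavy misclassification — how density
disagreements actually behave — instead of an arbitrary confusion matrix.
Thresholds are calibrated as Monte-Carlo quantiles of the
*radiologist-observed* latent values against the target marginals, so the
realized radiologist marginals match the targets by construction and the
AI marginals deviate exactly the way its lower noise makes them deviate
(fewer extreme categories) — mirroring the direction of the reported
AI-vs-radiologist marginal differences. The generator returns a truth
sidecar (latent values and true categories) used by the recovery tests.

What the generator does **not** emulate: real between-site heterogeneity,
acquisition-format effects (DM vs SM vs DBT), non-annual visit spacing,
menopause as anything richer than the age proxy, and any dependence of
noise on the latent value itself. Passing tests on simulated cohorts
therefore demonstrate the pipeline's correctness and the qualitative
mechanism (noisier rater ⇒ fewer constant, more bi-directional patterns),
not quantitative agreement of any particular clinical dataset.

## Numerical and design choices

* Densities are stored as integer codes 0–3 internally; labels only at I/O
  boundaries.
* Exams are ordered by date; same-date duplicates within a woman are
  invalid input (screening exams are annual; the correct handling of
  technical recalls is unknowable from a table) and are dropped-and-tallied
  in lenient mode, fatal in strict mode.
* Cohort loading tallies every exclusion (malformed rows by reason, women
  with < 3 valid exams) so that included women plus exclusions always
  reconcile with the input — the provenance attribute and JSON sidecar
  carry the tallies.
* Exact-test p-values are capped at 1; degenerate McNemar inputs
  (b = c = 0) return statistic 0, p = 1.
* Threshold calibration refuses zero-probability categories and
  non-increasing quantiles instead of silently producing empty categories.
* Reproducibility: the simulator restores the caller's RNG state, and a
  config (including its seed) determines the cohort byte-for-byte.

## Problem sizes used by the tests

The test suite and the acceptance script run the cohort pipeline at 120–
5 000 women, the calibration and recovery checks at 15 000–20 000 women,
and the null-size check at 2 000 replicates of 200 women — sizes at which
every Monte-Carlo property checked has comfortable margin while the whole
suite stays quick to run. These are the package's chosen demonstration
scales; all functions are vectorised and run the full 61 177-woman default
in well under a minute.

## Known limitations

* The four-pattern taxonomy is length-agnostic but blind to timing: a
  category change at exam 2 of 6 and at exam 5 of 6 are the same pattern.
* First-to-last transition tables ignore intermediate exams by design.
* The BMI proxy is a stand-in estimator, not a validated clinical model;
  its role is confined to the stable-BMI subgroup gate.
* The McNemar/Stuart–Maxwell machinery treats women (and exams) as
  independent; repeated exams of one woman enter the marginal-homogeneity
  test as separate pairs, which is how the corresponding published
  comparison is framed but overstates the effective sample size for
  inference at the exam level.
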