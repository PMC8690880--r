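---
title: "Indirect reference intervals for T-lymphocyte subsets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect reference intervals for T-lymphocyte subsets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcellri)
```

## The problem

Reference intervals — the central 95% range of an analyte in healthy
people — are the yardstick against which individual laboratory results are
judged. Recruiting a dedicated healthy cohort (the *direct* method) is
expensive, so the *indirect* method instead mines the laboratory
information system (LIS) of a hospital's routine checkup population and
relies on statistical cleanup to approximate a healthy reference
distribution. `tcellri` implements such a pipeline for the six
T-lymphocyte subset measurands of clinical flow cytometry: CD3+, CD3+CD4+
and CD3+CD8+ T cells, each as a percentage of lymphocytes and as an
absolute count in cells/µl (single-platform bead counting).

The pipeline has four statistical stages, each exposed as ordinary
functions and chained by `run_pipeline()`:

1. **Deduplication and stratification** (`deduplicate()`,
   `assign_stratum()`). One record per individual, keyed by
   (`subject_id`, `name_key`, `age`); closed integer age bands 14–30,
   31–45, 46–60, 61–75, 76–100 crossed with sex.
2. **Normality assessment and Box-Cox normalization**
   (`assess_normality()`, `fit_boxcox_mle()`). Skewness and excess
   kurtosis are standardized by their exact small-sample standard errors
   and compared against 1.96; non-normal analytes are transformed by
   $y = (x^\lambda - 1)/\lambda$ ($\lambda \neq 0$; $\ln x$ at
   $\lambda = 0$) with $\lambda$ maximizing the profile log-likelihood
   $L(\lambda) = -\tfrac{n}{2}\log\hat\sigma^2(\lambda) +
   (\lambda - 1)\sum\log x_i$.
3. **Outlier elimination** (`tukey_fences()`, `screen_analyte()`). A
   single pass of Tukey's inner fences ($Q_1 - 1.5\,\mathrm{IQR}$,
   $Q_3 + 1.5\,\mathrm{IQR}$, type-7 quartiles) on the transformed scale,
   one global round per analyte.
4. **Partitioning and estimation** (`harris_boyd()`,
   `partition_scan()`, `nonparametric_ri()`). The Harris–Boyd
   standard-normal-deviate test, in its CLSI EP28-A3C form
   $z^* = 3\sqrt{\bar n/120}$, decides whether sexes and adjacent age
   bands need separate intervals; limits are the 2.5th and 97.5th
   percentiles by the $(n+1)$-rank method with interpolation.

`validate_ri()` and `verify_reference_intervals()` implement external
verification (an interval passes when strictly fewer than 5% of an
independent healthy cohort falls outside), `compare_ri_sets()` contrasts
two candidate interval sets on one validation cohort by a pooled 2×2
chi-square (Fisher below expected counts of 5), and `age_trend()` /
`extreme_decline()` quantify immunosenescence.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `z_crit` | 1.96 | SE multiples for the skew/kurtosis normality rule |
| `lambda_range` | [−3, 3] | Box-Cox search interval; fitted to 1e−5 |
| `k` | 1.5 | Tukey fence multiplier (inner fences) |
| `sd_ratio_limit` | 1.5 | secondary Harris–Boyd SD-ratio trigger |
| `coverage` | 0.95 | central coverage of the interval |
| `min_n` / `warn_n` | 20 / 120 | hard / CLSI-recommended stratum minimum |
| verification threshold | 0.05 | strict: exactly 5% outside fails |

All are echoed into the run manifest so a report can be reproduced from
its own output directory.

## The decline conventions

The extreme-age decline (`extreme_decline()`) deliberately uses two
conventions. Percentage analytes are already on a percent scale, and their
decline is reported in absolute percentage points
(e.g. 70.05 − 60.10 = 9.95). Absolute counts decline relatively:
$100\,(m_{14\text{–}30} - m_{76\text{–}100})/m_{14\text{–}30}$
(e.g. (1309 − 910)/1309 = 30.48%). Published T-subset decline figures mix
exactly these two conventions while printing both with a percent sign;
the package makes the distinction explicit in code and documentation
because the two numbers are not comparable.

## The synthetic cohort generator

No suitable LIS extract is publicly available, so every downstream stage
is validated against `generate_cohort()`, whose law is chosen to make the
pipeline's own assumptions *exactly* true on clean data:

* Each analyte within each sex follows an **inverse-Box-Cox Gaussian**
  with a linear age trend on the transformed scale:
  $y \sim N(\mu + \beta\,(\text{age} - 14), \sigma)$,
  $x = (\lambda y + 1)^{1/\lambda}$. Box-Cox normalization is then the
  correct transform and $\lambda$ recovery is a well-posed test.
* Defaults (`default_stratum_models()`) are anchored to published adult
  immunophenotyping values: the analyte-specific exponents (0.068–2.45),
  young-band medians and central-95% limits, and old-band medians, from
  which $(\mu, \beta, \sigma)$ are derived by matching the band mid-ages
  22 and 88. Default stratum sizes mirror a large checkup census
  (the 46–60 band dominates; 76–100 is thin), with a 35.6% duplicate
  share and 1% contamination at 3× spread as the routine noise level.
* Ages are uniform integers within the band. Values are drawn by the
  inverse-CDF of the **truncated** normal on the valid range
  (percentages in [0, 100], counts ≥ 0 and within the Box-Cox domain) —
  identical in law to rejection sampling, with no point masses at the
  edges. The model constructor refuses parameter sets whose truncated
  mass exceeds 2% at any age, so truncation stays a tail nuisance.
* The three counts share one standard-normal latent per record
  (comonotone coupling), jointly truncated so that
  `cd4_count + cd8_count <= cd3_count` always holds. This keeps each
  count's marginal an exact truncated inverse-Box-Cox Gaussian — so
  `true_reference_interval()` and `cohort_truth()` integrate the *same*
  truncated law the generator samples, and the oracle is exact rather
  than approximate. The alternative (drawing CD3 and splitting it by a
  share model) enforces the same constraint but destroys the closed-form
  marginals of the CD4/CD8 counts, which would leave the end-to-end
  recovery tests without an exact target. The cost is perfect rank
  correlation among the three counts; no analysis stage uses
  cross-analyte correlation, and no richer dependence structure is
  claimed.
* Every random stream is derived deterministically from the master seed
  and a (stratum, analyte) path, so adding a stratum does not perturb the
  draws of another, and identical specs yield byte-identical cohorts.

What the generator does **not** emulate: non-uniform age densities within
bands, seasonal or analyzer drift, correlated percentage/count errors,
departures from the Box-Cox family, and duplicate visits with re-measured
values (duplicates repeat the first visit's values with a later date).
Passing tests therefore show the pipeline is correct *when its own
modelling assumptions hold*; they do not certify behaviour on real LIS
data, whose deviations from those assumptions are unknowable without the
data.

## Numerical choices

* Quartiles and percentile interpolation use the type-7 convention;
  reference limits use the $(n+1)$-rank convention with clamping to
  $[1, n]$. Alternative rank conventions move a limit by at most one
  order statistic, which is one reason published interval decimals are
  not bit-reproducible even in principle.
* Box-Cox fitting: 0.1-spaced coarse grid, then golden-section
  refinement; boundary optima snap to the boundary. $|\lambda| <$ 1e−12
  is treated as the log case.
* Tukey flagging is strict (`<` lower fence, `>` upper); boundary values
  are retained, matching the interval convention that boundary values are
  inside.
* Zero or negative analyte values error rather than being silently
  shifted; these measurands are positive, and a shift would change
  $\lambda$'s meaning.
* Degenerate inputs (zero variance, thin strata, missing strata) error
  or warn early with the offending group named; strata below 20 retained
  values are omitted from estimation, below 120 estimated with a warning.
* Deduplication keeps the earliest visit per key (first presentation),
  configurable to latest; ties break by file order, making the operation
  deterministic and idempotent.

## Design choices on genuinely open points

* **Normality rule**: "skewness and kurtosis below 1.96 standard
  deviations" is implemented as the standardized $z = G/SE$ form with the
  exact small-sample SEs; at LIS scale the $\sqrt{6/n}$, $\sqrt{24/n}$
  approximations agree to well under 1%.
* **One λ per analyte, fitted on the pooled deduplicated cohort**, then
  one global Tukey round — normalization precedes elimination, since
  fences assume rough symmetry. Screening on the transformed scale equals
  screening the raw values against back-transformed fences (monotone
  map); tests assert that equivalence.
* **Partition comparisons**: male vs female within band, and adjacent
  bands within sex (ordered bands make adjacent contrasts the meaningful
  ones); all-pairs mode is available. The SD-ratio criterion is reported
  separately so the mean-based decision is auditable alone.
* **Estimation on the original scale**: rank limits commute with the
  monotone transform up to interpolation, and back-transforming ranks
  avoids compounding rounding.
* **Correlation flavor**: Spearman by default, consistent with the
  rank-based testing used throughout; Pearson by option.

## Known limitations

* **Global single-pass screening clips extreme strata.** The fences are
  computed on the pooled sex-and-age mixture. When stratum effects are
  strong — the default models place the oldest band's mean about 1.5
  within-stratum SDs below the youngest's — roughly 1–1.5% of the 76–100
  band's lower tail lies outside the pooled fences and is eliminated,
  biasing that band's lower reference limit upward by up to ~10%
  relative. The package's end-to-end recovery test measures exactly this:
  limits in central strata recover to well within 3% relative of the
  generator's exact quantiles, while extreme-band lower limits do not.
  Per-stratum screening would remove the bias but is deliberately not
  performed, because the implemented design mirrors the global
  one-round-per-analyte elimination that indirect LIS studies report.
  Users comparing very unequal strata should treat extreme-band lower
  limits as conservative (too high).
* With $\lambda \approx 2.45$ (the CD3+ percentage), the observed-scale
  distribution is strongly left-skewed and the lower-limit estimator is
  noisy: its relative sampling SE is ~2% even at 5,000 per stratum, so
  single-run decimals should not be over-read.
* The verification rule is a point rule on one rate; at true coverage
  exactly 95% the strict <5% rule fails about half of honest validation
  cohorts, which is inherent to the rule, not to the estimate.
* Problem sizes in the test-suite simulations (up to 5,000 per stratum
  end-to-end, 20,000 for single-stratum calibration, 200 replicates for
  coverage) were chosen as the smallest sizes at which the binomial and
  rank-statistic theory quoted in each test has converged.
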