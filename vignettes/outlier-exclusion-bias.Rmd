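---
title: "How outlier exclusion biases response-time comparisons: the simulation model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How outlier exclusion biases response-time comparisons: the simulation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rtexclusion asks a practical question of mental-chronometry data analysis:
when you drop "outlier" response times (RTs) before a two-sample test, how
much does the exclusion rule itself change your conclusions? The package
answers it by Monte-Carlo simulation, where — unlike in empirical data — the
uncontaminated truth is known.

```{r setup}
library(rtexclusion)
```

## The generative model

**Valid RTs.** Each simulated condition draws its RTs from an Ex-Gaussian
distribution, the standard model for right-skewed RT data: the sum of a
Normal(mu, sigma) and an Exponential with mean tau, all in milliseconds. Its
mean is mu + tau, its variance sigma^2 + tau^2, and its skewness
2 tau^3 / (sigma^2 + tau^2)^(3/2).

One *iteration* simulates a pair of conditions sharing a trial number N and
the parameters sigma and tau, differing only by a population shift `diff`
added to mu in condition 2. Population parameters vary across iterations:

| parameter | law | unit |
|---|---|---|
| N | integer uniform on 20..100 | trials |
| mu | U(250, 500) | ms |
| sigma | U(20, 50) | ms |
| tau | U(150, 200) | ms |
| diff | grid 0..100 in 1 ms steps | ms |

These ranges span typical RT experiments; because they are drawn anew per
iteration rather than crossed factorially, aggregate results generalise over
the parameter ranges instead of conditioning on a few parameter cells. N is
drawn as an integer (trial counts are integers); mu, sigma and tau are
continuous. The full design runs 5000 pairs per difference level, i.e.
101 x 5000 pairs per contamination approach.

**Outliers.** Each pair draws an outlier count round(u), u ~ U(0, 0.1 N) —
samples with more than 10% outliers are taken to be beyond rescue and out of
scope — and a long-outlier share p ~ Beta(5, 1) (mean 5/6; fast outliers are
physiologically squeezed against the ~100 ms floor, slow ones are not).
Counts are fixed across the two conditions of a pair; the replaced positions
and outlier values are drawn independently per condition. Replacement keeps
the sample size constant. Two generative schemes are implemented:

* **tails** — long outliers uniform on (max(valid), max(valid) + 2000 ms),
  short outliers uniform on (100 ms, min(valid)); outliers are strictly
  outside the valid range, the "detectable by definition" case.
* **overlap** — outliers from shifted Ex-Gaussians:
  long ~ ExG(mean(valid) + 700, U(20, 50) + 10, U(150, 200)),
  short ~ ExG(mean(valid) - 200, 20, 10), with negative draws reflected to
  stay positive. Outliers can land inside the valid range, the "different
  process" case.

Two boundary choices the formulas leave open: if the valid minimum is at or
below 100 ms, short tails-outliers are drawn on (0, min(valid)) and a
warning is counted (the formula's range would otherwise invert); and in the
overlap scheme the contaminant sigma and tau are drawn once per sample, not
once per outlier — the formulas describe one contaminant distribution per
sample. Counts use round-half-to-even, with the short count defined as the
remainder so the split always sums to the total.

## The ten exclusion rules

`exclusion_methods()` lists the rules and constants; `apply_method()` runs
one. All statistics (mean, SD, median, quantiles, min, max) are computed on
the vector the rule is applied to — exclusion must work blind to ground
truth. Comparisons are strict: a value exactly on a threshold is kept
(the rules are phrased as "larger/smaller than"). Quantiles use linear
interpolation of order statistics (R's type-7 default), which also defines
the Tukey quartiles.

* `no` — keep everything.
* `cutoff` — a-priori bounds: below 200 ms (encoding + motor floor) or
  above mean + 1000 ms.
* `2sd`, `3sd` — outside mean ± k·SD (sample SD, n − 1 denominator).
* `tukey1.5` — outside the boxplot fences q0.25 − 1.5·IQR, q0.75 + 1.5·IQR.
* `q10`, `q05` — outside the 0.05/0.95 resp. 0.025/0.975 quantiles: fixed
  excluded shares by construction (up to small-sample rounding).
* `MAD`, `MAD_adjusted` — outside median ± 2.5·MAD with
  MAD = b·median(|x − median(x)|); b = 1.4826 calibrates the MAD to the SD
  of normal data, b = 1.1020 is the adjustment for the Ex-Gaussian shape
  (used as given; a smaller b means a smaller MAD, hence a *stricter* rule).
* `transform` — y = sqrt((x − min)/(max − min)), z-score y, drop |z| > 2;
  the square root symmetrises the skewed RT shape so both tails face a
  comparable criterion.

Degenerate inputs (constant vectors, MAD = 0, zero range, too few values
for the statistic) exclude nothing and warn rather than error, so a
simulation never loses iterations; the pipeline counts these events per
method instead of warning (see `run_experiment()`'s `counters`).

## Testing and the bias measure

Each pair — valid, and after each exclusion rule — is compared with a
two-sided Student t-test with pooled variance, significant at p < 0.05.
Pooled rather than Welch because variance equality holds by construction
(shared sigma, tau), and the pooled formula handles the unequal sample
sizes that exclusion creates. The statistic is oriented condition 2 minus
condition 1, so larger population differences push t upward. If exclusion
leaves fewer than `min_n` (default 3) observations on either side, the
iteration is recorded as non-significant for that method and counted.

For a method m at difference level diff,

> bias(m | diff) = p_sign(m | diff) − p_sign(valid | diff),

where p_sign is the proportion of significant tests. Positive bias means
the method manufactures significance the uncontaminated data would not show
(Type-I direction); negative bias means it conceals real differences
(Type-II direction). Per-method aggregates average over the 101 difference
levels within each approach; the cross-approach column is the unweighted
mean of the two approaches.

Two further summaries: an OLS regression of the t-values on diff, the
method factor (reference `no`), and the post-exclusion SD and n averaged
over conditions — it ranks the method's influence against effect size,
variability and sample size; and the Pearson correlation between a
method's |bias| and its mean excluded proportion, per approach, computed
without `no` (its large bias at zero exclusion would dominate). Because the
aggregation unit of that correlation is a free choice, both the
method-by-difference-cell and the per-method version are reported. For the
regression covariates, method rows use the *post-exclusion* SD and n (for
`no` these equal the contaminated values); the alternative — contaminated
covariates for all rows — would make the method coefficients absorb purely
mechanical SD changes.

## Numerical and design choices

* **Skewness** is the moment ratio g1 = m3 / m2^(3/2) per sample, averaged
  over samples — the simplest convention; estimator choice shifts the
  average skewness of small samples by a few percent, so skewness
  comparisons carry wider tolerances.
* **Reproducibility**: a master seed generates one sub-seed per iteration,
  so runs are rerun-identical and any single iteration can be reproduced in
  isolation; `records.csv` round-trips through `compute_bias()` exactly.
* **Rounding** of outlier counts is round-half-to-even (the convention of
  the numerical environment the model was developed in); rounding the long
  and short counts independently could break the total, so the short count
  is defined by subtraction.
* **Applied mode** (`exclude_table()`) computes thresholds within each
  condition separately — the same way the simulation applies rules to each
  condition's sample — and reports per-condition, per-tail excluded
  proportions, which is what a study should report alongside its rule.

## Problem sizes

The full design (2 x 505,000 pairs) is feasible but long; the package's
own verification runs the complete grid at reduced replication — 101
difference levels x 300 pairs x both approaches (60,600 iterations,
~670,000 t-tests) — which keeps Monte-Carlo standard errors on aggregate
proportions near one percentage point and on mean-bias aggregates near
0.002. A worked reduced run:

```{r, eval = FALSE}
res <- run_experiment(sim_config(diffs = 0:100, reps = 300, seed = 101))
res$bias$table
res$correlations
```

At this replication the cross-approach mean-bias ranking of methods is
stable for well-separated methods; methods whose true mean bias differs by
less than ~0.005 (the `transform` / `2sd` / `q10` cluster) can swap ranks
between seeds. Individual cells of the bias *curves* are much noisier than
the aggregates: a single method-by-difference cell rests on 300 paired
indicators and carries a standard error of roughly 0.01–0.02, so the
maximum of 101 such cells overshoots any band tighter than ~±0.04 by noise
alone — per-cell sign claims (a method "never" showing positive bias)
resolve only near the full 5000-pair replication.

## What the simulation does and does not show

The generator emulates the right-skewed shape, trial counts and
between-condition designs of typical RT studies, and contamination with a
*known* uncontaminated reference — which no empirical data set offers. It
does not emulate: trial-order effects or autocorrelation, participant-level
aggregation (each iteration is a single pair of samples, not a multi-subject
design), accuracy/speed trade-offs, or outliers "inside" the distribution
that no threshold rule can detect in principle. Conclusions about the
*ranking* of exclusion rules transfer to the extent that empirical outliers
resemble one of the two contamination schemes; the two schemes bracket
plausible cases and agree on the qualitative ordering, which is the result's
main support. Absolute bias magnitudes depend on the assumed outlier rates
(0–10%) and should not be quoted as universal constants.
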