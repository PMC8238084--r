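# rtexclusion

Monte-Carlo evaluation of response-time (RT) outlier exclusion methods.

RT research routinely drops "outlier" trials before comparing conditions,
but the field uses many different rules — absolute cutoffs, mean ± k·SD,
Tukey fences, fixed quantiles, MAD criteria, transform-then-z-score — and
the rule itself can change the statistical conclusion. This package
rebuilds that comparison as a tested, reusable simulation pipeline for
methodologists and RT researchers choosing (and justifying) an exclusion
rule.

## The model in brief

Each iteration simulates two conditions of *N* trials from an Ex-Gaussian
distribution (Normal(μ, σ) + Exponential(τ); mean μ + τ, variance
σ² + τ²), with N ~ U{20..100}, μ ~ U(250, 500), σ ~ U(20, 50),
τ ~ U(150, 200) ms and a known population shift *diff* ∈ {0, …, 100} ms
added to μ of condition 2. Between 0% and 10% of trials are then replaced
by outliers (long-outlier share ~ Beta(5, 1), mean 5/6) under one of two
schemes: **tails** (outliers strictly outside the valid range) or
**overlap** (outliers from shifted Ex-Gaussians that can land inside it).
Ten exclusion rules are applied to each contaminated pair, every version of
the pair is tested with a pooled two-sample t-test at α = 0.05, and each
rule *m* is scored by its bias at each difference level:

> bias(m | diff) = p_sign(m | diff) − p_sign(valid | diff)

the deviation of its significant-test proportion from the proportion in
the matched uncontaminated pairs. Positive bias = Type-I direction
(manufactured significance), negative = Type-II direction (concealed
effects).

## Worked example

```r
library(rtexclusion)

# one exclusion rule on a small sample
apply_method("2sd", c(300, 320, 340, 360, 380, 400, 2000))
#> Exclusion outcome: kept 6 of 7 (0.0% low tail, 14.3% high tail excluded)
#>   thresholds: [-663.44, 1834.87] ms

# a reduced run of the full design: 101 difference levels x 300 pairs
# per level x both contamination approaches (~3-4 min)
res <- run_experiment(sim_config(diffs = 0:100, reps = 300, seed = 101))
print(res$bias$table, digits = 3)
#>           method    mean overlap    tails
#>           <char>   <num>   <num>    <num>
#>  1:           no -0.2243 -0.1664 -0.28211
#>  2: MAD_adjusted  0.2004  0.2028  0.19795
#>  3:          MAD  0.1549  0.1583  0.15155
#>  4:     tukey1.5  0.1098  0.1153  0.10436
#>  5:       cutoff -0.0899 -0.1282 -0.05155
#>  6:          q05 -0.0718 -0.0467 -0.09683
#>  7:          3sd -0.0590 -0.0378 -0.08023
#>  8:    transform  0.0314  0.0519  0.01083
#>  9:          2sd  0.0285  0.0624 -0.00545
#> 10:          q10  0.0196  0.0304  0.00871
```

Reading the table: skipping exclusion altogether (`no`) misses real
effects (mean bias ≈ −0.22, Type-II direction), while the MAD rules and
Tukey fences *create* significance that is not in the uncontaminated data
(+0.20/+0.15/+0.11, Type-I direction — they trim much of the Ex-Gaussian
right tail). The SD/z-score-based rules (`2sd`, `3sd`, `transform`) and the
quantile rules stay within ±0.07. `res$records` holds every individual
test; `res$descriptives`, `res$regression` and `res$correlations` hold the
sample-characteristics table, the t-value regression, and the |bias| vs
excluded-proportion correlations. `write_experiment(res, "out/")` exports
all of them as CSV.

Applied mode, for empirical data (per condition, with the tail-wise
excluded proportions a paper should report):

```r
tab <- data.frame(id = 1, condition = rep(c("a", "b"), c(7, 4)),
                  rt = c(300, 320, 340, 360, 380, 400, 2000,
                         310, 330, 360, 390))
exclude_table(tab, "2sd")
#> Exclusion report, method '2sd' (applied per condition)
#>
#>  condition n prop_excluded_low prop_excluded_high prop_excluded
#>          a 7                 0              0.143         0.143
#>          b 4                 0              0.000         0.000
```

A thin CLI over the same functions ships in `inst/cli/rtexclusion`
(`simulate`, `summarize`, `exclude`, `methods` subcommands).

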