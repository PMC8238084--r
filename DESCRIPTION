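Package: rtexclusion
Title: Bias of Response-Time Outlier Exclusion Methods by Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Monte-Carlo comparison of response-time (RT) outlier exclusion
    methods. Simulates pairs of Ex-Gaussian RT samples with a known
    population mean difference, contaminates them with short and long
    outliers under two generative schemes (outliers strictly at the tails
    of the valid sample, or outliers drawn from shifted Ex-Gaussian
    distributions overlapping the valid range), applies ten exclusion
    rules (absolute cutoffs, mean +/- k SD, Tukey fences, fixed quantiles,
    MAD with normal-theory and Ex-Gaussian-adjusted constants, and a
    square-root range transform with z-scoring), and quantifies each
    rule's bias as the deviation of its significant two-sample t-test
    rate from the rate obtained on the uncontaminated samples. Also
    provides an applied mode that annotates empirical RT tables with
    per-condition exclusion flags and tail-wise excluded proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
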