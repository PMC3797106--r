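# breakscan

Chromosomal breakpoint counting and prognostic classification from SNP-array
copy-number profiles.

`breakscan` is for researchers who want to quantify tumor genomic instability
as a single number — the genome-wide count of chromosomal breakpoints — and
evaluate it as a prognostic marker against proliferation-based comparators in
early-stage luminal (ER+, HER2−, node-negative) breast carcinoma and similar
settings. It implements the full analysis chain as composable, tested R
functions: segmentation of per-probe log-intensity tracks, model selection
for the number of breakpoints, threshold training, proliferation scores, and
survival validation, together with seeded synthetic-data generators so every
stage can be exercised without array data.

## The method

**Segmentation.** Each chromosome's ordered log-scale probe signal
`y_1, …, y_n` is modelled as piecewise constant with homoscedastic Gaussian
noise. For every candidate number of breakpoints `k`, the globally optimal
partition minimises the within-segment residual sum of squares

    SS_k = min over 0 = τ_0 < τ_1 < … < τ_k < τ_{k+1} = n
           Σ_i Σ_{t = τ_{i-1}+1}^{τ_i} (y_t − ȳ_i)²

computed exactly by dynamic programming; both the textbook quadratic-time
recursion and a functionally pruned variant (near-linear in practice) are
provided and return identical optima.

**Model selection.** The breakpoint number is chosen by a modified Bayes
information criterion for the Gaussian mean-shift model with the variance
profiled out:

    mBIC(k) = (n/2)·log(SS_0 / SS_k) − ½·Σ_{i=1}^{k+1} log n_i − (k − ½)·log n

where `n_i` are the optimal segment lengths. Each breakpoint costs a
location term `log n` plus half a `log n` for its mean; `mBIC(0) = 0`.

**Two rounds.** A first segmentation round with a deliberately liberal
penalty identifies probes that land alone in length-1 segments; these
single-probe outliers are discarded, and the retained probes are segmented
afresh. The genome-wide count is the sum over chromosomes of
(segments − 1); chromosome junctions are never counted.

**Classification.** A tumor with strictly more than 34 breakpoints is
assigned to the high-risk complexity class. The cut-off can be re-trained on
any cohort by the Youden index (maximum sensitivity + specificity over all
integer cut-offs), with the ROC curve, Mann–Whitney AUC and DeLong 95%
confidence interval stored in the fitted model.

**Comparators and validation.** The package computes the genomic grade index
(panel contrast standardized so grade-1/grade-3 cohort means sit at −1/+1,
dichotomized at 0), the 14% KI67 dichotomization and the IHC3 score (the
IHC4 linear score with the HER2 term dropped), and validates classifiers
with Kaplan–Meier curves, log-rank tests and univariate/multivariate Cox
proportional-hazards fits (Efron ties; Wald intervals).

## Worked example

```r
library(breakscan)

# a synthetic tumor: two chromosomes, three true breakpoints, 1% outliers
sim <- simulate_profile(n_probes = c(chr1 = 300, chr2 = 300),
                        breakpoints = list(c(100L, 200L), c(150L)),
                        segment_means = list(c(0, 0.5, 0), c(0, -0.6)),
                        noise_sd = 0.1, outlier_rate = 0.01, seed = 42)
prof <- segment_tumor(sim$probes)
prof
#> <breakscan_profile> sim - 3 breakpoints ( low_risk at threshold 34 ), 6 outlier probes removed
prof$segments
#> # A tibble: 5 × 8
#>   tumor_id chrom start_probe end_probe start_bp end_bp mean_signal n_probes
#> 1 sim      chr1            1       100     1000 100000   0.00325        100
#> 2 sim      chr1          101       199   101000 200000   0.492           99
#> 3 sim      chr1          200       298   201000 300000  -0.0000954       99
#> 4 sim      chr2            1       147     1000 150000  -0.00245        147
#> 5 sim      chr2          148       296   151000 300000  -0.611          149
```

All three planted breakpoints are recovered (the 0.5 and −0.6 jumps at 5–6
noise SDs), the six injected outlier probes were screened out, and 3 ≤ 34
puts the tumor in the low-risk class.

```r
# a synthetic two-group cohort: train a threshold and validate it
co <- add_risk_classes(simulate_cohort(seed = 42)$cohort)
youden_threshold(co$breakpoint_count, co$group == "poor")
#> <breakscan_threshold> cut-off > 16 breakpoints
#>   sensitivity 0.97 (0.90-1.00)  specificity 0.82 (0.74-0.91)
#>   AUC 0.96 (95% CI 0.92-0.99)

lr <- logrank_test(co, "dfi_time", "dfi_event", "breakpoint_class")
sprintf("log-rank chi-square %.2f, p = %.3g", lr$statistic, lr$p_value)
#> "log-rank chi-square 21.10, p = 4.35e-06"
tidy(cox_fit(co, "dfi_time", "dfi_event", "breakpoint_class"))
#> # A tibble: 1 × 9
#>   variable         term    log_rr    rr ci_low ci_high p_value     n n_events
#> 1 breakpoint_class high_r…   1.61  5.02   2.34    10.8 3.42e-5   109       27
```

The high-complexity class carries a hazard ratio of ~5 in this draw
(simulated truth 3.5, inside the Wald interval), and the printed 2×2
statistics helper reproduces classical operating characteristics directly
from table counts:

```r
contingency_stats(74, 5, 13, 17)
#> # A tibble: 2 × 5
#>   statistic   estimate ci_low ci_high     n
#> 1 specificity    0.937  0.883   0.990    79
#> 2 sensitivity    0.567  0.389   0.744    30
```

A command-line wrapper over the same functions lives at
`inst/cli/breakscan.R` (`segment`, `simulate`, `classify` and an end-to-end
`pipeline` subcommand).

## Vignette

`vignettes/breakpoint-instability.Rmd` documents the model and its
assumptions, the modified-BIC derivation, the outlier-screen calibration,
the synthetic-data generators and their calibration targets, numerical
choices, and known limitations.
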