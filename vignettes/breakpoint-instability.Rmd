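---
title: "Counting chromosomal breakpoints as a genomic instability marker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting chromosomal breakpoints as a genomic instability marker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakscan)
```

## The problem

Early-stage luminal breast carcinomas (ER-positive, HER2-negative,
node-negative) are the most common screen-detected breast cancers, and the
hardest to prognosticate: classical anatomical markers are uninformative at
this stage, and proliferation markers (histologic grade, KI67, expression
proliferation scores) only partly separate outcomes. `breakscan` implements
an alternative marker: the *number of chromosomal breakpoints* in the
tumor's copy-number profile, i.e. the number of boundaries between adjacent
segments of differing mean signal. The count is a purely quantitative
measure of genomic instability — it deliberately ignores *which* regions
are gained or lost, because recurrent region-level alterations are
heterogeneous across luminal tumors while the overall level of rearrangement
is not.

## Signal model and segmentation

Within one chromosome, the ordered per-probe log-scale intensities are
modelled as piecewise constant plus homoscedastic Gaussian noise:

$$y_t = \mu_i + \sigma \varepsilon_t, \qquad \tau_{i-1} < t \le \tau_i,
\quad \varepsilon_t \sim \mathcal N(0, 1) \text{ iid}.$$

Under this model the maximum-likelihood segmentation for a fixed number of
breakpoints $k$ is the least-squares one, minimising the within-segment sum
of squared deviations $SS_k$. `optimal_segmentation()` computes the exact
optimum for every $k = 0,\dots,k_\max$ with two interchangeable engines:

* `method = "naive"`: the classical $O(k_\max n^2)$ dynamic program over
  prefixes, kept as an auditable reference;
* `method = "pruned"` (default): functional pruning — for each segment
  count, the cost of the current last segment is maintained as an explicit
  piecewise quadratic in its mean, and candidate change points whose
  quadratic is dominated everywhere are discarded. Expected complexity is
  close to linear in $n$; the optimum is identical by construction, and the
  test suite asserts exact agreement of both engines with each other and
  with exhaustive enumeration on small instances.

Segmentation is **per chromosome**, and the genome-wide count is
$\sum_{\text{chrom}} (\text{segments} - 1)$. Chromosomes are physically
independent linkage units, so a concatenated genome-wide fit would count
junction artifacts between chromosomes as breakpoints; summing
per-chromosome counts is the only coherent convention. Sex chromosomes are
included whenever present in the input — the marker is a genome-wide tally
and the package does not special-case them; users studying sex-mixed
cohorts should harmonise X/Y handling upstream.

### Choosing the number of breakpoints

`select_k()` maximises a modified Bayes information criterion. With the
noise variance profiled out, twice the maximised log-likelihood gain of the
$k$-breakpoint model over the constant model is $n \log(SS_0 / SS_k)$. For
the penalty, a Laplace (Bayes-factor) treatment of the Gaussian mean-shift
model gives three ingredient terms:

* each of the $k+1$ segment means is a regular parameter estimated from its
  own $n_i$ probes, contributing $\tfrac12 \log n_i$;
* the common variance contributes $\tfrac12 \log n$ in both models and
  cancels;
* each discrete breakpoint location, with a uniform prior over the $\sim n$
  admissible positions and a likelihood that concentrates geometrically
  around the optimum, contributes $\log n$.

Collecting terms (and subtracting the constant model's own
$\tfrac12 \log n$ for its mean):

$$\mathrm{mBIC}(k) = \frac n2 \log\frac{SS_0}{SS_k}
 - \frac12 \sum_{i=1}^{k+1} \log n_i - \Bigl(k - \frac12\Bigr) \log n,$$

equivalently a penalty of $\tfrac{3k}2 \log n + \tfrac12 \sum_i
\log(n_i/n)$: the familiar change-point result that a breakpoint costs
$\tfrac32 \log n$ at leading order, with a segment-length correction that
charges balanced segmentations slightly more than ones with short segments.
By construction $\mathrm{mBIC}(0) = 0$, the criterion depends on the data
only through the ratio $SS_0/SS_k$ and the segment lengths, and selection is
therefore invariant to shifting and positive rescaling of the signal (the
test suite asserts this). Ties are resolved towards the smallest $k$.

At the package's working scales ($n = 500$, jumps of 5 noise SDs, true
$k = 5$) this criterion recovers the true breakpoint number in $\ge 95\%$
of seeds and selects $k = 0$ on pure noise in $\ge 90\%$ — both measured in
the test suite.

### The two-round protocol and the outlier screen

SNP arrays produce sporadic single-probe artifacts whose intensity is
unrelated to the local copy number. Left in place, each artifact that the
segmentation isolates inflates the breakpoint count by two. The protocol
therefore runs two rounds per chromosome: a first segmentation whose only
purpose is to flag probes that fall alone in length-1 segments
(`remove_singleton_outliers()`), and a second segmentation of the retained
probes from which the reported breakpoints come.

The round-1 breakpoint number is itself mBIC-selected, but with the penalty
multiplied by `penalty_scale = 0.5`. This is a deliberate design choice,
fixed by a power analysis rather than by data fitting. Isolating one probe
costs two breakpoints; at the full penalty that is
$3\log n + \tfrac12\log\bigl(n \cdot n_1 n_2 / (n_1 + n_2 + 1)\bigr)
\approx 14.5$ log-likelihood units at $n = 500$, so a spike must deviate by
about $5.4\sigma$ to be isolated — a $6\sigma$ artifact (with its own noise
on top) is then caught only with probability $\approx 0.75$. At half
penalty the detection threshold drops to $\approx 3.8\sigma$: $6\sigma$
spikes are caught almost surely, while a *clean* probe needs
$|z| > 3.8$ to be falsely isolated, which at $n = 500$ happens to
$< 0.1\%$ of probes. The asymmetry is intentional: a missed artifact biases
the final count by $+2$, a falsely discarded noise probe barely perturbs
it. The screen runs exactly once — no iteration — and the final
segmentation uses the unscaled criterion.

### Degenerate inputs and numerical choices

* $SS_k = 0$ with $k < n - 1$ (noiseless toys): a floor of
  $10^{-12}\, n \,\widehat{\mathrm{var}}(y)$ is applied inside the
  criterion's logarithm; when $SS_0$ itself vanishes the likelihood term is
  defined as 0 and the penalty alone ranks the models, so constant signals
  always select $k = 0$.
* Signals are mean-centred before the dynamic programs for conditioning;
  the optimum is unaffected.
* Equal-cost placements are broken towards the leftmost breakpoints in the
  naive engine; with continuous signals exact ties do not arise, and the
  engines' agreement is asserted on random instances.
* `k_max` defaults to $\min(\lceil n/4 \rceil, 60)$ per chromosome — far
  above counts seen in practice while bounding runtime; larger values are
  capped at $n - 1$ with a warning.
* Chromosomes with fewer than 2 retained probes contribute 0 breakpoints,
  with a warning.
* In the pruned engine the mean domain is the observed signal range with a
  tiny padding, and pieces narrower than $10^{-12}$ are dropped.

## The classifier

`classify_risk()` implements the strict rule: **more than** 34 breakpoints
is high-risk; 34 itself is low-risk. `youden_threshold()` re-trains the
cut-off on any cohort by scanning all achievable integer cut-offs (every
distinct observed count plus one below the minimum) and maximising
sensitivity + specificity, ties towards the smallest threshold. The fitted
model stores the ROC curve, the Mann–Whitney AUC (ties counted one half)
and its DeLong 95% confidence interval. DeLong is the default interval
because it is the standard asymptotic choice for paired empirical AUCs; the
implementation is in-package and cross-checked against an independent one
in the tests. Sensitivity/specificity intervals are Wald,
$p \pm 1.96\sqrt{p(1-p)/n}$ truncated to $[0,1]$ — chosen because the Wald
form reproduces the conventional reporting of printed 2×2 tables, which
exact binomial intervals do not.

## Proliferation comparators

* **Genomic grade index**: `ggi_raw()` computes the per-sample contrast
  between the sum over a 112-probe-set panel (up in histologic grade 3) and
  a 16-probe-set panel (up in grade 1); user-supplied panels of other sizes
  are accepted with a warning. `fit_ggi_standardization()` maps the grade-1
  and grade-3 cohort means onto $-1$ and $+1$ exactly
  ($\text{scale} = 2/(m_3 - m_1)$, $\text{offset} = (m_3 + m_1)/2$); the
  fit anchors on grades 1 and 3 only, and grade-2 or ungraded samples are
  standardized with the fitted model. `genomic_grade()` dichotomizes at 0,
  with exactly 0 called GG1 — the conservative, lower-risk call at the
  boundary.
* **KI67**: dichotomized at 14% with the boundary value called high
  (matching the convention that "high" starts at the cut-off).
* **IHC3**: the IHC4 linear combination with the HER2 term dropped,
  $94.7(-0.100\,\mathrm{ER}_{10} - 0.079\,\mathrm{PR}_{10} +
  0.240\ln(1 + 10\,\mathrm{Ki67}))$, with ER/PR on 0–10 scales and KI67 as
  a fraction so that $10 \times \mathrm{Ki67}$ shares the same 0–10 scale.
  The coefficients are shipped as a citable data file
  (`inst/extdata/ihc3_coefficients.json`), not hard-coded. Manual KI67
  readings can be divided by a calibration factor (`ki67_rescale`, default
  1); any non-default factor is echoed as a message so the calibration is
  always visible in logs.

## Survival validation

Kaplan–Meier estimation, log-rank testing and Cox proportional-hazards
fitting delegate to the `survival` package (the field's reference
implementation) behind tidy wrappers; the test suite validates them against
hand-computed product-limit curves, a direct $O(\text{events})$ log-rank
tabulation and parameter-recovery simulations. Ties use the Efron
approximation — the default of modern survival stacks. Relative risks are
hazard ratios with Wald 95% intervals and Wald p-values; univariate mode
fits each term alone, multivariate mode fits the joint model (the standard
multivariate set is grade II/III vs I, KI67 class, genomic grade and
breakpoint class, assembled by `add_risk_classes()`). Non-convergence and
suspected separation are surfaced as warnings, never silenced; collinear
(duplicated) covariates are an error. Two endpoints are carried side by
side: the disease-free interval (any loco-regional, contralateral or
metastatic relapse) and the metastasis-free interval (metastasis only).

## What the generators emulate — and what they do not

`simulate_profile()` draws piecewise-constant signals with iid Gaussian
noise and sporadic additive single-probe spikes — exactly the model under
which the segmentation is optimal. Real SNP-array profiles additionally
show GC-content waves, probe-specific variances, allele-specific structure
and intra-tumor heterogeneity (sub-clonal segments at intermediate levels).
Passing tests on these simulations therefore demonstrate correctness of the
estimator under its own model, and calibrated operating characteristics at
stated signal-to-noise ratios; they do not demonstrate robustness to wave
artifacts or heterogeneity, which require upstream normalization.

`simulate_cohort()` generates a two-group cohort whose joint structure
matches the targets a validation series of this kind exhibits:

* breakpoint counts are negative binomial per group, with means solved
  numerically so the theoretical medians hit 7 (good prognosis) and 40.5
  (poor prognosis); dispersions 1.5 and 3 are calibration choices giving a
  realistic interquartile spread;
* the genomic grade index is tied to the counts through a rank-based
  Gaussian copula with latent correlation $2\sin(\pi\rho_S/6)$, hitting the
  target Spearman correlation (default 0.54) in expectation; infeasible
  targets ($|\rho_S| \ge 0.999$) are an error;
* KI67 (Beta-distributed fraction, ~55% at or above 14%) and histologic
  grade (~46/39/15% for I/II/III) derive from the same latent factor;
* disease-free times are exponential with baseline hazard 0.0261/year —
  chosen so the low-complexity class has a ten-year event fraction near
  23% — multiplied by the class hazard ratio (default 3.5) for counts
  strictly above 34; censoring is uniform on `horizon ± 3` years around the
  10.5-year median follow-up; 27% of disease-free events are metastatic.

Group sizes default to 79 + 30. All generators are pure functions of their
arguments including the seed. Under these conditions the package's own test
suite measures ~95% Wald coverage of the true log hazard ratio and ~90%
log-rank power at $n = 105$.

## Problem sizes in the tests

The suite runs brute-force segmentation oracles at $n \le 20$, engine
agreement at $n \le 200$, selection and outlier calibrations at $n = 500$
over 50 seeds, survival calibrations over 100–200 simulated cohorts of
$n = 105$–109, and an end-to-end command-line pipeline with 12–40 patients
and 3–6 chromosomes of 80–120 probes. These sizes were chosen so each
property is measured with useful precision while the whole suite stays fast
enough to run habitually; every one of them is an argument, not a constant.

## Known limitations

* No wave/GC normalization and no allele-specific (B-allele-frequency)
  modelling: the input is assumed normalized.
* Homoscedastic Gaussian cost: heavy-tailed noise beyond the single-probe
  spike model can inflate counts; the screen only removes *singleton*
  artifacts.
* The 34-breakpoint cut-off is platform- and resolution-dependent; counts
  from arrays of different probe density are not directly comparable and
  the threshold should be re-trained (`youden_threshold()`) when the
  platform changes.
* The KI67 rescaling factor for manual counts is cohort-specific and must
  be supplied by the user; the package defaults to 1 and reports the value
  used.
* Whether X/Y probes should enter the count is a cohort-design question the
  package does not decide; it tallies whatever chromosomes are present.
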