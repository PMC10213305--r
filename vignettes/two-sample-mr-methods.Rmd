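---
title: "Two-sample Mendelian randomization with mrkit: models, conventions, calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for an exposure. For instrument $j$, let $\gamma_j$ be its true
effect on the exposure and $\alpha_j$ its direct (pleiotropic) effect on
the outcome. The observed summary statistics are modelled as

$$\hat\beta_{xj} \sim N(\gamma_j,\ se_{xj}^2), \qquad
  \hat\beta_{yj} \sim N(\theta\,\gamma_j + \alpha_j,\ se_{yj}^2),$$

with $\theta$ the causal effect of interest (log odds of the outcome per
unit of exposure when the outcome is binary). Valid instruments require
$\alpha_j = 0$ and no association with confounders; the selection screens
and the sensitivity suite exist to probe exactly these assumptions.

Each SNP contributes a Wald ratio $\hat\theta_j = \hat\beta_{yj} /
\hat\beta_{xj}$ with the first-order standard error $se_{yj} /
|\hat\beta_{xj}|$, which ignores the exposure-side sampling error. This is
the standard approximation when instruments are strong (the packaged
datasets have F ≈ 50; at that strength the neglected term is below one
percent of the ratio variance), and every estimator and weight in the
package is built on it.

## Estimators

**IVW.** The pooled estimate is the inverse-variance-weighted mean of the
Wald ratios, with weights $w_j = (\hat\beta_{xj}/se_{yj})^2$ —
algebraically identical to a zero-intercept weighted least-squares fit of
$\hat\beta_y$ on $\hat\beta_x$ with weights $1/se_y^2$ (the test suite
cross-checks the two code paths to $10^{-10}$). Two variants share the
point estimate and differ in the SE:

- *fixed*: $se = (\sum_j w_j)^{-1/2}$;
- *multiplicative random effects* (the default): the fixed SE scaled by
  $\hat\sigma = \sqrt{Q/(k-1)}$, where $Q$ is Cochran's statistic below.

$\hat\sigma$ is deliberately left **unconstrained**: when the per-SNP
estimates are less dispersed than their SEs predict, $\hat\sigma < 1$ and
the random-effects interval is *narrower* than the fixed one. This is the
convention under which both packaged cohort analyses reproduce their
published confidence intervals and p-values (the Chinese set is
over-dispersed, $\hat\sigma \approx 1.12$; the Japanese set
under-dispersed, $\hat\sigma \approx 0.75$); a floor at 1 would be the more
conservative alternative, and anyone wanting it can take the wider of the
fixed and random SEs. IVW p-values are two-sided normal.

**MR-Egger.** Weighted least squares of $\hat\beta_y$ on $\hat\beta_x$
with a free intercept, weights $1/se_y^2$. Under the InSIDE assumption
(pleiotropic effects independent of instrument strength) the slope remains
a consistent causal estimate and the intercept estimates the mean
directional pleiotropic effect; an intercept distinguishable from zero is
the Egger test for directional pleiotropy. Because a constant intercept is
only meaningful when all instruments point in the exposure-increasing
direction, `mr_egger()` first applies `orient_positive_exposure()`
(sign-flipping both betas of any SNP with $\hat\beta_x<0$; Wald ratios are
invariant, the intercept is not, which is why orientation is built in
rather than left to the caller). SEs carry the same unconstrained
multiplicative residual scale, and slope and intercept p-values use the
t-distribution with $k-2$ degrees of freedom — with $k=4$ or $5$
instruments the normal approximation would visibly misstate them.

**Weighted median.** Wald ratios are sorted and the normalized weights
accumulated; with cumulative midpoints $s_j = \sum_{i\le j} w'_i - w'_j/2$
the estimate is the linear interpolation of the sorted ratios at
$s = 0.5$. It is consistent while at least half the total weight comes
from valid instruments. The SE is a parametric bootstrap (default 1000
resamples): effects are redrawn from normals centred on the observed
values with their reported SEs and the weighted median recomputed; the SE
is the SD of the resamples. The bootstrap is the one stochastic step in
the estimator panel, so `seed` makes it bit-reproducible; p-values are
two-sided normal.

## Sensitivity suite

**Cochran's Q** is $\sum_j w_j(\hat\theta_j - \hat\theta_{IVW})^2$ with
the first-order IVW weights, referred to $\chi^2_{k-1}$. A second-order
weight variant that also propagates $se_x$ is available
(`weights = "second_order"`) but off by default — the first-order form is
the one whose p-values match the packaged analyses.

**Leave-one-out** refits IVW with each SNP removed. An omission is flagged
"influential" when the point estimate crosses the null or leaves the
full-set confidence interval. That flag is a package convention (the
qualitative check is usually read off a forest plot); a CI-overlap
criterion was rejected because the multiplicative random-effects interval
inflates exactly when an outlier is present, masking it.

**MR-PRESSO.** The global test statistic is the leave-one-out weighted
residual sum of squares
$RSS = \sum_j (\hat\beta_{yj} - \hat\theta_{(-j)}\hat\beta_{xj})^2/se_{yj}^2$,
compared against parametric simulations from the no-pleiotropy model: in
each of `n_sim` draws, $\beta^*_{xj} \sim N(\hat\beta_{xj}, se_{xj})$ and
$\beta^*_{yj} \sim N(\hat\theta_{(-j)}\hat\beta_{xj}, se_{yj})$, with the
leave-one-out estimates recomputed per draw. The global p is the
add-one tail proportion $(1 + \#\{RSS^* \ge RSS\})/(n_{sim}+1)$, so it is
never exactly zero. Each SNP's observed residual against its own simulated
distribution gives the outlier test, Bonferroni-compared to
`outlier_significance / k`; the default `n_sim = 10000` resolves p-values
of interest with Monte-Carlo error around 0.005. When outliers are found,
the distortion test reports the shift in the IVW estimate due to removing
them, calibrated against a bootstrap of outlier-free subsets — a
convention of this package, exercised only qualitatively in tests.

**Funnel and forest data** are returned as plain coordinate tables
(ratio vs. precision $1/se$; per-SNP ORs with CIs) with `autoplot()`
methods, so any plotting layer can re-render them.

## Instrument selection

The selection pipeline applies, in order: a strict `p < 5e-8` exposure
significance filter; greedy LD clumping (take the smallest-p remaining
SNP, discard others with $r^2 > 0.001$ within a 10,000 kb window); proxy
substitution for instruments missing from the outcome (best available
$r^2 \ge 0.8$); a `p < 5e-8` outcome-association screen; and optional
confounder screens against user-supplied GWAS tables. All thresholds use
strict inequality and live in `selection_config()`.

Determinism required two conventions the underlying procedure leaves open:
clumping ties on p-value break by smaller genomic position then
lexicographic id, making the result independent of input row order (a
property test permutes rows and compares against a brute-force oracle on
all instances up to six SNPs); and an *unknown* $r^2$ between two SNPs
inside the window is treated as linkage by default
(`missing_ld_policy = "conservative"` — dropping a possibly-correlated SNP
costs efficiency, keeping it can bias the estimate), with a permissive
option for sparse user LD tables. Proxy ties break by higher $r^2$, then
smaller outcome p, then id.

Instrument strength uses $R^2_j = 2\,EAF_j(1-EAF_j)(\beta_{xj}/SD)^2$ and
$F = ((N-k-1)/k)\,R^2/(1-R^2)$. The trait SD is an explicit argument
(default 1, i.e. standardized betas): summing the formula over the
packaged Chinese instruments with SD = 1 gives $R^2 \approx 0.98\%$,
whereas the published analysis reports 0.36% — the SD used there is not
recoverable from the per-SNP table — so `instrument_strength()` also
accepts a reported `r2_total` as an input constant and computes F from it
($F = 52.5$ at $R^2 = 0.0036$, $N = 72{,}655$, $k = 5$, matching the
published value once rounded).

## Harmonization conventions

Outcome records are aligned to the exposure effect allele: swapped alleles
sign-flip $\hat\beta_y$ and complement the EAF; alleles matching only
after strand complementation (A↔T, C↔G) are complemented first; anything
irreconcilable is excluded as `allele_mismatch`. Palindromic SNPs (A/T,
C/G) cannot be strand-resolved from the letters, so the default policy
infers orientation from allele frequencies and drops SNPs whose EAF falls
in [0.42, 0.58] on either side, where frequency is uninformative; `drop`
and `keep` policies are available. The band and the default are package
decisions — standard two-sample practice — and do not affect the packaged
analyses, whose instruments are all non-palindromic. Every exclusion and
flip is logged (`exclusion_log()`), and proxy substitutions carry a
`proxy_for` audit column.

## The synthetic generator

`simulate_mr()` draws directly from the two-sample model above. Defaults
were fixed once, at the scale of the packaged datasets: positive
$\gamma_j$ with mean 0.08 and SD 0.03 (the packaged exposure betas span
0.036–0.131), exposure SEs uniform on 0.005–0.007 (a biobank-scale
quantitative GWAS), outcome SEs on 0.08–0.10 (a case–control GWAS of
roughly 1,500 subjects), EAFs uniform on 0.1–0.9, and non-palindromic
allele pairs so harmonization is lossless. SEs are drawn from ranges
rather than derived from sample size and EAF, keeping noise levels
directly controllable. Pleiotropy scenarios: `none`, `balanced`
(zero-mean $\alpha_j$), `directional` (nonzero mean), with
`inside_violation` the $\gamma$–$\alpha$ correlation. Ground truth
($\theta$, $\gamma$, $\alpha$, outlier flags) is returned alongside the
tables so recovery tests never re-derive it.

What the generator emulates — and what it does not — bounds what passing
tests show: instruments are independent (no residual LD), effects are
exactly linear and normal, SEs are correctly reported, and both samples
are non-overlapping. Calibration results under this model (fixed-effect
IVW coverage 95% ± 3% over 500 replicates; Egger intercept recovering the
directional-pleiotropy mean at k = 200; MR-PRESSO null p approximately
uniform over 200 datasets; an injected 10-SE outlier flagged in ≥ 90% of
50 seeds) therefore demonstrate correctness of the implementations, not
robustness to real-data pathologies such as sample overlap, winner's
curse, or mis-specified SEs.

## Numerical choices and degenerate inputs

- 95% intervals use the normal quantile 1.959964 throughout.
- p-values: normal for IVW and WME, t with $k-2$ df for both Egger terms.
- A single instrument supports only the fixed-effect IVW (equal to its
  Wald ratio); multiplicative random effects needs $k \ge 2$, Egger and
  WME need $k \ge 3$, MR-PRESSO $k \ge 4$. The pipeline degrades to IVW
  and Q with a warning below three instruments and fails at zero.
- $\hat\beta_x = 0$ cannot be oriented or divided by; such SNPs are
  excluded as `null_instrument`.
- Noise-free inputs (zero residuals) are handled exactly: Egger recovers
  slope and intercept to machine precision and Q is exactly 0 for
  identical ratios.
- The weighted-median interpolation clamps at the extreme order statistics
  when 0.5 falls outside the cumulative midpoints (possible when one SNP
  carries most of the weight).

Test problem sizes were chosen to make each statistical claim resolvable
at comfortable margins: 500 replicates bound coverage to about ±1%
Monte-Carlo error against a ±3% band; 200 datasets at `n_sim = 199`
suffice for the uniformity check; the seed-stability check uses 10
repeats at `n_sim = 10000`.

## Limitations

- No mode-based, multivariable, or contamination-mixture estimators; no
  radial MR.
- No LD simulation between instruments and no reference-panel lookups: LD
  arrives as user-supplied pairwise $r^2$ tables.
- The Wald-ratio SE ignores exposure-side noise; with weak instruments
  (F near 10) both it and the Egger slope attenuate, and the package does
  not correct for that beyond reporting F.
- Binary-outcome betas are treated as log odds ratios; no
  liability-scale conversion is attempted.
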