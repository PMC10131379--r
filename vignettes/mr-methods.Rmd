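---
title: "Two-sample and multivariable Mendelian randomization with mrflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and multivariable Mendelian randomization with mrflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrflow)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure (here, a
quantitative trait such as a circulating metabolic biomarker, in SD
units) on a binary outcome (such as lung cancer, on the log-odds scale)
from *summary-level* GWAS data alone. In the two-sample design the
per-SNP exposure associations $\hat\gamma_j \pm \sigma_{x_j}$ and
outcome associations $\hat\Gamma_j \pm \sigma_{y_j}$ come from
non-overlapping cohorts, so their sampling errors are independent.

A variant is a valid instrument when it is (i) robustly associated with
the exposure, (ii) independent of confounders, and (iii) affects the
outcome only through the exposure. mrflow implements the full workflow
around these assumptions: instrument selection and strength
quantification, allele harmonization, five univariable estimators with
heterogeneity and pleiotropy diagnostics, residual-simulation outlier
correction, multivariable MR for correlated exposures, and
false-discovery-rate control over a study grid — plus a synthetic
generator with known ground truth so every stage can be validated
offline.

## Instrument selection

`buildInstrumentSet()` applies four filters in a fixed order, mirroring
the canonical quality-control narrative for summary-level instruments:

1. genome-wide significance, strictly $p < 5\times10^{-8}$;
2. greedy LD clumping at $r^2 < 0.01$ in a 10,000 kb window — candidates
   are sorted by ascending p-value, the best remaining variant becomes
   an index SNP, and every remaining variant on the same chromosome
   within half the window whose $r^2$ with the index reaches the
   threshold is removed, so the lower-p member of any correlated pair is
   always the one retained;
3. minor-allele frequency $\ge 1\%$ (the boundary is kept: the exclusion
   rule is MAF *below* 1%);
4. outcome matching, with proxy fallback: a variant absent from the
   outcome GWAS may be replaced by the outcome variant with the largest
   $r^2 > 0.8$ (ties broken by smaller p, then lexicographic id),
   accepted only when the effect-allele frequencies are close enough
   (|difference| < 0.2) for the orientation to be unambiguous.

The window convention treats `window_kb` as the *total* clump window: a
candidate is "within the window" of an index SNP when
$|pos_\text{index}-pos_\text{cand}| \le$ `window_kb`·1000/2 on the same
chromosome. LD is an explicit input (`LDMatrix`): the package never
guesses a reference panel, and pairs absent from the input default to
$r^2 = 0$.

Instrument strength uses the standardized-trait identities
$R^2_j = 2\hat\gamma_j^2 f_j(1-f_j)$ and
$F = R^2(n-k-1)\,/\,k(1-R^2)$. The reported *mean F* averages per-SNP F
values computed with $k=1$; the joint F from the total $R^2$ is kept
alongside. A mean F at or below 10 triggers a weak-instrument warning
but never aborts the analysis.

## Harmonization

`harmonizePair()` places the outcome effect on the exposure's
effect-allele frame. Identical alleles pass through; swapped alleles
negate the outcome beta and complement its frequency; alleles that match
only after strand complement are complemented first (summary files from
different arrays may report opposite strands, so repair is attempted
before declaring alleles unconcordant). Palindromic variants (A/T, C/G)
cannot be resolved from labels: the default policy excludes them; the
`infer_by_eaf` policy orients them by frequency agreement, dropping any
variant whose frequency falls inside the ambiguity band (0.42, 0.58).
Exclusion is the conservative default because the correction rule used
in practice varies between analysts; both policies are first-class and
tested.

Two properties are enforced by tests rather than assumed: harmonization
is idempotent on its own output, and every downstream estimate is
invariant (to $10^{-12}$) under recoding an entire input file (swap
alleles, negate betas, complement frequencies).

## Estimators

With harmonized effects, the per-SNP Wald ratio is
$\hat\theta_j=\hat\Gamma_j/\hat\gamma_j$ with first-order
delta-method SE $\sigma_{y_j}/|\hat\gamma_j|$ (exposure-side noise is
neglected, appropriate when mean F $\gg 10$).

* **IVW** combines ratios with weights
  $w_j = \hat\gamma_j^2/\sigma_{y_j}^2$ — algebraically the weighted
  least-squares slope of $\hat\Gamma$ on $\hat\gamma$ through the
  origin. Cochran's Q over the ratios tests between-SNP heterogeneity
  ($\chi^2_{n-1}$). The default model is multiplicative random effects,
  inflating the SE by $\max(1, \sqrt{Q/(n-1)})$; this is the dominant
  practice when heterogeneity is significant, and a fixed-effect variant
  is available by flag.
* **MR-Egger** orients each SNP so $\hat\gamma_j \ge 0$ and fits the
  weighted regression $\hat\Gamma_j = \alpha_0 + \beta\hat\gamma_j$.
  The slope is consistent under InSIDE; the intercept estimates average
  directional pleiotropy and its t-test ($n-2$ df) is the Egger
  intercept test. SEs use the same overdispersion floor with $n-2$ df.
* **Weighted median** returns the weighted 50th percentile of the
  ratios. The quantile respects atoms: the smallest ratio whose
  cumulative weight reaches one half is returned, with adjacent ratios
  averaged only when the cumulative weight lands on one half exactly.
  This convention was chosen over pure midpoint interpolation because it
  preserves two exact identities at once: a SNP carrying more than half
  the weight *is* the estimate, and equal weights reduce to the plain
  median for both odd and even counts.
* **Weighted mode** maximizes a weighted Gaussian kernel density of the
  ratios over a 512-point grid spanning the ratios ± 3 bandwidths (ties
  resolved to the lowest grid point), with bandwidth
  $0.9\min(\mathrm{sd}_w,\mathrm{mad}_w)n^{-1/5}$ times a user
  multiplier. The density is evaluated with `stats::density` (FFT
  binning), which agrees with direct kernel evaluation to within grid
  resolution and keeps large replication studies tractable.
* Median and mode SEs use a parametric bootstrap: ratios are resampled
  from $N(\hat\theta_j, se_{\theta_j}^2)$, the estimator recomputed, and
  the SD taken; 1000 replicates and an explicit seed by default, so
  results are exactly reproducible.

Egger p-values use $t_{n-2}$; IVW p-values the normal distribution —
both conventional. `toOddsRatio()` maps any log-odds estimate to
$\mathrm{OR}=e^\beta$ with the 95% Wald interval $e^{\beta\pm1.96\,se}$.

The Wald ratio is implemented as outcome-over-exposure, $b_y/b_x$: this
is the only direction consistent with interpreting the result as
log-odds of outcome per SD of exposure, which is how ORs per biomarker
SD are reported.

## MR-PRESSO

`mrPresso()` detects pleiotropic outliers by residual simulation. For
each SNP the leave-one-out IVW slope $\hat\theta_{-j}$ defines an
expected outcome effect; the observed weighted residual sum of squares
is compared with its distribution over `n_sim` datasets simulated under
the no-pleiotropy model (both axes perturbed:
$b_y^* \sim N(\hat\theta_{-j}b_{x_j}, \sigma_{y_j}^2)$,
$b_x^* \sim N(b_{x_j}, \sigma_{x_j}^2)$). Per-SNP contributions give
two-sided empirical outlier p-values, floored at $1/(n_\text{sim}+1)$
*after* doubling (flooring the one-sided fractions first would push the
Bonferroni-corrected minimum above any usual $\alpha$, making detection
structurally impossible), and Bonferroni-corrected across SNPs. The
corrected estimate is the IVW fit on the outlier-free subset — computed
with identical arithmetic, so it matches `mrIvw()` bit for bit — and the
distortion test compares the raw-vs-corrected shift with the same
contrast under removal of equally many random SNPs. Note that detection
requires $n_\text{sim} \gtrsim 2\,n_\text{snp}/\alpha$; the default
`n_sim = 1000` is the working minimum for a 50-SNP panel at
$\alpha=0.05$.

## Multivariable MR

`mvmrIvw()` regresses the outcome effects on the $J\times K$ matrix of
exposure effects with weights $1/\sigma_{y_j}^2$ and no intercept; each
coefficient is a *direct* effect holding the other exposures fixed.
The coefficient covariance uses the weighted normal equations with
overdispersion $\max(1, Q/(J-K))$ and $t_{J-K}$ p-values. Design
assembly (`assembleMvmrInput()`) unions the per-exposure instruments,
re-clumps them jointly — the index SNP of a region is the one with the
smallest p-value across exposures, preventing double-counting of shared
or correlated instruments — and drops (with a log) SNPs missing from any
exposure rather than imputing zero effects, which would bias that
exposure toward the null. Covariate traits (smoking, alcohol, BMI in
typical applications) are appended as extra columns at the same
instruments via `mvmrWithCovariates()`; covariate-specific instruments
are not added, since the assembled design fixes the SNP set.

A descriptive conditional instrument-strength proxy is reported per
exposure (mean over SNPs of $d_{jk}^2/\sigma_{x_{jk}}^2$, with $d_{jk}$
the residual of exposure $k$'s effects regressed on the others); no
threshold is enforced.

## The study pipeline and FDR

`runUnivariable()` executes the full exposure-by-outcome grid, emitting
one row per estimator with Q, Egger-intercept and MR-PRESSO diagnostics,
per-pair scatter exports, an exclusion log, and a run log. Failures are
row-level: a pair with zero surviving instruments is flagged and the
study continues. Benjamini–Hochberg q-values are computed within each
(outcome, method) family across exposures — the layout in which
per-method FDR columns are conventionally reported — via
`stats::p.adjust`. All randomness (bootstraps, PRESSO, simulation)
derives from one master seed expanded into per-pair stage seeds with a
fixed splitting scheme, so reruns are byte-identical.

## The synthetic generator

`simulateTwoSample()` draws, for each SNP $j$: a frequency
$f_j \sim U(\text{eaf range})$, an exposure effect
$\gamma_j \sim N(\mu_\gamma, \sigma_\gamma^2)$, and a pleiotropic effect
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ (multiplied by
`outlier_scale` for a planted fraction of SNPs). The true outcome effect
is $\Gamma_j = \beta\gamma_j + \alpha_j$ on the log-odds scale —
generated directly rather than through a liability model, which keeps
the truth interpretable as a log-OR, the scale on which results are
reported. Observed effects add independent noise with the
standardized-trait SEs $1/\sqrt{2 n_x f(1-f)}$ and
$1/\sqrt{2 f(1-f)\,n_\text{eff}}$,
$n_\text{eff} = n_1 n_0/(n_1+n_0)$: these reproduce the familiar
coupling of power to sample size and allele frequency without
genotype-level simulation. Alleles are drawn from all ordered pairs,
with palindromic pairs at a configurable rate (default 10%) to exercise
harmonization. `simulateLdBlockGwas()` adds block LD (one shared effect
per block plus jitter; constant within-block $r^2$, zero between), and
`simulateMvmr()` draws per-SNP effect vectors on $K$ exposures from a
multivariate normal with a supplied correlation — which reproduces the
classic reversal where an exposure with no direct effect but strong
correlation to a causal one shows a clear univariable signal that
vanishes in the joint model.

Default scale parameters, chosen once: exposure GWAS of $10^5$, outcome
of 20,000 cases / 20,000 controls, 100 SNPs, per-SNP effects
$N(0, 0.05^2)$ SD units — typical of genome-wide-significant loci for
metabolic biomarkers — and frequencies in (0.05, 0.95). What the
generator does *not* emulate: realistic LD decay, winner's curse from
overlapping discovery, liability-scale case-control subtleties, indels
and multi-allelic sites. Passing tests therefore demonstrate internal
statistical correctness of the estimators under their assumptions, not
robustness to every artefact of real summary files.

## Validation design and measured behavior

The test suite checks three layers: exact oracles (closed-form
arithmetic, reduction identities such as single-SNP IVW = Wald ratio and
$K=1$ MVMR = fixed-effect IVW, a brute-force clumping reference over 100
random instances), invariances (allele recoding, SNP order, byte-level
rerun determinism), and Monte-Carlo calibration/recovery under the
generator. Replication sizes — 1000 null replicates for calibration,
200 for recovery, 100 seeded runs for outlier detection, with
`n_boot = 200` and `n_sim = 500` inside each replicate — were fixed as a
balance between Monte-Carlo error and suite runtime.

Calibration and recovery scenarios apply the estimators to the
genome-wide-significant subset of each simulated panel — the estimators'
operating regime in the pipeline. Feeding them *unselected* SNPs
includes near-zero exposure effects whose Wald ratios are essentially
unbounded; the weighted mode's evaluation grid then stretches over the
wild ratios and the estimator degrades — an instructive failure mode,
but not one any real analysis encounters, since instruments are
significance-filtered by construction.

Measured at the fixed default seeds, 1000 null replicates: Cochran's Q
rejects at 6.2%, the Egger intercept test at 3.8%, and the MR-PRESSO
global test at 5.9% (all at nominal 5%); IVW intervals cover the null at
95.0% and Egger at 96.1%. The weighted median (98.0%) and weighted mode
(99.1%) intervals over-cover: the parametric bootstrap SE used for both
is conservative for order/mode statistics, in line with published
simulations of the weighted-mode estimator showing well above 99%
coverage at the default bandwidth. The package reports this behavior as
is — the bootstrap is the standard SE for these estimators — and the
corresponding acceptance checks document the conservatism rather than
masking it.

## Known limitations

* LD must be supplied; there is no reference-panel computation from
  genotypes, no liftover, and positions are opaque coordinates within
  one dataset.
* Only biallelic SNPs with single-character alleles are handled; indels
  and multi-allelic records are dropped at ingest.
* No Steiger directionality filtering, radial MR, simple/penalized mode
  variants, or MVMR-Egger/median.
* Proxy alignment relies on frequency orientation; signed LD is not
  consumed.
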