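---
title: "Slice-dependent non-stationary signal power: model, correction and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-dependent non-stationary signal power: model, correction and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicevar)
```

## The model

In 2D echo-planar imaging all voxels of a slice are acquired
simultaneously, so any fluctuation of signal power during acquisition —
RF amplification inhomogeneity, coil resistance, susceptibility-induced
signal loss, B0 drift — hits every voxel of a slice identically, and
different slices differently. `slicevar` models the measured voxel
intensity in slice $m$ as a multiplicative decomposition

$$x_{m,t} = x^{(st)}_{m,t}\,\sigma_{m,t}, \qquad
  \sigma^2_{m,t} \sim IG(\alpha_m, s_m)\ \text{iid over}\ t,$$

where $x^{(st)}_{m,t}$ is the underlying weakly stationary signal
(zero-mean Gaussian with stationary variance $\sigma^2_x$ in the analytic
results; white or vector-autoregressive in the simulators) and
$\sigma^2_{m,t}$ is the slice's time-varying signal power, inverse-gamma
distributed with slice-specific shape $\alpha_m$ and scale $s_m$.

Three analytic consequences drive the package:

1. **Attenuation.** Sample correlation between two weighted series is the
   stationary correlation scaled by
   $\kappa = E[\sigma_m \sigma_n]/\sqrt{E[\sigma^2_m]E[\sigma^2_n]}$,
   which Cauchy-Schwarz bounds by 1. Uncorrected time-varying power can
   only shrink connectivity estimates (`kappaTheoretical()`,
   `expectedNonstationaryCorr()`).
2. **Variance inflation.** The sampling variance of sample correlation
   becomes $(1-\kappa^2\rho^2)/(T-2)$, never smaller than the stationary
   $(1-\rho^2)/(T-2)$; uncorrected maps are therefore more prone to
   spurious supra-threshold voxels (`varSampleCorr()`).
3. **Marginal.** The voxel-intensity marginal is a location-scale
   Student's-t with $\nu = 2\alpha$ and squared scale
   $(s/\alpha)\,\sigma^2_x$ — a heavy-tailed generalization of the
   Gaussian assumed by linear connectivity models, converging to it for
   large $\alpha$ (`dGeneralizedT()`, `marginalTParams()`).

The **precision correction** divides every sample by the square root of
its own slice's cross-sectional sample variance at that time point.
Because the slice estimate factorizes as
$\hat\sigma^2_{m,t} \approx \sigma^2_{m,t}\,\sigma^2_m$ (power times a
stationary scale factor), the corrected series equals the stationary
series up to one constant per slice, and pairwise correlation is restored
exactly — correlation is scale-invariant (`estimateSliceVariance()`,
`precisionCorrect()`).

### Parameterization

The inverse gamma is stored as (shape, scale) throughout. A rate-style
specification $IG(\alpha, 1/\beta)$ corresponds to `scale = 1/beta`; the
(shape, scale) convention is the one that makes the marginal's
$\sigma_t^2 = (s/\alpha)\sigma_x^2$ and the mean power $s/(\alpha-1)$
internally consistent, so it is used everywhere, including the simulation
defaults. $\kappa$ is invariant to each process's scale, so analyses that
only involve $\kappa$ are unaffected by this choice. Moments are
evaluated in log-gamma space (`lgamma`) so large shapes do not overflow.

## What the simulators emulate

`generateWhitePairs()` reproduces the package's reference protocol:
2,000 pairs, $T = 500$, underlying correlation $\rho = 0.3$, per-pair
means drawn uniformly from $[-100, 100]$ and stationary variances from
$(0, 10]$ (the variance, not the standard deviation, is drawn — the
choice is inert for correlation, which is scale-invariant). One shared
power realization per slice weights all series assigned to that slice,
mirroring the simultaneous acquisition of a slice's voxels; power
parameters default to being drawn from $[1, 10]$.

A note on means: the analytic attenuation result assumes zero-mean
stationary components. With means up to $\pm 100$ and variances up to 10,
the weighted series is dominated by the term
$\mu\,\sigma_{m,t}$ — a pure power-process signal — and the sample
correlation of weighted pairs collapses toward
$\mathrm{corr}(\sigma_{m,t},\sigma_{n,t}) \approx 0$ rather than
$\kappa\rho$. The correction divides that term away again, so corrected
correlations recover $\rho$ regardless of the means. Accordingly, checks
of the attenuation identity use `meanRange = c(0, 0)`, while checks of
the correction keep the full mean range. This also explains why the
correction "changes signal means": the raw signal, including its mean, is
divided — means are deliberately not re-centred first, and relative
spatial/temporal mean differences are preserved.

`generateVarPairs()` draws a random stable bivariate VAR($p$),
$p \in \{1,2,3\}$: coefficient entries uniform on $[-1,1]/p$, rejected
until the companion-matrix spectral radius is below 0.95. The cap below 1
avoids near-unit-root realizations whose burn-in would be impractically
long; burn-in is $\max(500, \lceil 10p/(1-r)\rceil)$ samples. Pole
placement for a coupled 2×2 system is under-determined, so rejection
sampling with an explicit stability test is used instead. Intercepts are
solved from target means via $\nu = (I-\sum_p A_p)\mu$ so long-run means
land in $[-100, 100]$; innovation covariance has off-diagonal
$\rho\,\sigma_x\sigma_y$.

`generateSyntheticBold()` stands in for experimental data, which the
package cannot ship: it builds a 4D volume of
(tissue baseline + ROI-correlated latent signal + white noise) scaled by
per-slice square-root inverse-gamma power, and returns the full ground
truth. It emulates the features the method addresses — slice-dependent
power, embedded seed connectivity, tissue-dependent baselines — and
deliberately omits physiological waveforms, motion, scanner drift and
spatial autocorrelation from smoothing. Passing tests on this generator
therefore validate the estimator pipeline under the model, not the
model's adequacy for any particular scanner's data. One practical caveat
the tests respect: if a planted ROI's latent signal contributes a large
share of its slice's cross-sectional variance, the slice-variance
estimate absorbs part of the signal and the correction then distorts it;
test volumes keep the ROI share small, which is also the realistic
regime (a seed region is a tiny fraction of a slice).

## The empirical battery

* `rankDistributions()` fits nine families (Weibull, Gaussian, Gamma,
  inverse gamma, three-parameter Student's-t, exponential, log-normal,
  Laplace, Rayleigh) by maximum likelihood and ranks by attained negative
  log-likelihood. Closed-form MLEs are used where they exist; Gamma and
  the t are optimized from moment starts (the inverse-gamma MLE reuses
  the Gamma fit on reciprocals); Weibull uses the 1-D profile likelihood
  in its shape. Ranking is by raw negLL with no complexity penalty, so
  nested families need care in interpretation: the three-parameter t
  contains the Gaussian as its $\nu \to \infty$ limit and will edge it
  out by a sliver on roughly half of all Gaussian samples. Ties are
  broken toward the earlier family in the fixed family order. The
  Student's-t entry is the three-parameter (location-scale) form, so
  that it is comparable with the other location-scale families.
* `adfTest()` runs the augmented Dickey-Fuller regression with a
  constant, no trend, and the $\lfloor (T-1)^{1/3} \rfloor$ lag rule,
  comparing the t statistic against MacKinnon finite-sample critical
  values at $\alpha \in \{0.01, 0.05, 0.1\}$.
* `pairwiseSliceTests()` applies the Wilcoxon signed-rank test to
  time-paired slice-variance differences (slice series share time
  indices; the unpaired rank-sum variant sits behind `paired = FALSE`),
  with normal-approximation p-values and continuity correction — exact
  enumeration is unnecessary at the series lengths involved (hundreds of
  time points). The decision matrix is reported unadjusted at
  $\alpha = 0.01$; no hidden multiple-testing layer is applied.
* `tissueVarianceAssociation()` regresses the whole-volume variance
  series out of both tissue- and slice-variance series before
  correlating residuals, because both are computed from overlapping voxel
  sets; per-slice inverse-gamma MLEs are additionally correlated with
  tissue proportions across slices (Fisher z). With a single global
  power source the regression removes everything — detectable
  associations require slice-resolved structure, which is exactly what
  the analysis is meant to find.

## Connectivity mapping

`correlationMap()` computes per-voxel Pearson correlations with a seed
mean series; zero-variance voxels are dropped with a warning, never
silently imputed. `fisherZThreshold()` standardizes $\mathrm{atanh}(r)$
by $\sqrt{df-3}$ (the standard Fisher variance) and applies a two-sided
Bonferroni threshold at $\alpha/n$, $n$ = in-mask voxels. Autocorrelated
series violate the nominal df; rather than hard-coding any particular
dependent-samples correction, the effective df is a hook
(`effectiveDf`), defaulting to $T$. Saturated voxels ($|r| = 1$) are
flagged significant and counted separately.

## Numerical choices and degenerate inputs

* Cross-sectional variances use the unbiased $n-1$ denominator; the
  constant cancels in correlation.
* `precisionCorrect()` refuses (rather than clamps) slice variances at
  or below the floor (default $10^{-12}$): a zero-variance slice signals
  a masking problem upstream.
* Correction uses each voxel's **own** slice estimate; the corrected
  slice re-estimates to an exactly flat variance, making the operation
  idempotent up to a constant rescale.
* Slice labels are 0-based in every table and error message; the slice
  axis defaults to the third array axis (axial acquisition) and is
  overridable for other slice directions.
* Optimizers are deterministic (fixed starts, no randomness), so
  distribution rankings are reproducible and permutation-invariant.

## Problem sizes used in the validation suite

The test battery runs the pair protocols at full scale (2,000 pairs,
$T = 500$) for the headline checks and at a few hundred pairs for
supporting properties; the distribution-ranking replication uses 100
seeds at 5,000 samples each; null connectivity calibration uses 100
replicates of $16 \times 16 \times 8 \times 200$ volumes. Monte-Carlo
tolerances are three standard errors of the quantity being estimated;
where a whole dataset shares one power realization per slice, the
standard error includes the realization-level term (the delta-method
variance of the time-averaged $\hat\kappa$), not just the pair-level
term.

## Known limitations

* The power process is iid over time; persistent (autocorrelated) power
  would make slice-variance series look non-stationary to the ADF test,
  as real data does, but is not simulated.
* The correction is slice-wise by design; voxelwise non-stationarity is
  unidentifiable without extra structure, and regional corrections are
  a separate, subsequent step.
* Negative (sign-flipping) weight processes are representable in the
  theory ($\kappa$ can be negative) but the simulators only generate
  positive square-root inverse-gamma weights.
* The default df in Fisher-z testing ignores temporal autocorrelation;
  for VAR-like data supply a corrected `effectiveDf`.

## A worked example

```{r, eval = FALSE}
library(slicevar)
ds <- generateWhitePairs(2000, T = 500, rho = 0.3, seed = 1)
w  <- applyPowerWeighting(ds, PowerProcessSpec(2, 2),
                          PowerProcessSpec(3, 2), seed = 2)
cd <- precisionCorrect(w, estimateSliceVariance(w))
c(stationary = mean(pairCorrelations(ds)),
  weighted   = mean(pairCorrelations(w)),
  corrected  = mean(pairCorrelations(cd)))
attenuation(PowerProcessSpec(2, 2), PowerProcessSpec(3, 2),
            rho = 0.3, T = 500)
```
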