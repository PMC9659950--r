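---
title: "Methods: regional homogeneity and seed-based connectivity group analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional homogeneity and seed-based connectivity group analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rehoflow implements a complete two-group resting-state fMRI analysis of
the kind used to ask whether patients who share a primary diagnosis but
differ in a comorbidity (here: obstructive sleep apnea with versus
without mild cognitive impairment, MCI defined by a MoCA score below
26) differ in spontaneous brain activity — and whether those
differences classify the two groups. This vignette documents the
models, the tunable parameters, the synthetic data generator the
package is validated on, and the numerical choices made where the
design was genuinely open.

## The measures

**Regional homogeneity (ReHo).** For each in-mask voxel, the time
series of the voxel and its 26 face/edge/corner neighbours are ranked
and Kendall's coefficient of concordance is computed:

$$W = \frac{\sum_t R_t^2 - n\bar R^2}{K^2 (n^3 - n)/12},
\qquad \bar R = \tfrac{K(n+1)}{2},$$

where $K$ is the realised in-mask neighbourhood size (27 in the
interior), $n$ the number of time points, and $R_t$ the rank total of
time point $t$ over the $K$ series. $W = 1$ for perfectly concordant
tie-free series; under independence $E[W] = 1/K \approx 0.037$. The
formula is implemented as printed, without tie correction (ties in
continuous BOLD data have probability zero); a tie-corrected
denominator is available via `kendall_w(tie_correction = TRUE)`.
Voxels whose mask-restricted neighbourhood falls below `min_k = 7`
are excluded rather than given an unstable $W$.

Single-subject maps go through: raw $W$ on *unsmoothed* residuals →
division by the in-mask global mean (mReHo, removing between-subject
level differences) → 6 mm FWHM Gaussian smoothing → z-standardisation
within the mask (szReHo; in-mask mean 0, population SD 1). The
"Fisher r-to-z" wording sometimes attached to ReHo maps is not
well-defined for a statistic bounded in $[0,1]$ that is not a
correlation, so z-standardisation is the default and an `atanh`
variant is provided behind `reho_pipeline(z_method = "atanh")` for
comparison.

**Seed-based functional connectivity (FC).** Clusters in which ReHo
differs between groups become seed ROIs. Each subject's ROI-mean time
series is correlated with every in-mask voxel (Pearson), and the map is
variance-stabilised with Fisher's $z = \operatorname{atanh}(r)$. FC is
computed on smoothed residuals by convention (toggle via
`fc_pipeline(presmoothed = ...)`); the z-maps are deliberately *not*
re-standardised, so group differences stay in interpretable coupling
units.

## Preprocessing

The chain mirrors standard resting-state practice for data already in a
common grid: discard the first 10 volumes; framewise displacement
(Power formulation, backward differences, 50 mm rotation radius) with
subject exclusion at mean FD above the cohort mean + 2.5 SD; ideal
(frequency-domain rectangular) band-pass 0.01–0.08 Hz with the temporal
mean removed; then linear regression of the Friston-24 motion expansion
plus mean white-matter and CSF signals. Confounds are band-passed with
the same filter before regression so that regression cannot reintroduce
out-of-band nuisance variance; as a consequence the residuals are a
fixed point of the filter (property-tested).

One consequence of the ideal filter deserves emphasis. After
filtering, each voxel's series lives in the pass-band Fourier subspace,
whose dimension is roughly $2 T \cdot \mathrm{TR} \cdot (f_{hi} -
f_{lo})$. At the study scale ($T = 230$ after discarding, TR = 2 s)
that is 64 dimensions and the 26-column confound model is unproblematic.
At strongly reduced $T$ the confounds can span the whole subspace and
the residuals collapse to numerical noise; `preprocess_subject`
refuses to continue when fewer than 4 residual dimensions would remain.
The package's own reduced-scale simulations therefore use motion-free
cohorts (the confound set reduces to WM + CSF) — a deliberate scaling
choice, documented here, that leaves the study-scale configuration
untouched.

## Group inference

Voxelwise two-sample pooled-variance t-tests (df $= n_1+n_2-2$, sign
convention group 1 − group 2) are thresholded two-tailed at voxel
$p < 0.005$ and corrected at cluster level $p < 0.05$ with random-field
theory. Field smoothness is estimated from the standardised residuals
of the group model: per axis, the variance $v$ of spatial first
differences of a unit-variance field gives $\mathrm{FWHM} =
2\sqrt{\ln 2 / v}$ voxels (independent noise thus reads ≈ 1.18 voxels,
a 6 mm kernel at 3 mm voxels reads ≈ 6.5 mm). RESELs = in-mask voxels
/ ∏ per-axis FWHM.

Cluster-level p-values use the expected cluster count $E[m] = R \cdot
\rho_3(u)$ with the *t-field* Euler-characteristic density at the
cluster-forming threshold,

$$\rho_3(u) = \frac{(4\ln 2)^{3/2}}{(2\pi)^2}
  \left(\frac{\nu-1}{\nu}u^2 - 1\right)
  \left(1 + \frac{u^2}{\nu}\right)^{-(\nu-1)/2},$$

the expected suprathreshold volume $E[N] = S\,P(T_\nu > u)$, and the
exponential approximation $P(n \ge k) = \exp(-\beta k^{2/3})$ with
$\beta = (\Gamma(5/2)/E[n])^{2/3}$, giving $p = 1 - \exp(-E[m]\,
P(n \ge k))$. An earlier variant of this package Gaussianised the
t-field before applying Gaussian EC densities; Monte-Carlo null
calibration (200 null cohorts, 24³ grid, $n = 10/10$) showed that
variant to be ~3× conservative, because the Gaussian density
underestimates the number (and so overestimates the typical size) of
excursion clusters of a t field with modest df. With the t-density the
empirical 95 % quantile of the max cluster extent matches theory within
one voxel and the null familywise error lands at 0.03–0.06. Components
use 26-connectivity by default (6/18 available). Two-tailed inference
splits the voxel p symmetrically and processes each tail separately.

Known limitation: at smoothness below ~2 voxels FWHM the lattice
approximation of RFT degrades and the correction becomes conservative;
this is a property of the method class, shared with the standard
neuroimaging toolboxes, and the calibration harness measures it rather
than hiding it.

## Classification

Features are per-cluster means of szReHo (the ReHo-difference clusters)
and of z-FC (the FC-difference clusters), one row per subject —
deliberately reproducing the published procedure, in which feature
selection uses whole-sample group differences *before*
cross-validation. That selection is circular, and LOOCV metrics
produced this way are optimistic; the package reproduces it as
described because the classifier report is descriptive of the
procedure, not a claim of out-of-sample performance. Collinear
features are pruned iteratively: while any pair has $|r| > 0.75$, the
member of the worst pair with the larger mean absolute correlation to
all remaining features is dropped (ties: the later column). A ridge
(L2) logistic model — penalty chosen from a log grid by LOOCV accuracy,
ties toward stronger regularisation — is evaluated by leave-one-out
cross-validation; `lambda = 0` falls back to plain maximum likelihood.
Metrics: confusion-matrix accuracy/sensitivity/specificity at the 0.5
probability threshold, Cohen's κ, and trapezoidal ROC AUC (identical to
the Mann–Whitney U statistic scaled by $n_1 n_0$; property-tested).
The permutation test re-runs the full pruning + grid search + LOOCV
pipeline under label permutations and reports
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(B+1)$ with LOOCV accuracy
as the default statistic (AUC available). With a discrete statistic the
tie-handling makes the test valid but conservative; the calibration
harness therefore checks uniformity of the null p on the AUC statistic.

## Clinical statistics

`required_sample_size()` iterates the noncentral-t power expression
(ncp $= d\sqrt{n/2}$) to the smallest per-group n reaching the target
power — $d = 0.8$, $\alpha = 0.05$, power 0.8 gives 26/group, 52 total.
Normality is assessed with the Lilliefors-corrected one-sample KS test
(estimated parameters; `exact = TRUE` gives the naive KS p); normal
variables are compared with the pooled Student t-test, non-normal ones
with the two-sided Mann–Whitney U (exact for small tie-free samples),
with Bonferroni adjustment over the explicitly stated family size.
`student_t_from_summary()` recomputes t-tests from printed mean ± SD
rows. AHI severity bands are the half-open AASM-style intervals
$[0,5)$, $[5,15)$, $[15,30)$, $[30,\infty)$.

The respiratory scorer computes a moving-average amplitude envelope of
the airflow trace over one breathing period (4 s), a rolling
80th-percentile baseline (180 s window), and scores contiguous spans of
relative reduction: ≥ 90 % sustained ≥ 10 s → apnea; 30–90 % sustained
≥ 10 s with a ≥ 4 % SpO2 drop below its rolling baseline within a 30 s
lag window after the span → hypopnea. The desaturation lag window and
the baseline quantile are configurable; both defaults are stated here
because the clinical definitions leave them open.

## The synthetic cohort generator

No raw data accompany the study the package is modelled on, so every
stage is validated against generated cohorts with known ground truth.
Per subject the signal model is

$$x_v(t) = w\,\ell_{r(v)}(t) + \sqrt{1-w^2}\,\varepsilon_v(t)
 + \text{drift} + \text{motion leakage} + \text{global components},$$

where $\ell_r$ is a shared AR(1) latent per planted region and
$\varepsilon_v$ is AR(1) noise — spatially smoothed (6 mm) outside
effect regions, independent across voxels *inside* them so that the
weight $w$ alone sets the within-region concordance from ≈ 1/K ($w=0$)
to 1 ($w=1$). The impaired group's weight is reduced by the region's
synchrony *drop*: $w_1 = w_0(1-\text{drop})$ — a direct manipulation of
the quantity Kendall's W measures. Seed–target coupling plants
$x = r_g \ell_{\text{seed}} + \sqrt{1-r_g^2}\,\varepsilon$ in the target
with a group-specific $r_g$. WM/CSF-like compartments carry their own
independent voxel noise plus the global components at weight 1 (0.1
elsewhere), so their means estimate the global signals cleanly — an
early variant that let the smoothed grey-matter field leak into the
compartments produced contaminated confound estimates and visible
global FC offsets, which is realistic but defeats validation against a
known truth.

Defaults chosen once for the study conditions: grid 24³ at 3 mm
(desk-scale stand-in for the resampled acquisition grid), $T = 240$,
TR = 2 s, groups 48/47, base synchrony $w_0 = 0.7$, default drop 0.5,
coupling 0.2 (impaired) vs 0.5, AR(1) $\varphi = 0.3$, noise smoothness
6 mm, motion amplitude 1 (random-walk traces, FD linear in amplitude).
Clinical covariates are independent truncated Gaussians with the
published group means/SDs; MoCA scores are integers rejection-sampled
to respect the group-defining cutoff (impaired < 26 ≤ unimpaired), so
labels are always consistent with scores. Independence across clinical
variables is an explicit simplification: only per-variable moments are
published, so covariances are unknowable.

What passing tests on these cohorts shows — and does not. The
generator emulates temporal autocorrelation, spatial smoothness,
motion/tissue nuisance structure, planted local-synchrony and coupling
effects, and cutoff-consistent clinical covariates. It does not
emulate scanner physics, physiological (cardiac/respiratory) signal,
spatial normalisation error, non-stationary smoothness, or
distance-dependent motion artifact; recovery results here bound what
the pipeline can do under its own assumptions, not on arbitrary real
data.

## Problem sizes used in validation

Chosen as the package's own reduced-scale study conditions: the
recovery experiment uses 20 replicate cohorts of $n = 20/20$ subjects,
24³ grid, $T = 64$ motion-free (drop 0.8, coupling 0.2 vs 0.6); the
null calibration uses 200 two-group cohorts of 6 mm-smooth Gaussian
maps ($n = 10/10$); permutation-null calibration uses 50 replicates at
$B = 99$; the oracle comparison runs the naive per-voxel Kendall loop
on a 6×6×6×40 volume. The `analysis/` workflow runs the full chain at
$T = 240$ with motion and the complete confound model on a 20/20
cohort.

## Degenerate inputs and tie-breaks

Constant series rank to all-midranks and are flagged; all-constant
rank matrices return $W = 0$ with a warning. Zero-variance voxels get
$r = 0$ (flagged) in FC maps; $|r| = 1$ is clipped to $1-10^{-7}$
before atanh with a warning. Empty suprathreshold sets yield empty
cluster lists, and a run whose ReHo stage finds no clusters reports
`"no ROIs"` instead of failing. Pruning ties drop the later column;
grid-search ties pick the stronger penalty; LOOCV folds whose training
labels collapse to one class are flagged and scored by the training
base rate.
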