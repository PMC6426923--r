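---
title: "Modelling stage-dependent brain-memory associations on the AD continuum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling stage-dependent brain-memory associations on the AD continuum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Memory decline on the Alzheimer's disease (AD) continuum — from healthy
ageing through amnestic mild cognitive impairment (aMCI) into clinical AD —
is driven by several partially overlapping degenerative processes: grey
matter atrophy in the medial temporal lobe and the default mode network
(DMN) hubs, white matter microstructural damage, extracellular free-water
accumulation (a marker of neuroinflammation and small-vessel damage), and
functional disconnection of the DMN.  Ordinary regression of memory on
brain measures assumes each association is constant across the whole
disease spectrum.  The model implemented here drops that assumption: each
brain measure's association with memory is a smooth function of dementia
severity, indexed by the Clinical Dementia Rating sum-of-boxes (CDR-SB, a
0–18 score in 0.5 steps).

## The model

With memory z-score \(y_i\) for subject \(i\) observed at severity
\(t_i\) and standardized predictors \(x_{ij}\) (six brain measures plus
four nuisance covariates),

\[
y_i = \sum_{j=1}^{p} \beta_j(t_i)\,x_{ij} + \varepsilon_i,
\qquad
\beta_j(t) = \sum_{l=1}^{L} \gamma_{jl} B_l(t),
\]

where \(B_1,\dots,B_L\) is a B-spline basis on the observed severity range
(default \(L = 4\), cubic, no interior knots — i.e. the cubic polynomials
in Bernstein-like form).  Coefficients are estimated by the functional
group LASSO,

\[
\frac{1}{2n}\sum_i \Big[y_i - \sum_j x_{ij}\beta_j(t_i)\Big]^2
+ \lambda \sum_j \sqrt{\textstyle\int \beta_j^2(t)\,dt},
\]

which zeroes *entire* coefficient functions, performing variable selection
jointly with fitting.  Writing \(\Omega_{lm} = \int B_l B_m\,dt\)
(computed exactly by per-span Gauss–Legendre quadrature) and
\(\Omega = R^\top R\), the change of variables
\(\tilde\gamma_j = R\gamma_j\) turns each penalty term into a Euclidean
norm, and the problem becomes a standard group LASSO solved by exact block
coordinate descent (each block update solves its stationarity condition
through the block Gram eigendecomposition and a one-dimensional root
find).  Solutions are certified by a KKT residual check.

\(\lambda\) is chosen by five-fold cross-validation over 50 log-spaced
values from the full-shrinkage bound \(\lambda_{max}\) down to
\(10^{-3}\lambda_{max}\); ties resolve to the larger (sparser) value.
The outcome is centred before fitting (the model has no intercept) and
every predictor — nuisance covariates included — is standardized and
penalized identically.

Replicate stability is assessed by refitting the entire pipeline
(including CV) on resampled data — nonparametric bootstrap over subjects
by default, with subsampling and CV-refitting available — and reporting
pointwise means, standard errors, and per-predictor selection counts; a
predictor is *stably selected* when it is selected in every replicate.
Specificity is assessed by permuting the memory scores across subjects and
repeating the whole stability analysis per permutation: on permuted data
the modal outcome should be an empty stable set.

## Design choices that were genuinely open

* **Measure of the penalty integral.**  \(\int\beta_j^2\) is taken with
  Lebesgue measure on the observed severity range (not the empirical design
  measure); this matches the quadrature identity tested in the suite.
* **One observation per subject.**  The severity index is cross-sectional,
  so the double sum over subjects and visits collapses; the API
  nevertheless accepts repeated severities (ties are common on the 0.5
  CDR-SB grid).
* **Replicates as bootstrap.**  "Replicates" are nonparametric bootstrap
  resamples by default.  A bootstrap draw of a cohort with a rare binary
  covariate (a handful of left-handers) can make that column constant; such
  a replicate treats the column as uninformative (all-zero after centring,
  never selectable) rather than failing.
* **CV numerical tolerance.**  Fold paths run at a block-update tolerance
  of 1e-5 (held-out MSE is insensitive to the trailing digits); the final
  fit uses 1e-7 with a 10^4-sweep cap and reports its KKT residual.
* **Trajectory reporting.**  Fitted trajectories are reported on the
  observed severity range only; extrema beyond CDR-SB 10 are flagged
  low-support, since few subjects occupy the severe tail.

## The synthetic world

No clinical data ship with the package; every analysis is exercised on a
seeded synthetic cohort designed to match the published study population:

* **Groups.**  151 subjects by default — 51 healthy controls (CDR-SB
  exactly 0), 54 aMCI (CDR-SB in [0, 4), the diagnostic rule), 46 AD
  (CDR-SB in [4, 18]).  Severities are truncated normals with the
  published group mean/SD (aMCI 0.8 (0.8), AD 6.7 (2.8)), rounded to the
  instrument's 0.5 step.  Because the published values parameterize the
  *untruncated* normal, left-truncation at 0 raises the realized aMCI mean
  to about 1.0; calibration tests therefore compare against the exact mean
  of the rounded truncated distribution rather than the nominal value.
* **Generating trajectories.**  Each coefficient function is encoded as
  control points joined by monotone (Fritsch–Carlson) cubic interpolation,
  which cannot overshoot — so the published peak effects are attained
  exactly at a control point: free water trough \(-0.9\) in early aMCI
  with a milder re-deepening at AD severities, fornix FA\(_T\) and mPFC
  volume peaks of 4.5 and PCC 1.4 early, hippocampal volume peaking at 2.4
  near the aMCI/AD boundary, DMN connectivity constant at 1.0 (a value in
  the "comparable positive betas" range; the study reports no number), and
  four identically-zero nuisance trajectories.  Control points were placed
  once so that each trajectory's projection onto the \(L = 4\) cubic model
  class — the class the fitted curves themselves live in — preserves the
  peak; effects plateau through the aMCI range and decay in the AD range,
  as the study's results describe.
* **Brain measures.**  Each measure follows a monotone deterioration mean
  in plausible native units (e.g. free-water fraction rising from 0.15,
  fornix FA falling from 0.50) plus independent Gaussian noise scaled so
  that measure-severity correlations land between roughly 0.3 and 0.45 —
  typical for clinical ROI data and strong enough collinearity to make the
  joint model non-trivial without destroying identifiability.
* **Residual noise.**  The study does not state the outcome's residual
  SD; the default is 0.5 memory-z units, consistent with the strongly
  determined regime implied by standardized effect sizes as large as 4.5.
  This is the package's choice, documented here, not a published value.

What a green recovery test establishes: that the full pipeline
(standardization → basis → CV → group LASSO → trajectory evaluation)
recovers the generating stage-dependent effects from data with the stated
design. What it does not establish: robustness to features of real
imaging cohorts that the generator deliberately omits — site effects,
measurement error correlated across ROIs, non-Gaussian outcomes,
longitudinal dependence, or selection into the study.

## Free-water imaging

The diffusion module fits the two-compartment (bi-tensor) model per voxel:

\[
S(g, b) = S_0\left[ f\,e^{-b d_{free}} + (1-f)\,e^{-b\,g^\top D g}\right],
\qquad d_{free} = 3\times10^{-3}\,\mathrm{mm^2/s},
\]

with \(f\) the free-water fraction (the FW map) and FA\(_T\) the
fractional anisotropy of the tissue tensor \(D\).  With a single shell
(b = 1150 s/mm², 61 directions, 7 b0) the model is only identifiable with
constraints: the tissue tensor is kept positive semidefinite with mean
diffusivity in [0.1, 2.0]×10⁻³ mm²/s, and the fit profiles the residual
over \(f\) (grid then golden-section refinement) with an inner log-linear
tensor fit — variable projection.  A tiny quadratic penalty pulls the
tissue mean diffusivity toward 0.7×10⁻³ mm²/s (typical healthy white
matter); it is negligible wherever the data identify the fit and acts only
on the isotropic ridge, where single-shell data cannot separate \(f\) from
an isotropic tissue compartment at all.  This stands in for the spatially
regularized estimation of the original free-water method, which is out of
scope here.  Fitting is Gaussian least squares; Rician noise is available
in the simulators.

## Screening

The region-identification step regresses each voxel of a subject-stack of
maps on memory (age, gender, handedness, ethnicity as covariates) and
controls the familywise error by permutation of the covariate-residualized
outcome (Freedman–Lane style), with three interchangeable corrected
statistics: the maximum |t| (maxT), threshold-free cluster enhancement
(TFCE, E = 0.5, H = 2, dh = max/100, 26-connectivity — the method's
canonical defaults), and cluster-level inference at a height threshold
(p < 0.01 two-sided by default, the published cluster-forming rule) using
cluster *mass* — summed |t| excess over the threshold — as the statistic,
because the max-extent null at desk-scale sample sizes is concentrated on
a handful of tied small sizes and extent-based permutation p-values are
then badly conservative.  The published
analysis used Gaussian-random-field corrections for two of its three
modalities; permutation analogues replace them here (exact at this scale,
no smoothness estimation) and the substitution is recorded in the run
report's deviations log.  Subject means over significant masks feed the
varying-coefficient model.

Because no NIfTI reader is available in this environment, volumes are
plain R arrays (x, y, z[, subject]); gradient tables use the FSL
bval/bvec text dialect.

## A worked run

```{r, eval = FALSE}
library(adcontinuum)

cfg <- run_config(n_total = 151, seed = 1, n_rep = 20)
rep <- run_pipeline(cfg)
print(rep)

# severity-dependent coefficient trajectories with bootstrap bands
plot(rep$bands, predictors = c("FW", "FA_T_fornix", "GMV_HIP"))

# specificity of the selection rule on permuted outcomes (scaled down;
# the published profile is 100 x 100)
spec <- permutation_specificity(simulate_svc_dataset(151, seed = 1)$obs,
                                svc_config(), n_perm = 20, n_rep = 20,
                                seed = 9)
print(spec)
```

## Known limitations

* Single-shell free-water fitting is intrinsically degenerate for
  isotropic tissue; the MD-prior tie-break resolves it deterministically
  but the returned \(f\) there reflects the prior, not the data.
* The cubic \(L = 4\) coefficient class cannot represent more than two
  interior extrema per trajectory; sharper or multi-phase severity
  profiles will be smoothed.
* Trajectory estimates beyond CDR-SB ≈ 10 rest on very few subjects and
  are flagged low-support rather than suppressed.
* The permutation screening assumes exchangeable subjects under the null;
  exchangeability blocks (e.g. for family structure) are not implemented.
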