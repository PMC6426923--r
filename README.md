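# adcontinuum

Stage-dependent modelling of brain–memory associations along the
Alzheimer's disease (AD) continuum.

Most studies relate brain measures to memory with ordinary regression,
which assumes one constant association across the whole disease spectrum.
`adcontinuum` implements the alternative: a **sparse varying coefficient
(SVC) model** in which each brain measure's association with memory is a
smooth function of dementia severity (CDR sum-of-boxes, `t`),

```
y_i = Σ_j β_j(t_i) x_ij + ε_i,      β_j(t) = Σ_l γ_jl B_l(t),
```

estimated with a functional group-LASSO penalty
`λ Σ_j sqrt(∫ β_j(t)² dt)` that zeroes entire coefficient functions, so
fitting and variable selection happen jointly.  `λ` is chosen by five-fold
cross-validation; stability bands and selection frequencies come from 100
bootstrap replicates; specificity from re-running the whole analysis on
outcome-permuted data.

Around the core model the package provides the full analysis pipeline:

* `freewater` — per-voxel bi-tensor free-water elimination for
  single-shell diffusion MRI (fixed free diffusivity 3×10⁻³ mm²/s),
  yielding FW and FA_T maps;
* `screening` — mass-univariate voxelwise GLMs with permutation-based
  familywise-error control (maxT, TFCE, cluster extent) and ROI mean
  extraction;
* `synthetic_data` — seeded generators for the three-group cohort
  (HC/aMCI/AD with diagnostic CDR-SB bounds), brain measures, memory
  outcomes, diffusion voxels/phantoms, and 3D effect maps, so everything
  is testable without clinical data;
* `pipeline` — config-driven orchestration with stage caching and a
  deterministic JSON report.

Volumes are plain R arrays (no NIfTI dependency is available in this
environment); gradient tables use the FSL bval/bvec text dialect.

## Worked example

```r
library(adcontinuum)

# a synthetic 151-subject cohort with the published group structure
dat <- simulate_svc_dataset(n_total = 151, seed = 1)
fit <- fit_svc(dat$obs, svc_config(seed = 1))
print(fit)
#> Sparse varying coefficient fit
#>   subjects: 151  predictors: 10  basis L: 4
#>   lambda (5-fold CV): 0.01024
#>   selected: FW, FA_T_fornix, GMV_mPFC, GMV_PCC, GMV_HIP, FC_DMN, gender, handedness, ethnicity

beta <- evaluate_trajectories(fit)
head(attr(beta, "peaks"), 3)
#>     predictor peak_beta peak_t
#> 1          FW -1.140572    6.5
#> 2 FA_T_fornix  4.248920    2.1
#> 3    GMV_mPFC  4.477263    2.5
```

The peak table gives each predictor's strongest association with memory
and the severity at which it occurs: fornix FA_T and mPFC volume show
their strongest protective associations (positive betas) in early aMCI;
free water's association is negative throughout, though at n = 151 its
trough location is noisy — at `n = 1000` the estimates tighten onto the
generating trajectories (FW trough ≈ −0.9 in early aMCI).  Bootstrap
bands and selection stability:

```r
bands <- stability_replicates(dat$obs, svc_config(), n_rep = 100, seed = 2)
plot(bands, predictors = c("FW", "GMV_HIP"))
```

## Acceptance script

`scripts/acceptance.R` regenerates the synthetic reference scenario from
scratch, runs the full SVC pipeline at n = 1000, and reports the signed
extrema of the recovered coefficient trajectories plus the severity-bound
checks of the cohort generator:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness is driven by `--seed`; the JSON maps target ids to the
recomputed values and the problem sizes used.
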