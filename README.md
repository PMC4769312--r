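# neuropet

Quantitative multimodal brain-PET analysis at desk scale: parametric cerebral
blood flow (CBF) mapping from dynamic ¹⁵O-water PET, relative-perfusion
mapping from ¹⁸F-FDDNP PET, and the spatial-normalization machinery needed to
report both through a common anatomical atlas — including symmetric
diffeomorphic registration that stays well-behaved on brains with focal
lesions.

It is aimed at imaging methodologists who want a fully inspectable,
dependency-light R implementation of this workflow, exercised end to end on a
deterministic digital brain phantom rather than patient data: every estimator
in the package can be run against inputs whose ground truth is known.

## What it computes

**Water kinetics.** Tissue tracer concentration follows the one-tissue
compartment model

    dC_T/dt = K1 C_b(t) − k2 C_T(t),     C_ROI(t) = C_T(t) + Vb C_b(t)

with delivery rate `K1` (the CBF surrogate; CBF = K1/E × 100 mL/100 g/min with
first-pass extraction `E = 0.85`), clearance `k2`, and vascular fraction `Vb`.
The measured arterial input is first corrected for delay and dispersion by a
grid search that minimizes the whole-brain fit residual. Voxel-wise maps come
from a linearized operational-equation fit with a spatially constrained ridge
second pass.

**FDDNP kinetics.** Without blood sampling, the simplified reference tissue
model (SRTM)

    C_T(t) = R_I C_R(t) + (k2 − R_I k2/(1+BP)) C_R(t) ⊗ e^{−k2/(1+BP) t}

is fitted per voxel by the basis-function method: 100 rates
θ = k2/(1+BP) spaced logarithmically in [0.00636, 1] min⁻¹, a weighted linear
fit per rate, and minimum-residual selection. `R_I` is the relative-delivery
(perfusion) surrogate; an early-summed image normalized by cerebellar gray
matter gives the companion ratio map `R_P`.

**Registration.** Summed PET images are rigidly co-registered to the
structural image by mutual-information maximization. The structural image is
matched to a template by greedy symmetric diffeomorphic normalization (SyN):
two half-warps meet at a midpoint, driven by a localized cross-correlation
metric with analytic gradients, regularized by Gaussian smoothing, over an
8/4/2/1 resolution pyramid. Focal lesions are handled as missing data
(constrained cost-function masking): lesion voxels never touch the metric and
the deformation inside the lesion is inpainted smoothly from its
surroundings, so the result is provably independent of lesion content.
Forward and inverse maps are returned, concatenated transform chains resample
atlas labels into PET space with a single interpolation, and regional
statistics plus Bland–Altman agreement (`bias ± 1.96 SD`) complete the
report.

**Phantom.** `phantom_spec()` / `make_phantom()` build a 128×128 labelled
head (13 gray-matter regions including the cerebellar reference, white-matter
core, ventricle, textured scalp), `synth_input()` a gamma-variate arterial
input, and `simulate_dynamic()` frame-averaged noisy dynamic PET for either
tracer from the same forward models the estimators invert.

## Worked example

```r
library(neuropet)

cfg <- make_phantom_bundle("bundle", phantom_spec(noise_percent = 3),
                           lesion = TRUE)
res <- run_workflow(cfg)
print(res$stats$CBF)
#> region_stats [ mL/100g/min ]
#>  region    n  mean     sd       units
#>     FRT  584 32.78 4.3656 mL/100g/min
#>     PAR  646 32.86 3.0755 mL/100g/min
#>    ...
#>     CGM  903 33.29 2.7585 mL/100g/min
#>     SWM 3037 20.35 2.1372 mL/100g/min
#>    WBGM 3959 32.54 0.4849 mL/100g/min
res$gray_white_ratio
#> [1] 1.599
print(res$agreement$R_I)
#> bland_altman (n = 14): bias 0.0198, SD 0.0139, LoA [-0.0075, 0.0470]
```

The phantom generates gray matter at 33 and white matter at
20 mL/100 g/min; the pipeline-recovered regional means (32.5 and 20.4 above,
ratio 1.60 vs the generating 1.65) quantify the whole chain — simulation,
registration, label propagation and kinetic fitting — in one number. The
Bland–Altman block compares the FDDNP relative-delivery map against
normalized CBF across the 14 reporting regions.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/neuropet.R phantom bundle --seed 1 --noise 3
Rscript inst/cli/neuropet.R run bundle/config.yaml
```

## Layout

| Path | Contents |
|---|---|
| `R/core_io.R`, `R/geometry.R`, `R/curves.R` | NIfTI/TSV readers and writers, frame schedules, blood and tissue curves |
| `R/water_kinetics.R` | one-tissue model, delay/dispersion correction, ridge parametric maps, CBF conversion |
| `R/srtm_kinetics.R` | SRTM forward model, basis sets, voxel and map fits, early-sum ratio |
| `R/field_ops.R`, `R/registration.R` | deformation fields, MI rigid registration, greedy SyN with lesion masking |
| `R/atlas_roi.R`, `R/agreement_stats.R` | label propagation, regional statistics, Bland–Altman, CV |
| `R/phantom.R`, `R/pipeline.R` | digital phantom and the config-driven workflow |
| `vignettes/methods.Rmd` | model assumptions, parameter choices, validation design |
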