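---
title: "Models, numerics and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, numerics and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the scientific and numerical choices behind the
package: the models and their assumptions, the parameters that matter and
why they default to what they do, what the digital phantom does and does not
emulate, and the places where the design was genuinely open and a decision
had to be made.

## Kinetic models

### One-tissue water model

¹⁵O-water is freely diffusible, so a single tissue compartment suffices:

$$\frac{dC_T}{dt} = K_1 C_b(t) - k_2 C_T(t), \qquad
  C_{ROI}(t) = C_T(t) + V_b\, C_b(t).$$

`K1` (1/min) is the delivery rate constant and the CBF surrogate, `k2`
(1/min) the clearance, and `Vb` (unitless, 0–1) the fractional blood volume
whose intravascular activity the scanner cannot separate from tissue.
Assumptions: the tracer is not metabolized in tissue on the 10-min time
scale, the input is the same everywhere up to delay/dispersion, and frames
measure time-averaged concentration (the model is therefore frame-averaged
before any comparison with data, which matters for the 5-s frames during the
bolus peak).

`flow_map()` converts K1 to CBF as `K1/E × 100` mL/100 g/min with tissue
density 1 g/mL. The extraction fraction is exposed because the literature
uses both conventions: `E = 0.85` (the default here, the first-pass
extraction of water) treats K1 as the product of flow and extraction, while
`E = 1` reports K1 itself as CBF. Both the raw K1 map and the converted map
are always available.

### Arterial delay and dispersion

The curve sampled at the wrist lags (delay Δt) and is smeared (dispersion,
monoexponential kernel `g_τ(t) = (1/τ) e^{-t/τ}`) relative to the input the
brain sees. `correct_delay_dispersion()` grid-searches Δt ∈ [−10, 20] s in
0.25 s steps and τ ∈ [0, 20] s in 0.5 s steps, scoring each candidate by the
residual of a one-tissue fit to the whole-brain curve. Numerical
deconvolution is avoided: the monoexponential kernel has the exact analytic
inverse `true = m + τ dm/dt`, applied on the fine grid after shifting by
−Δt. The sharpening is linear in τ, so the design columns of the inner
linearized fit split into shift-only and derivative parts computed once per
delay, making the 121 × 41 scan cheap.

The linearized inner fit carries a small frame-discretization floor that can
blur the minimum between neighbouring candidates, so the best 60 candidates
are re-scored with the exact frame-averaged nonlinear model (single
warm-started bounded fit each) and the winner is returned together with a
final nonlinear polish of the whole-brain parameters. On a noiseless
whole-brain curve with a densely sampled input this recovers a (6 s, 5 s)
degradation exactly at grid resolution. With only the 15 clinical blood
samples the dispersion constant is weakly identified — the sharpened
piecewise-linear curve is a crude representation of the true input — and τ
can be overestimated while leaving the fitted K1 essentially unbiased (K1
depends mostly on the input integral, which sharpening preserves). This is a
known limitation of sparse arterial sampling, not of the search.

### Voxel-wise maps: linearized fit with spatial ridge

Integrating the model equation gives the operational form

$$C(t) = P_1 \int_0^t C_b - P_2 \int_0^t C + P_3 C_b, \qquad
  P_1 = K_1 + k_2 V_b,\; P_2 = k_2,\; P_3 = V_b,$$

linear in `P` and solvable per voxel by weighted least squares — the only
formulation fast enough for 10⁴–10⁵ voxels. The published description of the
spatially constrained ridge that follows it does not pin down a formula, so
the package implements a fully specified, testable variant: a first
unpenalized pass; Gaussian smoothing of the first-pass maps (FWHM 2 voxels)
into a prior `P_s`; then per voxel a ridge solve
`(XᵀWX + h) P = XᵀWy + h P_s` with the per-component weight
`h = wrss_voxel / (local variance of the first pass + ε)`. Voxels where the
data fit well and the neighbourhood is flat are pulled strongly toward the
prior; voxels with genuine structure (high local variance) are left alone;
`h → 0` reduces exactly to the unpenalized estimator, which is what the
equivalence test exploits. All-zero voxels are returned as exact zeros, and
rare singular voxels are excluded from the prior instead of poisoning it.

Fit weights are proportional to frame duration throughout (the acquisition
counts statistics scale with duration; the original description is silent on
the weighting, so it is configurable through the curve objects).

### SRTM and the basis-function method

For ¹⁸F-FDDNP no blood is sampled; the cerebellar gray matter — essentially
free of specific binding — serves as reference:

$$C_T(t) = R_I C_R(t) + \Bigl(k_2 - \frac{R_I k_2}{1+BP}\Bigr)\,
  C_R(t) \otimes e^{-\theta t}, \qquad \theta = \frac{k_2}{1+BP}.$$

Assumptions: exchange between free and non-specific compartments is fast
(one apparent tissue compartment), and target and reference share the
non-displaceable distribution volume. For fixed θ the model is linear in
`(α₁, α₂) = (R_I, k2 − R_I θ)`, so the fit runs over a fixed grid of 100 θ
values spaced logarithmically in [0.00636, 1] min⁻¹ — the spacing makes the
relative quantization error uniform (≈ 5.2 % per step) — and keeps the
minimum-residual rate. Ties resolve to the smaller θ for determinism.
`α₂` is deliberately unconstrained: negative estimates (BP < 0) are
reported rather than clipped, and collinear designs are flagged, not filled.
The basis is built once per image and shared by all voxels, which is what
makes the voxel loop a handful of matrix products.

`R_P`, the early-summed image normalized by its cerebellar mean, needs no
model at all and is insensitive to whether the window is summed or averaged
(the normalization cancels the constant).

## Common numerics

All convolutions run on a uniform fine grid with step 0.01 min. The
convolution with `e^{-kt}` uses the exponential-integrator recurrence that
is *exact* for piecewise-linear inputs, so agreement with a stiff ODE solver
is limited only by the solver tolerance (the test asserts 10⁻⁶ relative).
Blood and reference curves are linearly interpolated and taken as zero
before their first sample; frame averages are computed from the cumulative
trapezoid integral of the fine-grid curve. Schedules are stored in seconds,
the kinetic axis is minutes, and the conversion lives in one place.

## Registration

### Greedy symmetric scheme

The normalization estimates two half-warps φ₁, φ₂ (and their inverses) that
carry source and target to a common midpoint, so the output cannot depend on
which image is called "source" — the forward map is φ₂⁻¹∘φ₁ and the inverse
φ₁⁻¹∘φ₂, and swapping the inputs exchanges the roles exactly (the test
demands ≤ 0.2 voxel mean agreement; in practice the runs agree to ~10⁻⁷
because every update is computed symmetrically). Rather than integrating a
time-dependent velocity field against the geodesic energy, the
implementation takes the greedy route used in practice: per iteration,
localized cross-correlation forces for each side, Gaussian "fluid" smoothing
of the update (σ = 3 voxels), a step cap of 0.25 voxel, composition into the
half-warp, and a light "elastic" smoothing of the total field
(σ = 0.5 voxel) that realizes the `(a∇² + bI)⁻¹`-type regularization
approximately. The geodesic energy itself is never evaluated — a deliberate
approximation, matching the practical implementations this design follows.

The similarity is the localized *squared* cross-correlation over a
(2r+1)^d window (r = 4 by default; the window size is a free choice, never
stated in the sources this follows), computed from window sums so each
iteration costs a few box filters. Its gradient with respect to the image is
derived exactly — including the window-mean terms — and verified against
central differences to 10⁻³; the mean-subtraction makes the metric invariant
to affine intensity maps, which is why neither bias-field correction nor
intensity normalization is needed upstream.

Iterations are accepted into the recorded trace only when the score does not
decrease (the trace is therefore monotone), but a worse iterate is *kept*
with a halved step rather than reverted: the first step away from the crisp
zero-displacement state always pays a small interpolation-blur penalty, and
reverting would deadlock there. Each level stops when the best score has
improved by less than 10⁻⁶ over the last 10 iterations, or at 250
iterations, over a 8/4/2/1 decimation pyramid. Positive Jacobians are
enforced by step halving and verified on every emitted field; inverses come
from the standard fixed-point iteration (20 sweeps or mean update
< 0.01 voxel).

### Lesions as missing data

With a lesion mask, masked voxels are excluded from every window sum and the
update field inside the lesion is replaced by diffusion inpainting (50
Jacobi sweeps with the exterior held fixed) — the lesion is carried along by
a smooth extension of the surrounding deformation instead of being matched.
Bit-exact invariance to lesion content requires more than zeroing the
gradient: any voxel whose interpolation stencil or pyramid-smoothing kernel
touched the lesion is treated as contaminated (the mask is warped and
downsampled with the *same* operators and thresholded at zero), and image
gradients are taken on the masked image so boundary derivatives cannot read
lesion intensities. The same exclusion is applied to the fixed image in the
rigid mutual-information stage, so the whole pipeline's outputs are
invariant — the acceptance suite checks bit-identical deformation fields and
identical region statistics after randomizing every voxel inside the mask.

### Transform bookkeeping

All transforms act by pull-back: a field `u` resamples `I(x + u(x))`, in
voxel units of the fixed grid. Chains are composed into a single field
before resampling, so an atlas travels template → subject → PET with one
interpolation; labels always use nearest-neighbour. Rigid transforms are
stored as rotation-about-center plus translation and invert analytically.
The package assumes chain members share a common grid shape (true for the
phantom workflow); general cross-geometry resampling through world
coordinates is out of scope.

## The phantom: what it emulates, what it does not

The phantom provides every input the pipeline consumes, with known ground
truth: a 128 × 128 labelled head slice (four cortical sectors, eight
subcortical nuclei, white-matter core, ventricle, cerebellar reference — 14
reporting regions; a textured scalp/skull layer surrounds the brain because
whole-head images are what registration actually sees, and featureless air
would make the deformation unidentifiable outside the brain); a
gamma-variate arterial input `A(t−t₀)^α e^{−(t−t₀)/β}` with a small
recirculation tail, sampled either finely or at the 15 clinical sample
times; dynamic series on the 26-frame water and 20-frame FDDNP protocols;
smooth random deformations (amplitude-scaled, boundary-tapered,
positivity-checked, with 25 landmark pairs); and ellipsoidal lesions.

Defaults are the study conditions: gray-matter flow 33 and white-matter
20 mL/100 g/min (`K1 = E·CBF/100`, `k2 = K1/0.9` for a 0.9 partition
volume, `Vb` 4 %/2 %), FDDNP relative delivery tracking the flow ratio and
binding potential 0.2–0.3 with a binding-free reference, proportional
Gaussian noise with per-frame SD scaled by `sqrt(dur_max/dur_f)` to emulate
count statistics (3 % default in the bundled workflow, 5 % in the recovery
tests). Noise is applied in image space — reconstruction physics (PSF,
scatter, sinogram Poisson statistics, motion) is not simulated, and the
2-D slice has no out-of-plane effects. Passing tests therefore demonstrate
the correctness and internal consistency of the estimators and the
registration machinery under controlled conditions; they do not certify
accuracy on scanner data, where partial-volume effects and reconstruction
correlations are substantially harsher. A 3-D code path exists (tests run
24³–32³) but the shipped workflow is 2-D for tractability.

Problem sizes were chosen so the whole suite runs in minutes on one CPU:
500-voxel regions for noisy-recovery statistics, the full 128² phantom for
registration and the pipeline.

## Resolved open questions

- Whether reported CBF is `K1` or `K1/E`: both are emitted; `E` defaults to
  0.85 and is configurable.
- Fit weights for the "weighted" least squares: frame durations.
- Whether the ridge operated on the linearized or nonlinear estimator:
  linearized (the only tractable voxel-wise choice), with the data-driven
  per-voxel penalty described above.
- Blood samples are assumed decay-corrected to injection time; the flag is
  carried but no correction is applied.
- `R_P` normalization by sum vs mean: irrelevant to the ratio; the mean of
  the summed image over the reference mask is used.
- Whole-brain gray matter (WBGM) is the unweighted mean of the 13
  gray-region means, not a voxel-pooled mean.
- Bland–Altman limits use the sample (n−1) SD, differences are
  first-minus-second.

## Known limitations

- Dispersion is weakly identified from 15 blood samples (see above); the
  delay remains well determined and parameter bias is negligible.
- Region statistics at 1.5 mm voxels include boundary voxels whose labels
  are misplaced by sub-voxel registration error; with a 33:20 gray:white
  contrast this biases the recovered gray/white ratio a few percent low
  (no partial-volume correction is attempted, by design).
- The greedy scheme approximates the geodesic formulation; the reported
  similarity trace is the only energy it monitors.
- Mutual information carries the usual `(bins−1)²/2N` sampling bias, visible
  when images are small relative to the 32² histogram.
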