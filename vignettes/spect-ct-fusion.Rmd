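---
title: "Fusing SPECT and CT brain images with NSCT, PCNN and frog-leaping optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing SPECT and CT brain images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectfuse)
```

## The problem

A SPECT scan carries functional information (perfusion, tracer uptake) as a
smooth, low-resolution pseudo-color image; a CT scan of the same head carries
anatomy — skull, tissue interfaces — as sharp grayscale. Clinicians reading
the pair benefit from a single image that keeps SPECT's color semantics while
inheriting CT's spatial detail. `spectfuse` fuses a *registered* pair (same
pixel grid; registration itself is out of scope) and quantifies the result
with four reference-free quality metrics.

## The pipeline

1. **IHS split of the SPECT image.** We use the linear triangular IHS model:
   intensity `I = (R+G+B)/3`, chroma coordinates `v1 = (2B−R−G)/√18` and
   `v2 = (R−G)/√2`, hue `H = atan2(v2, v1)`, saturation `S = √(v1²+v2²)`.
   This variant is chosen because it is an orthogonal *linear* map with an
   exact algebraic inverse — essential, since we put a modified intensity
   back through the inverse. On the gray axis `S = 0` exactly and `H` is
   conventionally 0, which keeps the inverse well defined. When the fused
   intensity pushes a pixel outside the RGB cube, we clip and count: a global
   rescale would shift the hue balance of every other pixel.

2. **NSCT decomposition** of the SPECT intensity and of the CT image
   (both on the [0, 1] scale). The non-subsampled pyramid splits the running
   lowpass at level *j* with the base filters dilated by `2^(j−1)`
   (à-trous scheme); each bandpass ring is split into `2^(n_j)` directional
   wedges by a binary tree of fan-filter pairs. Nothing is decimated, so
   every band is full-size and the transform commutes with translation away
   from the (mirror-extended) borders.

3. **PCNN coefficient selection.** For each matching band pair, both bands
   drive a pulse-coupled neural network (one neuron per pixel, stimulus =
   `|coefficient|` affinely rescaled to [0, 1]); per pixel the coefficient
   whose neuron fired strictly more often over `T` iterations is taken; equal
   counts average the two coefficients, which makes fusing a band with itself
   an exact identity and keeps the rule symmetric in its inputs.

4. **Parameter tuning.** The three free neuron parameters
   `(α_θ, β, V_θ)` are tuned per band by the shuffled frog-leaping algorithm
   maximizing a band objective, then the band is fused with the winner.

5. **Inverses.** Inverse NSCT yields the fused intensity `I′`; inverse IHS
   with the untouched `H`, `S` yields the fused color image.

## The neuron model

The model is the widely used *simplified* PCNN — no feeding leak, unit
feeding gain, a single linking compartment:

```
L[n] = W ⊛ Y[n−1]                        lateral linking
U[n] = S · (1 + β · L[n])                internal activity
Y[n] = 1  where  U[n] > e^(−α_θ) · θ[n−1]   (strict inequality)
θ[n] = e^(−α_θ) · θ[n−1] + V_θ · Y[n]
```

with `Y[0] = 0`, `θ[0] = 0`. The threshold is decayed *before* the
comparison, so a neuron with constant stimulus `S = 0.5`, `β = 0`,
`α_θ = ln 2`, `V_θ = 2` follows the orbit θ: 0 → 2 → 1 → 0.5 → 2.25 → 1.125
and fires at `n ∈ {1, 4}` in five iterations — this hand trace is locked in a
test, together with an exact comparison of the vectorized engine against a
naive scalar-loop oracle. Conventions worth noting:

* `θ[0] = 0` means every neuron with `S > 0` fires at `n = 1`; ties
  (`U = θ`) never fire.
* The firing statistic is the **cumulative count** over `T` iterations, not
  the first firing time: counts are bounded (`≤ T`), integer, and the
  standard activity measure for PCNN fusion.
* Defaults: `W` is the 3×3 inverse-distance kernel (1 on edge neighbours,
  `1/√2` on diagonals, 0 centre), `T = 100` for standalone use; the fusion
  pipeline default is `T = 50`, and the examples in this package use smaller
  `T` where the test sizes make the extra iterations uninformative.

## The optimizer

Fitness is maximized over the box `α_θ ∈ [0.01, 1]`, `β ∈ [0, 1]`,
`V_θ ∈ [1, 50]` (typical simplified-PCNN operating ranges; fully
configurable). Each shuffle round deals the descending-sorted population
round-robin into `m` memeplexes; within a memeplex the worst frog leaps

```
S_j      = rand() · (P_b − P_w)   clamped to [−S_max, S_max] per coordinate
P_w,new  = P_w + S_j
```

accepting only in-bounds, strictly improving candidates; on failure the leap
is retried toward the global best, and if that fails too the worst frog is
replaced by a fresh uniform random frog. Two details are deliberate:

* **`rand()` is drawn per coordinate by default.** With a single scalar draw
  every candidate lies on the *line segment* between `P_w` and `P_b`; as the
  population converges it collapses onto a one-dimensional manifold and
  late-stage refinement stalls (on the 3-D sphere benchmark only 6/10 seeds
  reach 1e−2 with the scalar draw, versus 10/10 with per-coordinate draws).
  The scalar variant remains available via `per_coordinate_rand = FALSE`.
* **Out-of-bounds candidates are rejected, not clipped**, which treats the
  feasible domain as a membership test and triggers the cascade.

A replacement can cost up to three fitness evaluations (candidate, retry,
random frog), so the per-round budget is at most `3·m·N` plus the initial
population scoring; an evaluation counter asserts this bound in the tests.

## The band objective

The objective the optimizer maximizes on each band pair is **the entropy of
the fused band** linearly remapped to 8 bits. Among the four quality metrics
this is the one most directly improved by a better coefficient selection and
it needs no reference image; it is also the metric on which tuning has the
clearest headroom over fixed parameters. `"gradient"` (mean gradient of the
remapped band) and `"entropy_gradient"` (equal-weight blend, each term
normalized to [0, 1]) are selectable alternatives. Optimization runs per band
by default; `shared_optimization = TRUE` tunes once (on the low band) and
reuses the parameters, trading quality for speed. With
`inject_fixed = TRUE` the fixed baseline parameters join every initial
population, so by best-ever tracking the tuned objective can never fall below
the fixed-parameter baseline — a property the test suite asserts band by
band.

The low-frequency band is fused with the same tuned PCNN rule by default; a
regional average-energy rule (choose the coefficient whose 3×3 neighbourhood
carries more energy) is available as `low_rule = "energy"` for users who
prefer a classical smooth-band treatment.

## Filter bank and numerical choices

* **Pyramid pair**: separable 5×5 binomial (maximally flat) lowpass with
  `H1(0,0) = 1`, highpass `H2 = δ − H1`, synthesis filters `δ`. Each split is
  then `low = H1⊛x`, `high = x − low` and reconstruction is the sum — the
  perfect-reconstruction identity `H1G1 + H2G2 = 1` holds exactly, and the
  round-trip error is at machine precision (the tests require < 1e−6, the
  measured residuals are ~1e−16).
* **Directional pair**: a maximally flat diamond lowpass built by the
  McClellan transform of the 7-tap halfband `(−1, 0, 9, 16, 9, 0, −1)/32`
  (polynomial `(2 + 3x − x³)/4` in `x = (cos ω₁ + cos ω₂)/2`), modulated by π
  along the row-frequency axis into a fan; `U2 = δ − U1`. Because the
  complement is exact and survives any integer dilation of the tap lattice,
  *every* split in the directional tree is perfect-reconstruction
  regardless of its upsampling matrix.
* **Directional tree geometry**: stage 1 uses the fan, stage 2 the fan on
  the quincunx lattice (quadrant wedges), stages ≥ 3 sheared fans on dilated
  lattices following the classical directional-filter-bank expansion. The
  wedge geometry beyond 8 directions is approximate, but numerically each
  oblique sinusoid concentrates 70–80% of its energy in a single distinct
  band, and a horizontal one > 99% in its half of the tree.
* **Boundaries**: symmetric (mirror) extension everywhere; convolutions are
  "same"-size. Kernels are stored as sparse offset/weight sets, so à-trous
  dilation and quincunx/shear upsampling are exact integer index maps.
* **Default decomposition**: 3 levels with `dirs = c(2, 3, 3)` — enough
  directional resolution for 128×128 and larger heads. The examples and the
  acceptance script use 2 levels with `dirs = c(2, 2)` at 128×128, a size at
  which the extra level changes the metrics marginally but doubles runtime.

## Metrics

All four scores are computed on the 8-bit scale of the fused *intensity*
plane (that is the plane the method actually fuses; scoring the RGB output
would mix in the untouched hue/saturation):

* SD with the population divisor `M·N`;
* mean gradient as the average of `√((Δx² + Δy²)/2)` over the
  `(M−1)×(N−1)` forward-difference grid — note forward differencing anchors
  the grid at one corner, so this metric is flip-invariant only up to the
  boundary row/column;
* spatial frequency `SF = √(RF² + CF²)` with the `1/(M·N)` normalizer inside
  each component;
* entropy over the 256-bin gray histogram in bits. Images already on the
  8-bit scale are rounded directly (so an in-range constant shift does not
  change the score); signed sub-bands and unit-range images are min-max
  remapped first.

## The phantom generator

Real SPECT/CT pairs are not redistributable here, so the package generates
registered phantoms: the CT phantom is a bright skull annulus (≈ 230) with
sharp edges around a mid-gray interior carrying low-amplitude smoothed
texture on a dark background; the SPECT phantom places 2–4 Gaussian activity
blobs inside the same head mask and renders them through a fixed hot-iron
colormap, black outside the mask. Both are deterministic per seed and
registered by construction. Defaults (128×128, skull radius 0.42, thickness
0.06, 3 blobs of σ = 0.1 of the image size, no added noise) were chosen once
to mimic the salient statistics the method exploits — sharp anatomical edges
against smooth colored activity.

What the phantoms do **not** emulate: attenuation and reconstruction
artifacts, Poisson counting noise, partial-volume effects, anatomical
asymmetry, or miscalibrated registration. Passing tests on phantoms
therefore validate the *mechanics* of the method (exact inverses, selection
rules, optimizer behaviour, metric directions), not clinical image quality.

## Problem sizes and reproducibility

The test suite and the acceptance script run at 64–128 pixels square with
small optimizer budgets (population 6–8, 2–3 memeplexes, 2–3 steps and
shuffles, `T = 20–30`); these sizes were chosen as the smallest at which
every property of interest is expressed. All randomness — phantoms,
population initialization, leaps — flows from explicit seeds, the package
restores the caller's RNG state, and two runs with the same configuration
produce byte-identical images and manifests (asserted in the tests).

## Known limitations

* Only PNG/TIFF bitmaps are read; DICOM and clinical metadata are out of
  scope, as are registration and resampling.
* The directional wedge partition for ≥ 8 directions is approximate (exact
  perfect reconstruction, approximate wedge boundaries).
* The optimizer's objective is computed per band; nothing guarantees the
  *combination* of per-band optima is globally optimal for the final image.
* Gamut clipping after intensity substitution slightly perturbs hue and
  saturation of the clipped pixels; the count is reported in every result.
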