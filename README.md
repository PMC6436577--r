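# spectfuse

Fusion of registered SPECT/CT brain image pairs in R.

SPECT shows function (perfusion, metabolism) as a low-resolution pseudo-color
map; CT shows anatomy (skull, tissue boundaries) in sharp grayscale. A fused
image should keep the SPECT color semantics while inheriting the CT's spatial
detail. `spectfuse` implements a fusion method built from four pieces:

1. **IHS split.** The SPECT image is decomposed by the linear (triangular)
   intensity–hue–saturation transform
   `I = (R+G+B)/3`, `v1 = (2B−R−G)/√18`, `v2 = (R−G)/√2`,
   `H = atan2(v2, v1)`, `S = √(v1²+v2²)`.
   Only `I` is fused; `H` and `S` pass through, so the functional color is
   preserved and the inverse is exact.
2. **NSCT.** `I` and the CT image are each decomposed by a non-subsampled
   contourlet transform: an à-trous pyramid (binomial lowpass `H1`,
   complementary highpass `H2 = δ − H1`) with, per level, a non-subsampled
   directional filter bank (maxflat fan filters, `2^n` wedges). Every
   sub-band keeps full image size; both perfect-reconstruction identities
   `H1G1 + H2G2 = 1` and `U1V1 + U2V2 = 1` hold to machine precision.
3. **PCNN selection.** Matching sub-bands are fused per pixel by a simplified
   pulse-coupled neural network: each band drives a neuron grid, and the
   coefficient whose neuron fired more often over `T` steps wins (ties
   average). The neuron model is
   `L[n] = W⊛Y[n−1]`, `U[n] = S·(1+βL[n])`,
   `Y[n] = 1{U[n] > e^{−α_θ}θ[n−1]}`, `θ[n] = e^{−α_θ}θ[n−1] + V_θ Y[n]`.
4. **SFLA tuning.** The three free PCNN parameters `(α_θ, β, V_θ)` are tuned
   per band by the shuffled frog-leaping algorithm, maximizing the entropy of
   the fused band (mean gradient and a blend are selectable objectives).

Four baselines (`ihs` substitution, `nsct_fl` max/average, `dwt` 2-level Haar
max/average, fixed-parameter `nsct_pcnn`) and the four reference-free quality
metrics — standard deviation, mean gradient Ḡ, spatial frequency SF and
information entropy E — are included, plus a deterministic CT/SPECT phantom
generator so everything runs without clinical data.

## Worked example

```r
library(spectfuse)

pair <- make_phantom_pair(phantom_spec(size = c(128, 128), seed = 1))
cfg  <- fusion_config(nsct_levels = 2, nsct_dirs = c(2, 2),
                      pcnn_iterations = 30,
                      sfla_pop = 8, sfla_memeplexes = 2,
                      sfla_steps = 3, sfla_shuffles = 3,
                      inject_fixed = TRUE, seed = 1)
res <- fuse_spect_ct(pair$spect, pair$ct, cfg)
res$metrics
#> SD = 74.3558  Gbar = 8.2651  SF = 37.1380 (RF 25.4326, CF 27.0632)  E = 5.8968 bits

compare_methods(pair$spect, pair$ct, cfg)
#>      method       sd mean_gradient spatial_frequency  entropy
#> 1       ihs 73.08149      7.167895          43.85257 3.094258
#> 2   nsct_fl 51.39895      7.521052          35.80117 5.534216
#> 3       dwt 50.08875      8.410802          37.41762 4.910710
#> 4 nsct_pcnn 71.78798      7.879454          41.48019 4.995050
#> 5  proposed 74.35578      8.265054          37.13802 5.896750
```

Reading the table: the tuned method (`proposed`) yields the highest contrast
(SD) and the most informative histogram (E) of the five; plain IHS
substitution inherits the CT's spatial frequency but discards most gray-level
diversity (E ≈ 3.1 bits). `inject_fixed = TRUE` seeds each band's optimizer
with the fixed baseline parameters, so the tuned band objective can never
fall below the `nsct_pcnn` baseline's.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/spectfuse.R phantom --out data --size 128 --seed 1
Rscript inst/cli/spectfuse.R fuse --spect data/spect.png --ct data/ct.png --out results
Rscript inst/cli/spectfuse.R compare --spect data/spect.png --ct data/ct.png --out table.csv
Rscript inst/cli/spectfuse.R evaluate --image results/fused.png
```

Every `fuse` run writes a `manifest.json` (config, seed, per-band chosen
parameters, metrics) from which the run is exactly reproducible.

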