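# veinclear

Recovery and enhancement of degraded near-infrared finger-vein
transmission images.

Finger-vein biometrics shines NIR light through a finger; hemoglobin
absorbs it, so vessels project as dark curvilinear strokes on a brighter
tissue background. Uneven LED illumination and multiple scattering inside
the tissue frequently collapse the vein/background contrast to a few tens
of gray levels, with regional brightness differences larger than the vein
signal itself. `veinclear` is for people building vein-recognition or
vessel-analysis pipelines who need those degraded frames restored before
feature extraction — and who need the restoration step to be testable
without a biometric dataset.

## The model and the pipeline

The observation is modeled as a transmission analogue of the atmospheric
scattering (dehazing) equation

```
I(x) = J(x) ε(x) + A(x) (1 − ε(x))
```

with `I` the acquired gray value, `J` the latent image, `ε ∈ (0,1]` the
local tissue absorption rate and `A` the regional incident light — a
smooth spatial field here, not the global constant of outdoor dehazing.
Three stages:

1. **Gray-level quantization** (`quantize_gray`) — min–max normalization,
   Gaussian blur (σ = 1.5), and a bounded exponential transform
   `Wg = G1^r · Gm + Gn` into the band [30, 230]; `r` is auto-selected per
   image so the mean maps to mid-band.
2. **Scattering-model restoration** (`restore_scatter`) — a pixel-mutation
   filter over nested windows (Ω2 = 7 inside Ω1 = 31) estimates the
   outgoing light, the mean of the top 5 % of each Ω1 window estimates
   `A`, `ε = FMP/A` is clamped to [0.1, 1], and the model is inverted:
   `J = (I − A(1 − ε))/ε`.
3. **Homomorphic normalization** (`homomorphic_normalize`) — log-domain
   frequency filtering with
   `H = (rH − rL)(1 − exp(−c (D²/D0²)^n)) + rL` (D0 = 25, rH = 2,
   rL = 0.5), then a min–max stretch to full 8-bit range.

The package also provides the evaluation metrics (`mssim`, `cii`,
`det_curve` for FAR/FRR/EER), a seeded synthetic phantom generator that
degrades clean vessel images with the same forward model
(`synth_config`, `synth_sample`, `generate_dataset`), PNG/TIFF gray-image
I/O, and a command line (`inst/cli/veinclear.R`).

## Worked example

```r
library(veinclear)

# a severely degraded synthetic phantom with known vein mask
s <- synth_sample(synth_config(severity = "severe", seed = 0))

res <- enhance(s$degraded)

res$report$r
#> [1] 2.838914
cii(s$degraded, res$image)
#> [1] 2.855778
mssim(s$degraded, res$image)
#> [1] 0.7567368
```

The auto-selected exponent 2.84 says the degraded frame was over-bright
(scattering mixes bright ambient light in) and was darkened toward
mid-band. A contrast-improvement index of 2.86 means the mean blockwise
Michelson contrast nearly tripled, and the MSSIM of 0.76 against the
degraded original quantifies how far the enhancement departed from it —
for a low-quality input, further is better.

Score-based verification evaluation works on any matcher's outputs:

```r
det <- det_curve(genuine = c(0.91, 0.85, 0.77, 0.95, 0.88),
                 impostor = c(0.42, 0.55, 0.80, 0.30, 0.61))
det
#> DET curve over 10 thresholds; EER = 0.2000
```

From a shell, the same pipeline:

```sh
Rscript inst/cli/veinclear.R synth phantoms --n 10 --seed 0 --severity severe
Rscript inst/cli/veinclear.R enhance phantoms/degraded_0000.png out.png
Rscript inst/cli/veinclear.R metrics phantoms/degraded_0000.png out.png
```

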