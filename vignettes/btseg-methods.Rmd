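---
title: "Methods: adaptive denoising and hybrid GCPSO–FCM segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive denoising and hybrid GCPSO-FCM segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btseg)
```

This vignette records how the pipeline's stages are defined, which knobs
matter, and where genuinely open design choices were resolved — the things a
maintainer would otherwise have to reverse-engineer from the code.

## The pipeline at a glance

An 8-bit grayscale slice passes through: (1) adaptive bilateral
multiresolution denoising, (2) hybrid GCPSO–FCM intensity clustering into
`c = 3` tissue classes, (3) extraction of the brightest class as the tumour
mask, (4) GLCM texture description, and optionally (5) kernel-SVM
classification of the texture vector. `run_pipeline()` chains the stages and
records a JSON report; all randomness flows from one integer seed, so a
configuration reproduces a run exactly.

## Denoising model

The noise model is additive zero-mean Gaussian with clipping to `[0, 255]`.
Rician noise — the physically correct model at low MRI SNR — is deliberately
out of scope; at the moderate noise levels exercised here the Gaussian
approximation is standard.

**Wavelet stage.** The transform is the CDF 9/7 biorthogonal pair computed by
lifting. Lifting updates one polyphase component from the other, so the
inverse is exact to machine precision regardless of the boundary extension —
the perfect-reconstruction property the tests assert at 1e−8 relative error
is structural, not numerical luck. Two decomposition levels are the default:
on 64–128 px images a third level leaves approximation bands too small for
windowed filtering to be meaningful. Odd side lengths are handled by edge
replication to even length per level, cropped on reconstruction.

Detail bands are shrunk with the per-band universal threshold
`sigma_hat * sqrt(2 log N)`, with `sigma_hat = median(|HH1|)/0.6745`. The
*hard* rule is the default: with piecewise-smooth anatomy the universal
threshold is large, and soft shrinkage subtracts it from every surviving
(edge-carrying) coefficient, visibly biasing edges; hard thresholding keeps
them intact. Soft shrinkage remains available (`rule = "soft"`) for
oscillatory noise where its smoothness is preferable.

**Bilateral stage.** The range scale defaults to `1.0 * sigma_hat`
(`sigma_r_scale` = 1), the spatial scale to 1.8 px, window 11×11. The
adaptive part has two detectors:

* *Block discontinuities.* The `[-1, 0, 1]` probe is evaluated across every
  inter-pixel boundary; the response across a boundary is the sum of the two
  halved central differences flanking it, so a clean step of height `h`
  reports exactly `h` and a linear ramp reports the same value at boundary
  and interior positions (no false blockiness on gradients). Where a block
  boundary is genuinely discontinuous, `sigma_r` is raised to
  `1.1 * step` (the filter can only remove a step its range scale reaches)
  and decays linearly back to base over 2 px.
* *Texture.* Local population standard deviation over a 7×7 window drives
  `sigma_d = base * clamp(s0 / (s0 + activity), 0.3, 1)` with `s0` the noise
  estimate: smooth regions keep the full spatial scale, textured regions
  shrink it to avoid over-smoothing.

**Deciding whether an image is blocky at all.** A boundary probe responds to
noise and to anatomy as much as to compression artifacts, so raising
`sigma_r` wherever the probe fires would smooth real structure. Two gates
prevent this. Per boundary, the *median* response must clearly exceed (by a
factor 1.5) the median response at interior positions — sparse edge
crossings and i.i.d. noise excite boundary and interior positions alike,
while DCT quantisation concentrates steps exactly on the block grid. (The
interior reference excludes positions adjacent to a boundary, whose probes
straddle the step; medians rather than means because a few strong anatomical
edges dominate any mean.) This decision is made once at full resolution,
where the 8×8 grid lives, and gates the `sigma_r` adaptation at every scale;
per step, a bump additionally requires the step to exceed twice the noise
level. On clean or merely noisy images the deblocking machinery therefore
stays silent, which is what makes the near-identity property (clean input,
zero thresholds → output within 1 intensity unit) hold.

The bilateral pass is applied to the approximation band at every
reconstruction scale *including* scale 0: the low-frequency residual noise
the wavelet shrinkage misses lives in those bands, and the block grid is
only observable at the pixel grid.

## Clustering

`fcm()` is the classical alternating scheme for
`J_m = sum_ij u_ij^m ||x_i - c_j||^2` with fuzzifier `m = 2`. Numerical
conventions: a point at zero distance from one or more centres splits its
membership equally among those centres; convergence is declared when
`max |U - U_old| < 1e-5`; a cluster whose total membership vanishes aborts
with a diagnostic; all-identical data is rejected as degenerate.
Max-membership ties resolve to the lowest cluster index.

`gcpso_fcm()` wraps the same objective in a swarm. Each particle is a
flattened centre set; its fitness is `J_m` with memberships recomputed at
its centres. The particle owning the global best follows the
guaranteed-convergence rule `v <- -x + gbest + omega v + rho (1 - 2r)` — its
successor position samples a box of radius `rho` around `gbest + omega v`,
which provably avoids the total-stagnation failure of plain PSO when
`x = pbest = gbest`. All other particles follow the canonical two-attractor
rule with `c1 = c2 = 1.49`, `omega = 0.72` (the standard constricted
setting). `rho` starts at 1, doubles after more than 15 consecutive
successes, halves after more than 5 consecutive failures, clamped to
`[1e-10, data range]`. Defaults: population 20, at most 100 generations,
stop after 20 stagnant generations, 2 FCM refinement iterations per particle
per generation with Lamarckian acceptance (refined centres replace the
position only when they improve fitness). These population-level constants
are conventional PSO practice; all are exposed as arguments.

The hybrid matters on multimodal objectives: head-to-head on a fixture with
two competing cluster layouts the hybrid's final `J_m` is no worse than
plain FCM's in essentially every seeded trial (the test suite requires at
least 70%).

`segment_image()` clusters *intensity only* (1-D features, no spatial
coordinates), after rounding intensities to the 8-bit grid and weighting
each distinct value by its pixel count. The fit therefore costs the same
for a 64×64 and a 1024×1024 image; `bin = FALSE` restores raw-float
clustering. Labels are reordered by ascending centre intensity so the
brightest class is always `c - 1`; `tumour_mask()` takes that class and, by
default, its largest 8-connected component (isolated bright noise pixels are
not tumour).

## Texture and classification

GLCMs are *directed* (not symmetrised): the offsets (0,1), (−1,1), (−1,0),
(−1,−1) carry signs, and symmetrisation is an explicit option. Quantisation
is `floor(v * levels / 256)`. Correlation returns `NA` when a marginal
variance is zero rather than an arbitrary number. The feature table spans
{128, 256} levels × four angles; the flattened 32-vector (undefined
correlations mapped to 0) is the classifier input.

The five kernels are implemented directly; two conventions the literature
leaves ambiguous are fixed here and documented in `kernel_spec()`: the
exponential RBF uses the *unsquared* distance `exp(-||x-y|| / (2 sigma^2))`,
and the ANOVA kernel is `(sum_k exp(-sigma (x_k - y_k)^2))^degree`. The
soft-margin dual is solved by the interior-point QP solver in kernlab
(`ipop`) with a `1e-8` ridge on the Gram matrix; features are standardised
(constant columns left unscaled); the bias is averaged over unbounded
support vectors. `C = 1` by default.

## Evaluation conventions

Mask rates are pixel-level percentages; accuracy is the *balanced* form
`(TPR + TNR)/2`, which is the arithmetic that links TP/TN columns to the
accuracy column in per-image score tables of this kind (and is therefore
what `scripts/acceptance.R` checks); it is deliberately not symmetric in
(prediction, truth), and the suite pins that asymmetry down. PSNR uses
peak 255 and returns `Inf` at zero MSE.

## The phantom generator

`make_phantom()` renders one axis-aligned brain ellipse (semi-axes 0.44 and
0.46 of the image sides) on background, with one disk-shaped tumour whose
centre is drawn uniformly (from the seed) inside the ellipse shrunk by the
tumour radius plus 2 px — the blob never touches the brain edge. Defaults:
96×96 px, tissue means (20, 120, 230), radius 10 px. Noise is added
separately so the clean reference stays available; `add_blockiness()`
simulates JPEG-style artifacts by per-8×8-block DCT quantisation with the
standard luminance table scaled by a quality factor (quality 100 is the
identity; the mean boundary step grows as quality drops, though not strictly
monotonically at fine quality spacing — DC-coefficient rounding makes
adjacent blocks occasionally quantise to the same level).

What passing on phantoms shows — and does not show. The phantoms are
piecewise-constant with sharp boundaries and exactly three intensity
classes: ideal for intensity clustering. Real MRI adds bias fields, partial
voluming, Rician noise and anatomy with overlapping intensity
distributions; none of these are emulated, so the ≥95% phantom segmentation
accuracy is a correctness check of the machinery, not a clinical performance
claim.

## Problem sizes

The test-suite and acceptance-script sizes were chosen so each property is
measured with comfortable margin while the whole suite stays quick to run:
96×96 phantoms (10 seeds) for segmentation, 64×64 (20 seeds) for the
denoising rates, 150 2-D points × 20 seeds for centre recovery, 40 images
for the 5-fold CV, 20 random ≤7×7 images against the brute-force bilateral
oracle, and 16×16 images against the GLCM enumeration oracle.

## Known limitations

* 2-D single-channel only; no DICOM, no volumes, no bias-field correction.
* Intensity-only clustering cannot separate tissues with equal means but
  different textures; adding spatial or texture features to the particle
  encoding would be the natural extension.
* The deblocking detector assumes the block grid is aligned at multiples of
  the block size (no grid-offset search).
* The per-image score-table accuracy identity is reproduced exactly by the
  balanced-accuracy convention for all but two rows of one published table,
  which are presumed typos; the package makes no attempt to model them.
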