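# btseg

Brain-tumour identification in 2-D grayscale MRI slices: adaptive bilateral
multiresolution denoising, hybrid GCPSO–FCM segmentation, GLCM texture
features, kernel-SVM classification, and the matching evaluation metrics —
all exercised end-to-end on synthetic brain phantoms with exact ground truth.

The package is aimed at medical-image-analysis practitioners who want a
tested, reproducible implementation of this pipeline, and at methodologists
who want its individual stages (the guaranteed-convergence particle swarm,
the fuzzy c-means core, the adaptive bilateral filter) as reusable, classed
R objects.

## The method

**Denoising.** The image is decomposed with a CDF 9/7 wavelet (lifting
scheme, perfect reconstruction). Detail bands are shrunk with the universal
threshold σ̂√(2 log N), σ̂ estimated as median(|HH₁|)/0.6745; during
reconstruction every approximation band — including the full-resolution
image — passes through a bilateral filter

  w(p,q) = exp(−‖p−q‖²/2σ_d²) · exp(−(I(p)−I(q))²/2σ_r²)

whose scales adapt per pixel: σ_r is raised at compression-block boundaries
to at least the measured `[−1,0,1]`-probe discontinuity (a range scale below
a step cannot remove it; one above it can), and σ_d shrinks where local
texture activity is high so real texture is not over-smoothed. Defaults are
σ_d = 1.8, σ_r = 1.0·σ̂, 11×11 window.

**Segmentation.** Fuzzy c-means minimises
J_m = Σᵢ Σⱼ u_ij^m ‖xᵢ − cⱼ‖² with memberships
u_ij = 1/Σₖ (d_ij/d_ik)^(2/(m−1)). A swarm of particles, each encoding a
full centre set, explores J_m under guaranteed-convergence PSO: ordinary
particles follow v ← ωv + c₁r₁(pbest−x) + c₂r₂(gbest−x), while the
global-best particle samples the box gbest + ωv ± ρ(t), with ρ doubling
after more than sc = 15 consecutive successes and halving after more than
fc = 5 consecutive failures. Each generation every particle is refined by a
couple of FCM iterations (Lamarckian update). Pixels take their
maximum-membership cluster; the brightest cluster, reduced to its largest
connected component, is the tumour mask.

**Features and classification.** Gray-level co-occurrence matrices at
offsets (0,1), (−1,1), (−1,0), (−1,−1) — 0°/45°/90°/135° — and 128/256 gray
levels yield contrast, correlation, energy and homogeneity; a soft-margin
SVM with linear, polynomial, Gaussian-RBF, exponential-RBF or ANOVA kernels
separates tumour-bearing from tumour-free textures.

**Metrics.** MSE and PSNR = 10·log₁₀(255²/MSE) for image quality; pixelwise
TPR/TNR/FPR/FNR (percentages) with the balanced accuracy (TPR + TNR)/2 for
masks.

## Worked example

```r
library(btseg)

spec <- phantom_spec(96, 96, tissue_means = c(20, 120, 230),
                     tumour_radius = 10, noise_sigma = 10, seed = 1)
ph    <- make_phantom(spec)                      # clean image + truth mask
noisy <- add_noise(ph$image, spec$noise_sigma, seed = 2)
den   <- denoise_image(noisy)

mse(noisy, ph$image); psnr(noisy, ph$image)      # 99.11, 28.17 dB
mse(den,   ph$image); psnr(den,   ph$image)      # 39.16, 32.20 dB

seg <- segment_image(den, c = 3, seed = 1)
seg
#> Segmentation: 3 intensity clusters, centres 20.39, 119.88, 229.27
#> Pixel counts per label: 3360, 5539, 317

confusion_rates(tumour_mask(seg), ph$mask)
#> TPR 100.000  TNR 100.000  FPR 0.000  FNR 0.000  accuracy 100.000
```

Denoising here recovers ~4 dB of PSNR; the three recovered intensity
centres sit within a unit of the true tissue means (20, 120, 230), and at
noise σ = 10 the tumour mask matches the ground truth exactly (Dice 1.0).
The label map and mask can be written with `write_gray()` / `write_mask()`,
or the whole chain run at once with `run_pipeline(run_config(...))`, which
stores every intermediate plus a JSON report.

A thin command-line front end with subcommands
`phantom | denoise | segment | features | classify | eval | run` ships as
`inst/cli/btseg.R`:

```sh
Rscript inst/cli/btseg.R phantom --sigma 10 --seed 3 --out ph.png --mask-out truth.png
Rscript inst/cli/btseg.R denoise --in ph.png --out den.png
Rscript inst/cli/btseg.R segment --in den.png --mask-out mask.png
Rscript inst/cli/btseg.R eval --pred mask.png --truth truth.png
```

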