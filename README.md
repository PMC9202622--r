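# angioseg

Automated segmentation and diagnosis of coronary artery disease (CAD)
in X-ray angiograms, built so the entire method runs and is testable at
desk scale on synthetic data. The intended users are researchers in
vascular image analysis who need a self-contained, fully seeded
reference implementation of this pipeline — including a phantom
generator with exact ground truth — rather than one tied to a clinical
database.

## The method

X-ray angiograms show contrast-filled arteries as dark tubular
structures on a brighter, textured background, confounded by noise,
low contrast and structural interference. The pipeline:

1. **Multi-constraint preprocessing.**
   *Noise removal* by a frequency-domain Wiener filter: under the
   additive model N(f) = O(f) + A(f), the gain
   W(f) = |O(f)|² / (|O(f)|² + |A(f)|²) is applied, estimated from the
   data as W(f) ≈ (|I(f)|² − |A(f)|²)/|I(f)|² with the noise power set
   adaptively from directional (diagonal/horizontal/vertical)
   first-difference residuals.
   *Contrast enhancement* by maximum principal curvature: from the
   Gaussian-smoothed Hessian, G = k₁₁k₂₂ − k₁₂², M = (k₁₁ + k₂₂)/2,
   and γ± = M ± √(M² − G); dark vessels score strongly positive γ⁺.
   *Binarization* by Otsu's criterion: the threshold t maximizing the
   between-class variance w₁(t)w₂(t)[μ₁(t) − μ₂(t)]².
2. **Segmentation** by an attention-gated nested U-Net (UNet++-style
   dense skips). Each skip is gated by
   f = ReLU(W_F·F + b_F) + (W_G·G + b_G),
   α = σ(W_θ·f + b_θ), output = F ⊙ α,
   with F the encoder features and G the upsampled decoder signal.
   Per-artery angles are estimated from region principal axes, with
   crossings split where skeleton-local orientations differ by more
   than 30°; the binary mask is AND-ed with the original image.
3. **Threefold features** per artery region: color (intensity moments
   and local contrast), texture (GLCM entropy, correlation,
   homogeneity, ASM), shape (diameter D = √((x₁−x₂)² + (y₁−y₂)²)
   across the lumen plus area, angle, length, eccentricity, roundness,
   dispersion, convexity, solidity).
4. **Classification** (normal vs abnormal, i.e. ≥ 50% stenosis) by a
   VGG-16-style CNN with an avg/max-pool spatial-attention block
   (C(F) = σ(f⁷ˣ⁷[F_A; F_M])) and a softmax output, fused with an
   attention-weighted linear head over the handcrafted features.
5. **Metrics**: accuracy, sensitivity, specificity, ROC/AUC, rCNR,
   MSE, Dice, Jaccard, Hausdorff distance, PSNR and pixelwise
   segmentation accuracy — each tested against an independent
   brute-force oracle.

The synthetic phantom generator renders seeded branching vessel trees
(Bezier tubes with optional Gaussian-profile stenoses, dark-on-bright,
structured background, additive noise) with bit-identical
reproducibility, exact masks, labels and per-branch geometry.

## Worked example

```r
library(angioseg)

# a 64 px phantom with a stenosed branch
cfg <- phantom_config(size = 64, n_branches = c(1L, 2L),
                      diameter_range = c(6, 10), branch_child_prob = 0,
                      stenosis_range = c(0.5, 0.7), noise_sigma = 8)
s <- generate_tree(cfg, seed = 3, force_label = "abnormal")
s
#> <phantom_sample> 64x64, 1 branch(es), label = abnormal, sigma = 8, seed = 3
s$branches[, c("diameter_px", "stenosis_fraction")]
#>   diameter_px stenosis_fraction
#> 1    7.539769         0.6261959

pre <- preprocess_pipeline(s$image)
pre$otsu$threshold          # adaptive Otsu threshold on the enhanced image
#> [1] 91
dice_jaccard(s$mask, pre$binary)
#>      dice   jaccard 
#> 0.8774704 0.7816901

dm <- measure_diameter(s$mask)
c(median = dm$d, minimum = dm$d_min)
#>  median minimum 
#>       6       3
```

The median lumen width tracks the 7.5 px calibre and the narrowest
width tracks diameter × (1 − stenosis) = 7.54 × 0.374 ≈ 2.8 px — the
focal narrowing that makes this sample abnormal.

```r
estimate_artery_angles(s$mask)
#> <angio_regions> 1 region(s)
#>  region_id angle_deg length_px mean_width_px area_px
#>          1  23.50151  37.38478      7.141945     267
```

A complete end-to-end run (phantoms → preprocessing → segmenter
training → segmentation → features → classifier → metric suite) at
smoke scale:

```r
rep <- run_pipeline(run_config(seed = 42, n_train = 16, n_test = 6,
         phantom = phantom_config(size = 32, n_branches = c(1, 3),
                                  diameter_range = c(3, 6), noise_sigma = 8),
         segnet = segnet_config(depth = 2, base_channels = 4),
         seg_hyper = train_config(lr = 3e-3, epochs = 20),
         classifier = vgg_config("tiny", input_size = c(16, 16, 1),
                                 conv_blocks = list(4L), fc_sizes = 8L),
         clf_hyper = train_config(loss = "cross_entropy", lr = 1e-2,
                                  epochs = 10, weight_decay = 10)))
rep
#> <metrics_report>
#>   classification: accuracy 0.500, sensitivity 0.667, specificity 0.333, AUC 0.667
#>   segmentation:   dice 0.904, jaccard 0.826, hausdorff 1.74 px, pixel accuracy 0.972
#>   image quality:  PSNR 32.96 dB, rCNR 17.34, MSE 32.91
```

Segmentation is strong even at this scale; meaningful classification
needs the 64 px phantoms and the 100/30 split (a 50% stenosis of a
3-px vessel is not resolvable at 32 px — see the methods vignette for
the study conditions, where held-out accuracy reaches ~0.93–0.97).

A thin CLI wrapping these functions ships in `inst/cli/angioseg`
(`phantom`, `preprocess`, `evaluate`, `run` subcommands).

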