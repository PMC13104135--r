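# emalign

3D alignment of serial-section volume electron microscopy (vEM/ssEM) stacks
in R: feature-based rigid alignment, frequency-decoupled elastic
registration along the section axis, a ground-truth-free registration
quality metric, overlapping-patch processing for very large sections, and a
synthetic phantom generator so the whole pipeline is testable without any
data downloads.

Intended users are microscopists and image-analysis developers who need to
re-stack serial-section EM images into a coherent volume before downstream
segmentation or isotropic reconstruction — and who need to *verify* the
alignment they get.

## The method

**Rigid stage.** For each adjacent slice pair, multi-scale Harris keypoints
are restricted to an edge mask (membrane edges deform least between
sections), described by orientation-normalized intensity patches, matched by
mutual nearest neighbor with a ratio test, filtered by a
locality-preserving-matching criterion, and fed to the closed-form
Kabsch/SVD rigid fit

    S = X̃ Ỹᵀ,  S = U Σ Vᵀ,  R = U diag(1, det(UVᵀ)) Vᵀ,  t = u − R v

(reflection-guarded, exact on clean correspondences). Transforms are
propagated sequentially — each slice is matched against the already-aligned
previous slice — and every slice is resampled exactly once under its
cumulative transform.

**Elastic stage (the core).** Nonlinear artifacts are high-frequency along
z, genuine anatomy is low-frequency. A radius-1 Gaussian kernel g along z is
applied to the stack *through displacement fields*: pairwise fields from a
coarse-to-fine optical-flow estimator are scaled by kernel weights, used to
form intermediate targets, re-estimated, and combined as

    φᵢ = ḡ₀ φᵢ,ᵢᵗᵐᵖ + ḡ₁ φᵢ,ᵢ₊₁ᵗᵐᵖ,   Îᵢ = Iᵢ ∘ φᵢ

so each output slice is one warp of its own original pixels. On
pure-translation stacks this provably reduces to a scalar linear filter:
constant (aligned) configurations are exact fixed points, and alternating
per-slice jitter is attenuated ~97 % while smooth trends pass through — the
test suite checks the image pipeline against this closed form to 1e-6.

**Evaluation.** With ground truth: SSIM, NCC, mutual information, Dice,
Hausdorff. Without: adjacent-slice difference images are Laplacian-filtered
and scored by histogram entropy, bilateral-split SNR, and GLCM contrast over
a difference-of-Gaussians pyramid.

**Large sections.** Slices beyond ~2k px are split into overlapping 1024-px
patches; per-patch elastic fields are fused by raised-cosine feathering
normalized to a partition of unity (single patch ≡ whole-image pipeline,
bit-identically).

See `vignettes/alignment-methods.Rmd` for assumptions, parameter defaults,
numerical choices and known limitations.

## Worked example

```r
library(emalign)

# phantom volume -> sectioned, jittered, distorted, noisy stack
vol   <- generate_phantom(c(16, 256, 256), n_structures = 24, seed = 1)
clean <- slice_volume(vol, interval = 2)
jit   <- apply_rigid_jitter(clean, t_max = 20, theta_max = 8, seed = 2)
dis   <- apply_elastic_distortion(jit$stack, alpha = 1, seed = 3)
raw   <- add_gaussian_noise(dis$stack, sigma = 0.02, seed = 4)
raw
#> <slice_stack> 8 slices of 256 x 256 (bit depth 8)

res <- align_stack(raw)   # rigid, then one elastic sweep

res$transforms[[3]]$theta_deg        # 5.38 — applied jitter was -5.31 deg
mean(reference_metrics(raw,       clean)$SSIM)   #> 0.289
mean(reference_metrics(res$stack, clean)$SSIM)   #> 0.674

evaluate_stack(raw)$summary$mean_H         #> 6.40  bits
evaluate_stack(res$stack)$summary$mean_H   #> 5.72  bits (lower = better)
```

The recovered per-slice rotation inverts the applied jitter to within a
tenth of a degree; alignment raises mean SSIM against the undistorted
ground truth from 0.29 to 0.67; and the ground-truth-free entropy of the
difference stack drops by ~0.7 bits, agreeing in direction with the
full-reference score.

A thin command-line front end is installed at `inst/exec/emalign`
(`emalign simulate|rigid|elastic|evaluate|tile|run`), reading/writing
multi-page TIFF stacks, JSON transforms, float32 TIFF displacement fields
and CSV/JSON reports.

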