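# dentamorph

Fine-scale morphometry of hippocampal dentation — the sub-millimetre,
ridge-like undulations on the inferior surface of the hippocampus (CA1 /
subiculum) whose prominence varies strongly between individuals and across
age. Clinical T1 images are ~1 mm isotropic, so a voxel mask at native
resolution cannot represent a 0.2 mm bump; dentamorph is a toolkit for
researchers who want to measure these features anyway, by exploiting the
partial-volume information in the grayscale image.

The package implements, in R:

* **Sub-voxel surface refinement.** A coarse segmentation probability map
  `M` (from any upstream model) is cropped to the region of interest,
  upsampled 5× to 0.2 mm by cubic interpolation, initialized from the
  high-confidence region `{M > η}` and evolved as a narrow-band level set
  with normal speed

  `L(x) − α·M(x) + β·κ`

  (LoG edge force from the upsampled image, regional probability force,
  mean-curvature regularization — `κ` is the sum of principal
  curvatures). The surface converges to strong-edge locations close to
  the confident probability region, recovering sub-voxel structure.
* **Dentation quantification.** The refined mask is sampled into a
  uniform interior point cloud (rejection sampling), projected by PCA
  onto its long-axis/height plane, and reduced to the inferior silhouette
  `y(x)` (per-bin extreme of the projected height). A four-parameter
  sinusoid `y = A·sin(wx + φ) + b` is fitted by simulated annealing
  (acceptance rule `exp(−ΔD/T) > U(0,1)`, geometric cooling, restarts,
  Nelder–Mead polish), giving amplitude `A`, frequency `f = w/2π`, bump
  height `H = 2A` and bump width `L = 1/f`.
* **Synthetic validation shapes.** Dentated cuboids with known `(A, F)`
  voxelized at 0.2 mm, plus degradation operators (box-average to 1 mm,
  blur, noise, companion grayscale image) that stand in for an upstream
  segmentation, and a recovery-study runner over the
  16-combination grid `A ∈ {0.1…0.4} mm × F ∈ {0.1…0.25} bump/mm`.
* **Evaluation & statistics.** Dice / Jaccard / precision / recall,
  HD and HD95 (exact distance transforms), slice-wise 2D Hausdorff
  distance on a characteristic sagittal slice, and pairwise Welch t-test
  group comparison with 0.05 / 0.005 / 0.001 significance tiers.

Volumes are S3 array objects with world geometry (NIfTI-1 I/O via
RNifti); tabular results are tibbles with `tidy()` / `glance()` /
`autoplot()` methods. A thin command-line wrapper over the same functions
lives at `inst/cli/dentamorph.R`.

## Worked example

Simulate a dentated shape (A = 0.3 mm, F = 0.2 bump/mm), degrade it to a
1 mm probability map + image, refine back to 0.2 mm, and measure the
dentation:

```r
library(dentamorph)

spec  <- sim_shape_spec(amplitude_mm = 0.3, frequency_bpm = 0.2)
truth <- simulate_dentated_cuboid(spec)
prob  <- degrade_to_probability_map(truth, coarse_spacing_mm = 1, seed = 1)
img   <- companion_intensity_image(truth, noise_sd = 4,
                                   out_spacing_mm = 1, seed = 2)
img   <- resample_to_grid(img, prob, mode = "nearest", outside = 40)

fine  <- fine_scale_segment(img, prob, dentamorph_config())
fit   <- fit_sinusoid_sa(extract_silhouette(fine, dentamorph_config(),
                                            seed = 7), seed = 7)
fit
#> <sinusoid_fit>
#>   A = 0.1708 mm   f = 0.2007 bump/mm   phi = 3.056 rad   b = 5.196 mm
#>   H = 2A = 0.3415 mm   L = 1/f = 4.982 mm
#>   cost J = 0.00268 (n = 160, seed = 7, ok)

evaluate_segmentation(
  threshold_mask(resample_to_grid(fine, truth, mode = "nearest")), truth)
#>      dsc jaccard recall precision  hd_mm hd95_mm
#> 1 0.9826  0.9658 0.9949    0.9706 0.6928  0.2828
```

Reading the output: the bump **frequency** comes back almost exactly
(0.2007 vs 0.2 bump/mm — width `L` 4.98 vs 5 mm), and the refined surface
overlaps the 0.2 mm ground truth at Dice 0.98 with a 95th-percentile
boundary error of 0.28 mm. The fitted **amplitude** through the full 1 mm
pipeline (0.17 mm vs 0.3 mm) is attenuated, because box-averaging and
blurring at 1 mm irreversibly damp a 5 mm-wavelength displacement signal;
measuring the 0.2 mm ground-truth mask directly gives A = 0.24 mm, the
remainder being voxel-quantization of the envelope. The methods vignette
(`vignettes/dentation-morphometry.Rmd`) quantifies both effects.

## Default configuration

| parameter | default | meaning |
|---|---|---|
| `upsample_factor` | 5 | 1 mm native → 0.2 mm fine grid |
| `eta` | 0.5 | high-confidence threshold for the initial region |
| `alpha` | 0.3 | regional (probability) force weight |
| `beta` | 0.1 | mean-curvature force weight |
| `log_sigma_mm` | 0.5 | Laplacian-of-Gaussian scale (mm) |
| `n_points` | 200000 | interior sample points for the PCA projection |
| `bin_width_mm` | 0.2 | silhouette bin width (= fine voxel) |
| `trim_fraction` | 0.1 | silhouette x-range trimmed per end |
| `seed` | 1 | seed for all stochastic steps |

`sa_schedule()`: T0 = 1 (variance-normalized costs), cooling 0.95,
50 proposals/temperature, T_min = 1e-4, 4 restarts.

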