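# ssvmsi — spectral-spatial variation features for multispectral tissue imaging

Multispectral endoscopy of the stomach produces image cubes — two spatial
axes and a few wavelength bands (six on 400–650 nm here) — that cannot be
shown to a clinician directly, so carcinoma must be flagged pixel by pixel.
Pixelwise classification cannot afford thousands of texture features, and
this package implements a pipeline built around one *strong* feature, the
**spectral-spatial variation (SSV)**: the residuum

    r[i,j,k] = I[i,j,k] − Î[i,j,k]

between the cube and a local spatial–spectral regression fit computed on
small disjoint sub-images. Healthy mucosa leaves a residuum dominated by
the sensor-noise floor; carcinoma, with its elevated local spatial and
spectral variance, stands out. The same residuum supplies the noise
covariance for a **minimum noise fraction (MNF)** transform
(`Φ = V₁ S₁^(−1/2) V₂` from two SVDs; components sorted by SNR; truncation
denoises), so one computation feeds both the feature and the noise filter.

The package provides, end to end:

* **cube I/O** — multi-page TIFF or an R-serialization container, label
  masks, dataset manifests (`read_cube`, `write_cube`, `read_mask`,
  `read_manifest`);
* **pre-processing** — FFT notch filtering of the endoscope's horizontal
  line artifacts (0.5/0.25/0.125 cycles/px), Brown radial
  barrel-distortion calibration and correction, per-band standardization,
  MNF denoising, Gaussian smoothing, in a fixed audited order
  (`run_pipeline`);
* **SSV** — residuum estimation, MNF transform, SSV maps and feature
  channels (`estimate_noise_residuum`, `fit_mnf`, `denoise`, `ssv_maps`,
  `ssv_features`);
* **Laguerre-Gaussian spatial features** — a rotated 40×40 kernel bank
  (p ≤ 3, l ∈ {1,2,3}, 5 rotations) with max-absolute pooling over
  rotations: 72 channels on a six-band cube (`build_filter_bank`,
  `extract_lg_features`);
* **evaluation** — leave-one-patient-out harness with PCA reduction, 1%
  training subsampling, MCC (threshold optimized on training scores) and
  rank-based AUC, plus a full-factorial parameter sweep exported as a tidy
  CSV (`train_eval_lopo`, `run_sweep`, `mcc`, `auc`);
* **synthetic phantoms** — multispectral phantoms (350 × 370 × 6, noise
  σ = 5, line artifacts, elliptical lesions with independently switchable
  spectral shift and variance multiplier), calibration checkerboards and
  multi-patient cohorts, all bit-reproducible from a seed
  (`generate_phantom`, `generate_checkerboard`, `generate_cohort`);
* a **CLI** (`ssv_main()`, launcher in `inst/cli/ssvmsi`) with subcommands
  `synth`, `preprocess`, `ssv`, `mnf-denoise`, `lgfeat`, `evaluate`.

## Worked example

A phantom whose lesion differs from the background *only* by a 4× noise
variance — the case where plain spectral features are blind by
construction:

```r
library(ssvmsi)

cfg <- phantom_config(
  lesion = list(center = c(140, 229), axes = c(58, 44), rotation_deg = 20,
                spectral_shift = 0, variance_multiplier = 4),
  seed = 42)
ph   <- generate_phantom(cfg)
filt <- fourier_line_filter(ph$cube)           # remove line artifacts first
res  <- estimate_noise_residuum(filt, subimage_size = 30)
tr   <- fit_mnf(filt, res)
maps <- ssv_maps(filt, res)

print(res)
#> residuum_cube: 350 x 370 x 6, subimage_size = 30, regressor = ols
#>   pooled residuum sd (valid px): 5.625
print(tr)
#> mnf_transform: 6 bands, fitted on 128781 pixels
#>   component SNR (noise-whitened variance): 3.22e+03, 5.56, 3.03, 1.35, 1.16, 0.995

vm <- res$valid_mask
auc(maps$aggregate[vm], ph$mask$labels[vm])
#> [1] 0.9263715
```

The pooled residuum sd (5.6) sits just above the injected sensor noise
(σ = 5) — the lesion's extra variance is in there — and the SSV aggregate
map alone separates lesion from healthy pixels with AUC ≈ 0.93. In the
leave-one-patient-out harness, adding the SSV channels to the raw bands
lifts mean AUC from ≈ 0.68 to ≈ 0.89 on a 4-patient cohort of such
variance-only lesions (`run_sweep` with `use_ssv = c(FALSE, TRUE)`).

From a shell, the same loop runs as:

```sh
inst/cli/ssvmsi synth --patients 4 --out cohort/ --seed 7
inst/cli/ssvmsi evaluate --manifest cohort/manifest.csv \
    --use-ssv FALSE,TRUE --classifiers random_forest \
    --out results.csv --seed 7
```

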