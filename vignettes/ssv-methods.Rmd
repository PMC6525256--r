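---
title: "Spectral-spatial variation: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral-spatial variation: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multispectral endoscopy records a cube $I_{i,j,k}$ — two spatial axes and a
handful of wavelength bands (here six, 400–650 nm, roughly 350 × 370 px per
frame) — from which carcinoma should be flagged pixel by pixel. Pixelwise
classification cannot afford thousands of texture features per band, so the
package is built around a small set of *strong* features. Its centerpiece is
the **spectral-spatial variation (SSV)**: the residuum between the cube and a
local regression fit,

$$ r_{i,j,k} = I_{i,j,k} - \hat I_{i,j,k}, $$

where $\hat I$ is predicted from the pixel's spatial and spectral
neighborhood inside small disjoint tiles. Healthy mucosa leaves a residuum
dominated by the (nearly constant) sensor noise; carcinoma, with its
elevated local spatial and spectral variance, leaves a visibly different
one. The same residuum doubles as the noise estimate that drives a minimum
noise fraction (MNF) denoising transform, so one computation feeds both the
feature and the noise filter.

## The pre-processing chain

Six steps run in a fixed order, each recorded in the cube's history:

1. **Fourier notch filtering.** The endoscope imprints line artifacts
   parallel to the x-axis at 0.5, 0.25 and 0.125 cycles/pixel. Lines
   parallel to the x-axis vary along y, i.e. live on pure vertical
   frequencies, so per band we zero a one-bin-wide band at $\pm f$ along the
   vertical-frequency axis for all horizontal frequencies. The DC bin is
   never touched, and the operation is idempotent. This step must precede
   the distortion correction, which would smear those fixed frequencies.
2. **Barrel-distortion correction.** A two-coefficient Brown radial model,
   $r_d = r\,(1 + k_1 r^2 + k_2 r^4)$ on radii normalized by a scale in px.
   Coefficients come from checkerboard corner correspondences by linear
   least squares ($r_d - r$ regressed on $r^3, r^5$); images are resampled
   bilinearly at forward-distorted coordinates, and pixels whose source
   falls outside the frame are flagged invalid rather than invented. The
   model is monotone for $|k_1| \le 0.5$ within about 1.3 normalized radii
   of the center; calibration targets should sit inside that range.
3. **Per-band standardization** (zero mean, unit population sd over valid
   pixels) so the noise regression sees scale-free input. The population
   (1/n) form is used so a two-valued band standardizes to exactly ±1.
   Location/scale are kept for exact inversion.
4. **MNF denoising** (below), at a configurable component cut.
5. **De-standardization**, the exact affine inverse of step 3.
6. **Gaussian smoothing**, separable, σ = 1 px by default, reflective
   (edge-repeating) boundaries: the per-band image sum is conserved and the
   variance never increases. The source never states the σ; 1 px removes
   residual pixel-level noise without erasing the gastric-pit scale
   texture that the spatial features need.

## Noise residuum and the MNF transform

The image is tiled into disjoint squares (default 30 px; the methodological
sweep range is 10–100 px, and the last tile in each direction absorbs the
remainder). Per tile and band, ordinary least squares predicts each pixel
from an intercept, the centered tile coordinates $(i, j)$, the causal
same-band neighbors $I_{i-1,j,k}$ and $I_{i,j-1,k}$, and the spectral
neighbor $I_{i,j,k-1}$ (omitted in the first band) — the
spectral-and-spatial-decorrelation idea, augmented with a local affine
trend. The coordinate terms matter: neighbor predictors carry the same
noise as the response, and on large tiles that errors-in-variables
attenuation inflates the residual sd by over 10%; the noiseless coordinate
regressors absorb smooth shading and keep the pooled residuum sd within a
few percent of the injected σ across tile sizes 10–100 (measured 5.05/5.18/
5.22 for σ = 5 at sizes 10/30/100 on the full-size phantom). Pixels in the
image's first row/column lack causal neighbors; they are excluded from the
fits, set to zero and masked. A linear ε-insensitive SVR
(ε = 0.1 × tile sd) is available behind a flag for parity with the
regressive-SVM formulation; OLS is the default because it is deterministic
and nests the same signal model.

With $R_2$ (N × bands) the vectorized residua over valid pixels and $X_2$
the data, the MNF transform is assembled from two SVDs:
$V_1, S_1$ from the eigen-expansion of the noise covariance
$R_2^t R_2/(N-1)$; whitening $W = X_2 V_1 S_1^{-1/2}$ (element-wise square
root; pseudo-inverse with tolerance $10^{-10}\times$ the largest singular
value, rank drops logged); $V_2$ from the SVD of $W$; and
$\Phi = V_1 S_1^{-1/2} V_2$, with its pseudo-inverse for the return trip.
Components of $B = X_2 \Phi$ carry unit noise variance by construction, so
their data variances are their SNRs and arrive sorted. Denoising zeroes all
but the leading `mnf_cut` components and maps back; keeping all components
is an identity to machine precision. The covariance (1/(N−1)) normalization
— rather than the raw Grammian — is what makes the transformed residua have
unit covariance; the reconstruction is invariant to that scale choice.
`mnf_cut` values above the band count clamp to the band count: the
methodology quotes cuts of 4, 5, 7 and 35, and on a six-band cube the
larger two can only mean "keep everything".

SSV maps are read directly off the residuum: the per-band residua, their
per-pixel RMS across bands (the 2D aggregate; the reduction is our choice,
as the source shows a single 2D image without naming one), and the
aggregate divided by the pixel's mean intensity — masked where the mean
intensity is below $10^{-6}$ of the image maximum — which removes most of
the illumination dependence. As classification features the per-band
residua plus the RMS give bands + 1 channels.

## Laguerre-Gaussian spatial features

The comparison features are rotated Laguerre-Gaussian kernels,
$$ k(r, \varphi) = \Big(\tfrac{r\sqrt2}{w}\Big)^{l}
   L_p^l\!\Big(\tfrac{2r^2}{w^2}\Big)\, e^{-r^2/w^2} \cos\!\big(l(\varphi -
   \theta)\big), $$
sampled on a 40 × 40 grid, unit L2 norm, with the generalized Laguerre
polynomials $L_p^l$ implemented in closed form for $p \le 3$ (validated
against a symbolic Rodrigues-form oracle). Angular order $l = 0$ is
excluded: its rotation step $180^\circ/l$ is undefined, and only
$l \in \{1,2,3\}$ with $p \in \{0..3\}$ reproduces the advertised
$12 \times 6 = 72$ channels on a six-band cube. For each $(p, l)$ the
kernel is rotated in five evenly spaced steps spanning $[0, 180^\circ/l)$ —
taking absolute responses makes the other half-period redundant — each
rotation is correlated with each band (reflective boundaries, FFT-based),
and the per-pixel maximum of absolute responses over rotations is the
feature, giving approximate rotation invariance. The envelope width
defaults to $w = \text{size}/4$: the Gaussian falls to $e^{-4}$ (≈ 2%) at
the edge midpoint and $e^{-8}$ at the corner. Note the full kernel decays
more slowly than the bare envelope — the radial polynomial grows as $r^{l}
x^{p}$ — so high-order kernels retain up to ~10% of their peak at the edge
midpoint; responses within half a kernel of the border mix in reflected
content and the stack records that margin.

## Evaluation harness

Evaluation is leave-one-patient-out: all images of one patient form the
test fold, so within-patient correlation cannot leak. Per fold, PCA
(centered, unscaled) is fitted on all training pixels and the smallest
component set covering 99% of variance is kept; a stratified 1% subsample
(floored at 500 pixels per class, capped at availability — the floor keeps
small phantoms trainable) fits the classifier; all labeled held-out pixels
are scored. AUC is the rank-based Mann-Whitney statistic with tie
averaging. MCC is reported at the threshold that maximizes MCC on training
scores only (scanned over up to 512 quantile midpoints; training scores are
capped at 50 000 pixels for the scan, deterministically subsampled) — the
operating-point protocol is our choice, as is per-fold rather than global
subsampling. MCC's zero-denominator case returns 0, logged. Classifiers are
delegated to established implementations: linear/RBF SVM (e1071), a
probability random forest (ranger), shallow boosted trees (xgboost, depth
2 — the AdaBoost-with-stumps analogue) and a label-noise-tolerant boosting
variant (xgboost with η = 0.1 and 70% row subsampling); re-deriving the
exact RobustBoost algorithm is out of scope, since the contribution under
study is the features, not the learners. The parameter sweep crosses
sub-image size × MNF cut × feature toggles × classifier, recomputes
features per (size, cut) cell, and exports a tidy per-fold table (CSV,
`%.17g`, byte-identical under a fixed seed) ready for external
repeated-measures analysis; the five-way ANOVA itself is deliberately not
reimplemented here.

## The synthetic phantom generator

Phantoms emulate what the method assumes about the data, at the stated
acquisition conditions: 350 × 370 px, six bands on 400–650 nm, smooth
backgrounds (low-order polynomial surfaces per band on 8-bit-like levels,
~90–180, rising with wavelength as mucosa reflectance does), additive
Gaussian sensor noise of σ = 5 intensity values, horizontal line artifacts
at 0.5/0.25/0.125 cycles/pixel (cosine phase — a sine at half-Nyquist
vanishes identically on the pixel grid; amplitude 3, below the noise floor,
as such artifacts are visible but not dominant), an elliptical lesion, and
optionally a barrel-distorting camera (scene warped before artifacts and
noise, which are sensor effects). The lesion's abnormality is split into
two independently switchable knobs — a mean spectral shift (default +10
intensity units) and a noise-variance multiplier (default 4) — so that
SSV-specific gains can be isolated on variance-only lesions, the
configuration where plain spectral features are blind by construction.
Cohorts add per-patient random offsets of the band levels
(sd 8 intensity units by default) to emulate inter-patient variation, the
dominant difficulty in vivo, plus per-image jitter of the lesion pose; the
background anatomy is drawn from a shared seed so that
`inter_patient_sigma = 0` really means identical patients. Everything is
bit-reproducible from config + seed.

What the phantoms do *not* model — and hence what passing tests cannot
show: specular highlights, motion artifacts, mucus, realistic gastric-pit
texture, expert mislabeling of margins, and the spectral complexity of real
tissue. Results on phantoms validate the machinery (the SSV lifts AUC when
lesions differ in variance), not clinical performance.

## Problem sizes and numerical choices

The test-suite and acceptance computations run at these sizes, chosen so a
desk machine reproduces them in minutes: full 350 × 370 × 6 phantoms for
noise-σ recovery (tile sizes 10/30/100) and the pixelwise SSV AUC;
128 × 128 × 6 for the MNF round trip and whitening; a 4-patient,
2-images-each cohort at 200 × 220 px for the leave-one-patient-out SSV
gain (variance-only lesions, multiplier 4, random forest). Key numerical
conventions: pseudo-inverse tolerance $10^{-10}\times$ the leading singular
value; notch bandwidth one FFT bin; bilinear resampling with Newton
inversion of the radial map (25 iterations, well within 0.1 px over the
supported coefficient range); tie-averaged ranks in the AUC; MCC threshold
ties resolve to the lowest candidate; degenerate inputs (constant bands,
single-class folds, undersized tiles, all-zero residua) raise classed
errors or produce flagged rows rather than silent numbers.
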