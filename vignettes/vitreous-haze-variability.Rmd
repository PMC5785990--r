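---
title: "Quantifying vitreous haze on OCT and the variability of the measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vitreous haze on OCT and the variability of the measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octhaze)
```

## The measurement

Inflammatory activity in the vitreous (vitritis, a hallmark of
posterior-segment uveitis) scatters light and raises the background signal
of the vitreous cavity on OCT B-scans. `octhaze` quantifies this as the
**vitreous/RPE-relative intensity (VRI)**:

$$\mathrm{VRI} \;=\; \frac{\bar I_{\mathrm{vitreous\ patch}}}{\bar I_{\mathrm{RPE}}}$$

the mean intensity of an automatically delineated vitreous patch divided
by the mean intensity of the segmented retinal pigment epithelium. The RPE
is the brightest stable band in the scan, so dividing by its mean acts as
a normalisation term: a global attenuation of the signal (media opacity,
gain changes) multiplies numerator and denominator alike and leaves the
ratio unchanged. `analyse_bscan()` implements the measurement as

1. binarise the scan (Otsu threshold by default),
2. morphological opening with a disc structuring element (radius 5 px) and
   retention of the largest connected component — the retina/RPE complex,
3. per column, the lowest 6 px of the component form the RPE band,
4. the vitreous patch is everything more than 10 px above the inner
   retinal boundary within the central 60% of columns, minus tissue,
5. VRI = patch mean / RPE-band mean.

Each stage can refuse: tissue spanning under 60% of columns, an empty RPE
band, a patch under 500 px, or zero RPE signal all yield a `failed`
measurement with a reason rather than an error. These thresholds, the
threshold method, the opening radius and the band/patch geometry are all
exposed in `seg_config()`; none of them is canonical, and raw exports can
optionally be linearised first via the `inverse_gamma` option (most OCT
viewers gamma-transform displayed images, which inflates dim vitreous
pixels relative to the raw signal).

## The acquisition protocol and what is being tested

The reliability question is operator-driven: how do frame averaging (ART:
6, 12, 25, 50 or 100 frames per section), focus offset (−10 to +10
dioptres from optimal retinal focus) and vertical positioning of the
retina (middle vs bottom of the window) change the VRI and its
variability? `canonical_protocol()` holds the ten setting combinations;
`enumerate_protocol(n_subjects, repetitions, sections)` expands them into
the full design — with 15 subjects, 3 repetitions and 7 sections per
raster scan this is 30 raster scans per subject and 1575 theoretical
section measurements in each five-setting arm.

## The synthetic study

No public image set accompanies this protocol, so the package carries a
phantom generator and a study simulator; every downstream stage is
exercised against data whose ground truth is known.

**Phantom images.** `make_phantom()` renders a bright retina band with a
brighter RPE sub-band and a Gaussian foveal dip over a dark vitreous.
The acquisition setting enters through three mechanisms:

* *Averaging*: additive Gaussian noise with standard deviation
  `base_noise_sd / sqrt(art_level)` — the `1/sqrt(N)` law of frame
  averaging. Default `base_noise_sd = 0.03` (intensity units at ART 1)
  keeps the ART-100 scan visibly clean and the ART-6 scan visibly grainy
  without destabilising segmentation.
* *Focus*: a separable (gain, blur) pair per offset. The gain multiplies
  the vitreous signal (defocusing toward the vitreous images it more
  brightly); the blur is a Gaussian PSF. Defaults are calibrated so the
  in-focus ratio is smallest and positive offsets give the largest
  ratios, reproducing the qualitative ordering seen in practice; no
  published optical model ties dioptres to gain, so the maps are plain
  config (`phantom_optics()`).
* *Positioning*: bottom positioning translates the band into an intensity
  roll-off at the lower edge of the acquisition window (the well-known
  edge-fading artefact, default 20% over the last 30 rows), dimming the
  RPE, and raises the vitreous signal slightly — together pushing the
  ratio up, as observed clinically when oedema forces a low placement.

Noise is additive Gaussian clipped to [0, 1] rather than true
multiplicative speckle: the analysis consumes only region means and
standard deviations, for which this is sufficient. Clipping at zero
slightly inflates the measured vitreous mean of very dark, very noisy
scans (about +3% at vitreous intensity 0.04 and noise sd 0.03); this is a
real property of 8-bit exports, not an artefact of the simulator.

**Study values.** `generate_study()` draws the VRI of slot (subject $i$,
repetition $j$, section $k$) under setting $s$ as

$$y_{ijks} = \mu_s + b_i + c_{ijs} + e_{ijks}$$

with $b_i \sim N(0, \sigma^2_{\mathrm{subject}})$ per subject,
$c \sim N(0, \sigma^2_{\mathrm{scan}})$ per raster scan (one acquisition
= one subject x setting x repetition) and
$e \sim N(0, \sigma^2_{\mathrm{section}})$ per section. Defaults:
$\mu_s$ from `reference_setting_means()` (published reference estimates,
0.039–0.048 in focus, up to 0.200 at +10 D) and
$(\sigma_{\mathrm{subject}}, \sigma_{\mathrm{scan}},
\sigma_{\mathrm{section}}) = (0.012, 0.007, 0.010)$, the magnitudes
reported for a mid-range averaging setting. Random draws come from
per-key seeded streams — the key string (slot id plus root seed) is
hashed to a seed — so a subset of a design reproduces exactly the values
it would have had inside the full design.

`inject_failures()` emulates the automated measurement refusing an image.
Default per-setting probabilities are calibrated to the reported
arm-level failure rates (3% over the ART arm, ~32% over the focus arm)
with failures concentrated at large offsets, where acquisition and
segmentation genuinely struggle.

**What the simulator does not emulate**: speckle texture, vitreous
floaters and posterior hyaloid structures, eye motion, oedema, media
opacities. Tests passing on phantoms therefore validate the pipeline's
arithmetic, its failure handling and its statistical calibration — not
the clinical segmentation performance on pathological eyes.

## The statistical analysis

**Exclusions.** A raster scan with fewer than 3 of its 7 sections
measured is discarded whole; a subject x setting cell left with fewer
than 2 repetitions is discarded whole (`apply_exclusions()`, idempotent,
with a log).

**Mean effects.** `fit_mean_model()` fits, per factor, a linear mixed
model with the factor categorical (the settings are discrete levels, not
doses) and random intercepts for subject and for raster scan nested in
subject, by REML (`lme4`). The overall factor p-value is a
likelihood-ratio test of maximum-likelihood refits with and without the
factor; a Wald-style alternative was considered and rejected as the
default because the LRT is the more standard choice for comparing nested
mixed models of this size. The same routine accepts the vitreous or RPE
mean intensity as the response, which is how the two components of the
ratio are analysed separately.

**Variability.** Residuals are formed at three levels
(`compute_level_residuals()`): each measurement about its scan mean
(within-scan), each scan mean about its cell mean (intra-subject), each
subject mean about the across-subject mean (inter-subject). If residuals
are approximately normal their squares are scaled chi-squared, a Gamma
case, so `fit_variability()` models squared residuals with a Gamma GLM
and log link, categorical factor; the reported variability is the square
root of the fitted mean. With one categorical predictor that fitted mean
is exactly the group mean of squared residuals, so the estimate is the
per-group RMS residual — the test suite holds the GLM to that closed form
at 1e-8. The Gamma dispersion is estimated by the Pearson method and
affects only standard errors, never the fitted means. Exact zero squared
residuals (a measure-zero event for continuous data, common only in
degenerate synthetic inputs) are dropped with a logged count; a level
that is entirely zero is reported as zero variability and flagged.

Inter-subject residuals are computed **per setting** (switchable): the
variability is reported per setting, and pooling subject means across
settings would mix setting effects into the residuals.

**Contrasts.** `pairwise_compare()` produces all pairwise level
contrasts with Tukey-family adjusted p-values via `emmeans`
(multivariate-t family, the standard generalisation of the studentized
range to GLM/LMM contrasts). With two levels the adjustment is a no-op.

**Box plots.** `boxplot_stats()` uses linear-interpolation (type-7)
quartiles, whiskers at the most extreme points within 1.5 IQR of the box
and everything beyond flagged as an outlier.

## Numerical and design choices

* **Intensities** are floats in [0, 1] in memory and 8-bit grayscale PNG
  on disk; writing quantises explicitly so a written-and-reread study is
  bit-stable.
* **Coordinates**: row 1 (0 in the geometry spec) is the top of the scan,
  the vitreous side; "bottom positioning" means translation to larger row
  indices.
* **Degenerate fits**: zero-variance synthetic data make the mixed model
  singular; the fit falls back to ordinary least squares with zero
  variance components and a non-convergence flag, and the balanced-design
  identity (fixed-effect estimates = cell means) still holds.
* **Variance-component recovery** (`recover_variance_components()`) uses
  bias-corrected method-of-moments: each level's mean squared residual is
  corrected for mean-centering shrinkage ($n-1$ degrees of freedom per
  group of $n$) and for variance leaking up from the levels below
  ($\sigma^2_{\mathrm{scan}} + \sigma^2_{\mathrm{section}}/7$ in a scan
  mean of 7 sections, and so on). The section and scan components are
  estimated with hundreds of degrees of freedom and recover tightly. The
  subject component is fundamentally limited by the number of subjects:
  with 15 subjects any estimator of $\sigma_{\mathrm{subject}}$ has ~14
  degrees of freedom, for which the probability that a single replicate
  lands within 25% of the truth is
  $P(\chi^2_{14} \in [14 \times 0.75^2,\ 14 \times 1.25^2]) \approx 0.81$.
  Replicate-level recovery rates for this component should be read
  against that ceiling; it is a property of the design size, not of the
  estimator.
* **Haze range of validity**: the Otsu binarisation assumes the vitreous
  is the dark class. When the vitreous intensity approaches the retinal
  band's (phantom vitreous mean ≳ 0.25 against a 0.45 retina) the
  threshold merges the classes and the measurement fails — mirroring the
  real algorithm's failures on brightly imaged vitreous (strong positive
  defocus). Monotonicity of measured VRI in the haze parameter is
  therefore asserted over the clinically occupied range (ratios up to
  ~0.24).
* **Problem sizes** used by the test suite and acceptance script are the
  study's own: the full 15 x 10 x 3 x 7 design for single fits, 50
  replicate studies for recovery, 200 for the LRT size check, 100 noisy
  phantoms for measurement robustness.

## Running a whole study

```{r, eval = FALSE}
cfg <- pipeline_config()             # 15 subjects, canonical protocol
res <- run_pipeline(cfg, "study-out")
res$failure                          # theoretical / failed / pct per arm
res$mean_fits$focus                  # focus effect on the mean VRI
res$variability$focus                # variability per level and setting
```

`run_pipeline()` writes the study table, mean-effect, variability and
pairwise-contrast CSVs, box-plot JSON, the failure summary and a plain
report; identical config and seeds give byte-identical outputs. Setting
`render = TRUE` routes the simulation through actual phantom images and
the full measurement stage instead of simulating VRI values directly
(slower; the phantom optics are calibrated per slot so the measured VRI
tracks the simulated target).

## Limitations

The phantom is a geometric stand-in, not an optical simulation; absolute
agreement with device imagery is out of scope. The exact segmentation
parameters of the original measurement software are not published, so
this implementation's defaults are its own, documented choices. The
clinical question — discriminating vitritis from healthy vitreous — is
deliberately not addressed here; this package is about the measurement
and its operator-factor reliability.
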