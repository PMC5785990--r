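# octhaze

Objective quantification of **vitreous haze** — the light scatter caused
by inflammatory cells and protein in the vitreous body — from OCT
B-scans, and analysis of how acquisition settings affect the measurement.
The intended users are imaging researchers in uveitis who need an
objective alternative to subjective clinical haze grading, and anyone
validating an intensity-ratio imaging biomarker against "operator
factors": frame averaging, focus, and image positioning.

## The measurement

The haze index is the **vitreous/RPE-relative intensity (VRI)**

```
VRI = mean intensity of the vitreous patch / mean intensity of the segmented RPE
```

computed per B-scan by thresholding (Otsu), morphological opening with a
disc structuring element, keeping the largest connected component as the
retina/RPE complex, taking the lowest 6 px of the complex per column as
the RPE band, and building the vitreous patch from everything more than
10 px above the inner retinal boundary in the central 60% of columns.
Normalising by the RPE mean makes the ratio invariant to global signal
attenuation. Any stage can declare the scan unmeasurable (insufficient
tissue coverage, undersized patch, zero RPE signal); failures carry
reasons instead of raising errors.

Around the measurement the package provides:

* a **synthetic phantom and study simulator** (`make_phantom()`,
  `enumerate_protocol()`, `generate_study()`, `inject_failures()`)
  emulating the ten-setting acquisition protocol (ART averaging 6–100,
  focus offsets −10 to +10 D, middle/bottom positioning), `1/sqrt(ART)`
  noise scaling, focus gain/blur, bottom-edge fading, and a nested
  subject / raster-scan / section random-effects structure;
* the **statistical analysis** (`fit_mean_model()`,
  `compute_level_residuals()`, `fit_variability()`,
  `pairwise_compare()`): linear mixed models with nested random effects
  for setting effects on the mean VRI, a three-level residual
  decomposition, Gamma GLMs with log link on squared residuals for the
  within-scan / intra-subject / inter-subject variability (reported as
  the square root of the fitted mean), Tukey-adjusted pairwise
  contrasts, and the exclusion rules for unmeasurable scans;
* an end-to-end **pipeline** (`run_pipeline()`) writing study tables,
  effect and variability tables, box-plot summaries, failure accounting
  and a text report, byte-reproducibly from explicit seeds.

## Worked example

```r
library(octhaze)

# one phantom B-scan at the reference setting (middle, ART 100, in focus)
b <- make_phantom(phantom_geometry(), phantom_optics(),
                  acquisition_setting("middle", 100, 0), seed = 1)
analyse_bscan(b)
#> <vri_measurement> VRI 0.0483 (vitreous 0.0410 / RPE 0.8500)
b$truth$vri
#> [1] 0.04823529
```

The measured ratio (0.0483) agrees with the phantom's ground-truth
region ratio (0.0482) to the noise level; on a noise-free phantom the
two are identical to machine precision.

```r
# a full simulated 15-subject study, analysed end to end
res <- run_pipeline(pipeline_config(), "study-out")
res$failure
#>        arm theoretical failed pct
#>        art        1575     59   4
#>      focus        1575    510  32
#>   position         630     23   4

res$mean_fits$focus
#> <mean_effect_fit> vri ~ focus  (lmer_reml)
#>  level   estimate          se
#>    -10 0.16840823 0.004159780
#>     -5 0.08978165 0.004118108
#>      0 0.05204265 0.004077004
#>      5 0.19506742 0.004115801
#>     10 0.20320026 0.004146046
#> overall p-value (LRT): 2.544e-161
```

Each theoretical arm holds 15 subjects x 5 settings x 3 repetitions x 7
sections = 1575 section measurements; about a third of defocused scans
fail, as configured in `default_failure_probs()`. The focus effect is
large and highly significant: defocused acquisitions inflate the mean
VRI roughly three- to four-fold relative to the in-focus 0.052, with
positive offsets worst — exactly the behaviour the simulator's reference
means encode. `res$variability$focus` gives the per-level variability
tables and `pairwise_compare(res$mean_fits$focus)` the Tukey-adjusted
contrasts.

The methods vignette
(`vignettes/vitreous-haze-variability.Rmd`) documents the model, the
simulator's assumptions, and every tunable parameter.

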