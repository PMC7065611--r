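---
title: "Detecting invisible surface stains: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting invisible surface stains: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfstain)
```

## The problem

Organic soil on touch surfaces — skin residue, food traces, microbial
deposits — is frequently invisible to the eye, yet it feeds bacterial growth
and marks surfaces that need cleaning. Hospital practice assesses surface
hygiene with ATP bioluminescence swabs (total organic soil, in relative
light units, RLU) and total plate counts (culturable bacteria, CFU/cm²);
both are point measurements that say nothing about where the soil sits.
Multispectral fluorescence imaging offers a spatial alternative: many
fluorophores found in organic soil, flavins such as riboflavin in
particular, absorb blue-green light and re-emit near 500 nm. Imaging a
surface under switched LED excitation (red, green, blue) through a swept
bandpass filter produces a spectral cube in which such a stain is bright in
exactly the channels where its excitation and emission bands line up with
the light and the filter — even when no single raw frame shows it to the
eye.

`surfstain` implements this workflow end to end on synthetic phantoms with
known ground truth: a forward model of the acquisition, three detectors of
increasing automation (absolute threshold, dirty-vs-clean differencing,
full-cube k-means), a tile-wise max-margin surface classifier, and the
ATP/TPC guideline benchmarks with survey aggregation.

## The acquisition model

An acquisition protocol is the full grid of (excitation light, bandpass
filter) pairs. The default mirrors the published instrument: three LEDs and
filters swept 420–720 nm in 20 nm steps, giving 3 × 16 = 48 channels of
1393 × 1040 px frames. Drive levels (`relative_intensity`, 0–255) are set
per light; they are kept low for lights whose wavelength falls inside the
filter sweep, because when the filter passes the LED wavelength itself the
direct reflection can saturate the sensor. The model reproduces this with a
leak-through term: per channel the background intensity is

$$ b + g_\text{leak} \cdot \frac{I_\text{rel}}{255}
   \exp\!\left(-\frac{(\lambda_L - \lambda_F)^2}
                     {2(\sigma_L^2 + \sigma_F^2)}\right), $$

with $b$ the surface reflectance, $\lambda_L, \lambda_F$ the light and
filter centers, and $\sigma_L, \sigma_F$ their Gaussian widths. At
$I_\text{rel} = 255$ and $\lambda_L \approx \lambda_F$ this clips at 1
(saturation); at $I_\text{rel} = 50$ it does not.

A stain's contribution in a channel is the standard first-order
fluorescence product

$$ q \cdot \underbrace{e^{-(\lambda_L - \mu_x)^2 / 2\sigma_x^2}}_{\text{excitation}}
   \cdot \frac{I_\text{rel}}{255}
   \cdot \underbrace{\frac{\sigma_F}{\sqrt{\sigma_m^2+\sigma_F^2}}
     e^{-(\mu_m - \lambda_F)^2 / 2(\sigma_m^2+\sigma_F^2)}}_{\text{emission--filter overlap}}, $$

with excitation band $(\mu_x, \sigma_x)$, emission band $(\mu_m, \sigma_m)$
and brightness scale $q$. The overlap factor is the exact
Gaussian–Gaussian integral, normalized to its narrow-filter limit. The
response is linear in both drive level and stain concentration, and is set
to exactly zero beyond five widths off-band so that off-band channels are
clean zeros rather than denormal noise.

Modeling choices made where the source instrument is not characterized (all
configurable): Gaussian lineshapes for LED, filter and fluorophore spectra;
filter passband FWHM 10 nm; blue LED center 460 nm; LED FWHM 20 nm. The
default fluorophore is flavin-like — excitation 450 ± 60 nm (broad enough
that both blue and green excite it, red barely), emission 500 ± 25 nm — so
the stain lights up under green/blue excitation through the 500 nm filter
and stays dark under red, which is precisely the asymmetry the two-channel
clustering view exploits.

## The phantom generator

A scene is a flat background (default reflectance 0.2), a list of
rectangular or elliptical stains in millimetre coordinates, i.i.d. Gaussian
pixel noise (default sd 0.02 on the [0,1] scale, about 5 digital numbers of
an 8-bit sensor), and a seed. The default pixel scale is 0.05 mm/px, which
makes the worked-example 3 × 1.5 mm stain exactly 60 × 30 px; the default
stain concentration and brightness put its green/500 nm intensity near
0.65 against the 0.2 background, so the hand-picked 0.35 threshold falls
comfortably between. The dirty and clean variants are rendered in perfect
registration (the instrument images the same spot before and after cleaning
without moving), and rendering is bit-reproducible from the seed.

What the generator deliberately does **not** emulate: lens blur and
vignetting, dark current, spatially correlated noise, partial cleaning
(clean means the stain is entirely gone), surface texture, and registration
error. A green suite therefore establishes that the detectors recover
planted fluorescent patches under additive Gaussian noise on a flat
background — not that they survive optical artifacts or misregistration on
real instruments.

## Detection

Three detectors of increasing automation, all on the [0,1] absolute
intensity scale (8-bit values divided by 255 — not per-image min-max, so
one threshold means the same thing in every image):

* **`threshold_map`** — pixels strictly above a hand-picked threshold are
  stain. Pixels exactly at the threshold are background; the source
  procedure defines both sides with strict inequalities and leaves equality
  undefined, so it is resolved here once, conservatively. No morphological
  cleanup is applied — the raw thresholded image is the result.
* **`differential_mask`** — `threshold_map(dirty) AND NOT
  threshold_map(clean)`: removes bright fixed features of the surface
  itself. Whether the published procedure thresholded the dirty frame alone
  or always compared against the cleaned image is ambiguous; both
  operations are provided and the pipeline reports the differential one.
* **`kmeans_cluster`** — every pixel of the region becomes its full-channel
  intensity vector; Lloyd's algorithm with k-means++ seeding (10 restarts,
  300-iteration cap, best objective wins) partitions them, k = 2 by
  default (stain vs background; the source does not state k). Channels are
  standardized to zero mean / unit variance within the region first —
  otherwise high-drive channels dominate the distance metric — and constant
  channels are dropped; both behaviors are switchable. The stain cluster is
  the one with the higher mean raw intensity in the designated emission
  channel (default green/500 nm); a minority-size fallback rule is
  available. Ties in assignment break toward the lower cluster id (the
  underlying `stats::kmeans` convention).

Recovery is scored by the Jaccard index against the planted mask. On
noise-free phantoms both detectors are exact (Jaccard 1); the stochastic
suites fix the stated world at a stain-background gap of five noise
standard deviations, threshold at the midpoint, analysis cropped around the
stain (the published procedure also crops), and require median Jaccard
≥ 0.9 over 20 seeds.

## Tile classification

The region of interest is tiled into 10 px (0.5 mm) squares; each tile is
summarized by per-channel mean and SD (length 2 × channels). The published
feature set and classifier internals are proprietary, so this package fixes
a transparent recipe and isolates it behind `tile_features` for wholesale
substitution. The classifier is a linear max-margin separator. No SVM
library ships in this environment, so it is implemented directly as an
L2-regularized squared-hinge (L2-loss) linear SVM minimized by BFGS from a
zero start — the smooth variant of the hinge objective, standard in
LIBLINEAR — which keeps training deterministic given the data. Training
tiles come from phantom pairs labeled by truth-mask coverage (≥ 50% of the
tile dirty, configurable). A surface is called dirty as soon as one tile
classifies dirty (configurable minimum count): stains concentrate in a few
tiles, so any dirty tile is signal.

## Hygiene benchmarks

ATP ≥ 1 RLU/cm² is dirty (derived from the common 100 RLU/surface limit);
TPC ≥ 2.5 CFU/cm² exceeds the hygiene benchmark and ≥ 40 CFU/cm² is heavy
growth. All boundaries are inclusive; values above 100 CFU/cm² remain heavy
growth (no more-severe category exists); TPC below the detection limit is
conventionally stored as half the limit (0.5 CFU/cm²). `summarize_hygiene`
aggregates per-sample tables per location plus a pooled total row
(sample-pooled, not location-averaged — the source table does not say
which; pooling is assumed and flagged); a single-sample location reports
SD 0 with a degeneracy flag.

The packaged hospital survey table is aggregated per location;
`survey_totals` reconstructs integer positive counts from each location's
printed percent × N and pools them. One genuine inconsistency in the source
is preserved rather than repaired: the per-location TPC sample counts sum
to 102, while the table's printed total row says 112 — and the printed
overall S. aureus rate, 11.6%, equals 13/112, with 13 being exactly the
positives the per-location rows reconstruct. `survey_totals` therefore uses
the printed total-row denominators when present and raises a data-quality
warning about the mismatch. The inferred surface area behind the worked
ATP pair (1.9 RLU/cm² vs 109 RLU/surface implies ≈ 57 cm², outside the
armrest range 47–53 cm²) is a second such inconsistency, noted and left
unresolved.

## Reproducibility and numerical choices

All randomness flows from explicit seeds: the scene seed drives rendering,
and the pipeline fans its top-level seed out to the stages by fixed offsets
(+1 clustering, +2 classifier). Functions that consume randomness restore
the caller's RNG state. Stacks quantize to 8-bit on write and reload
bit-exactly; `run_all` reports contain only relative artifact paths, so a
rerun with the same config and seed is byte-identical. Degenerate inputs
are defined errors (constant region for k-means, single-class training,
k > distinct points), with one pipeline-level exception: a constant region
in an empty scene reports an empty stain rather than an error, and a scene
with no dirty training tiles skips the classifier and calls the surface
clean.

## Worked example

```{r example, eval = FALSE}
report <- run_all(default_run_config(seed = 0), out_dir = "run0")
report$detection$jaccard_differential  # 1 on the default phantom
report$kmeans$jaccard                  # 1
report$tiles$dirty_surface_call        # "dirty"
report$tiles$clean_dirty_fraction      # 0
```

The numbered scripts under `analysis/` run the same stages as a narrated
workflow (simulate, threshold-detect, cluster, tile-classify, hygiene
report) and write their tables under `results/`.

## Limitations

The phantom is the validation world: flat backgrounds, Gaussian optics and
noise, perfect registration, binary cleaning. The published study's
biological results (per-location means, ANOVA) rest on swab data that are
not deposited and are not reproduced here beyond the printed aggregation
arithmetic. The tile classifier reproduces the stated input/output
behavior of the proprietary original, not its exact outputs; its
correlation with real ATP readings cannot be checked without the original
images.
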