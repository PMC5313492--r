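---
title: "Methods: the PET/CT skeletal tumor-burden index and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PET/CT skeletal tumor-burden index and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pettbi)
```

## The measurement model

NaF PET visualizes osteoblastic activity: bone metastases appear as focal
regions of elevated standardized uptake value (SUV). The package measures
skeletal tumor burden as the fraction of segmented bone volume occupied
by metastatic "hotspots", rescaled to the whole skeleton:

$$\mathrm{index} = 100 \times f \times \frac{\sum_i v_i}{V_\mathrm{bone}}
\quad [\%]$$

with $v_i$ the volumes of included hotspots, $V_\mathrm{bone}$ the
segmented bone volume, and $f = 0.33$ the default skeletal fraction: the
axial bones typically available in a PET/CT field of view (thoracolumbar
spine, sacrum, pelvis, ribs, scapulae, clavicles, sternum) hold about a
third of total skeletal volume, and skeletal parts outside the
segmentation are assumed metastasis-free. The index is reported in
percent, so hotspot volume equal to the entire segmented skeleton gives
exactly 33%.

The pipeline (`run_pipeline()`) composes five stages:

1. **Smoothing.** The SUV volume is convolved with an isotropic Gaussian,
   $\sigma = 2$ mm by default, to suppress voxel noise that would
   otherwise fragment lesions into an unmanageable number of
   single-voxel hotspots. Sigma is specified in millimetres and converted
   per axis to voxels ($\sigma/\mathrm{spacing}_a$), so anisotropic grids
   are handled correctly. Smoothing is applied in both operating modes,
   before thresholding.
2. **Detection.** Voxels with smoothed SUV strictly above the threshold
   are grouped into 3D connected components (26-connectivity). Each
   component is one hotspot: voxel count, physical volume, peak SUV,
   centroid.
3. **Bone-overlap filter.** Hotspots with no voxel inside the bone mask
   are removed; the mask is brought onto the PET grid by
   nearest-neighbour resampling when the grids differ.
4. **Classification (manual mode only).** A reader labels each hotspot
   `metastasis` or `benign` (degeneration, inflammation, fracture);
   benign hotspots are excluded. The automated mode includes every
   bone-overlapping hotspot.
5. **Index computation** per the formula above.

Two modes mirror clinical practice: `manual`, with a per-patient
threshold chosen by the reader (typical choices SUV 6–9; the package
warns outside a plausibility range of 4–12), and `auto`, with a fixed
threshold of SUV 15 and no manual selection — fully automated and
therefore reproducible, at the cost of missing lower-uptake disease.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma_mm` | 2 | mm | pre-threshold smoothing; 0 disables |
| `threshold_suv` | 15 (auto) | SUV | hotspot detection cut, strict `>` |
| `skeletal_fraction` | 0.33 | — | extrapolation from segmented bones to whole skeleton |
| `volume_mode` | `full` | — | volume credited to boundary-straddling hotspots |
| `connectivity` | 26 | — | 3D component neighbourhood |
| `horizon_years` | 5 | years | administrative censoring of survival data |

## Design choices where the design was open

* **Common grid.** Hotspots are PET objects, so their volumes are
  measured on the PET grid; the CT-resolution bone mask is resampled
  PET-ward (nearest neighbour, voxel-center mapping). The bone-volume
  *denominator*, however, is taken from the mask's native grid, where it
  is most accurate; the resampled mask only decides overlap.
* **Partial bone overlap.** The removal rule is stated only for hotspots
  with *no* overlap, so by default a hotspot that touches bone with at
  least one voxel keeps its full volume (`volume_mode = "full"`). An
  `intersection` mode restricts volume to the bone-overlapping part for
  sensitivity analyses.
* **Threshold comparison** is strict (`>`), matching "uptake above" a
  value; a `>=` option exists.
* **Hotspot identifiers** are assigned by ascending minimum voxel index,
  slowest-varying axis first. Ids are therefore deterministic across
  runs and platforms, which keeps manual-label CSV files valid.
* **Unlabeled hotspots in manual mode** count as metastases with a
  warning, so a labels file need only list exclusions; a strict mode
  requires complete labels.
* **Degenerate inputs.** An empty bone mask is a hard error (the index
  would divide by zero). An entirely supra-threshold volume is allowed
  and produces one warned hotspot spanning the volume.

## Numerical choices

The Gaussian kernel is truncated at $4\sigma$ per axis and renormalized
to unit sum, so constant volumes are exact fixed points and an interior
impulse conserves total intensity to machine precision. Boundaries use
half-sample symmetric reflection. Nearest-neighbour resampling resolves
half-spacing ties with `floor(x + 0.5)` for platform stability.
Connected components are labeled through an adjacency graph over
supra-threshold voxels; the test suite verifies exact agreement with an
independent flood-fill labeler on hundreds of random scenes.

## The phantom generator

`generate_phantom()` renders a declarative `phantom_spec` — ellipsoid or
tube "bones", spherical lesions with constant SUV plateaus, soft-tissue
background SUV 1, healthy-bone SUV 4 — into a PET-grid SUV map and a
CT-grid bone mask covering the same world box, plus analytic ground
truth: lesion volumes in closed form $\tfrac43\pi r^3$ (or voxel-counted
when a lesion leaves the lattice), bone volumes both analytic and
digitized, and the expected index. Lesions are plateaus rather than
Gaussian blobs precisely so that the supra-threshold volume is known
analytically; smoothing is tested separately against a brute-force
convolution oracle. Voxel membership is decided by the voxel center,
consistently across generator and pipeline, which is why noise-free
pipeline runs at $\sigma = 0$ reproduce the digitized truth *exactly*
and the analytic truth to within the digitization error (below 5% for
lesion radii of at least 3 voxels).

What the phantom does **not** emulate: scanner point-spread functions,
NaF pharmacokinetics, scatter or attenuation artifacts, irregular bone
shapes, or the correlation between lesion location and uptake. Passing
phantom tests therefore demonstrates the geometry and bookkeeping of the
measurement, not clinical detection performance.

## Survival statistics

The evaluation module reproduces the standard battery for a prognostic
imaging biomarker:

* `censor_at_horizon()` censors all follow-up at 5 years (times exactly
  at the horizon keep their event status).
* `median_split()` dichotomizes at the cohort median (midpoint of the
  central order statistics for even $n$); values strictly above the
  median form the high-risk group, ties go low.
* `km_estimate()` wraps the product-limit estimator (events precede
  censorings tied at the same time). The median survival is the earliest
  time the curve reaches 0.5 or below; if the curve never gets there the
  median is reported as *not reached* — the expected outcome for low-burden
  groups within a 5-year window.
* `logrank_test()` and `cox_univariate()` delegate to the `survival`
  package (Efron tie handling, Wald CIs on the log-hazard scale); the
  score test is exposed because it equals the log-rank chi-square for
  binary covariates, which the tests verify to $10^{-6}$.
* `harrell_cindex()` enumerates all patient pairs: a pair is comparable
  when the shorter observed time is an event; with the default
  orientation, concordance means the shorter-lived patient has the
  *higher* biomarker (higher index ⇒ worse prognosis, the HR > 1
  direction); biomarker ties score ½. The CI is a seeded percentile
  bootstrap over patients (2000 resamples by default).

### Comparing two C-indices

For `compare_cindex()` the literature method is cited without formulas,
so the package makes its own choice. A naive paired t-test on raw
per-patient concordance contributions is badly anti-conservative — the
contributions are strongly correlated because every pair is shared
between two patients; in a 200-replicate null simulation (two independent
noise biomarkers, $n = 100$) it rejected at ≈ 32% instead of 5%. The
package instead estimates the variance of
$\Delta = \hat c_A - \hat c_B$ by the leave-one-patient-out jackknife
over concordance contributions — the standard variance estimator for
U-statistics — and refers $\Delta/\widehat{se}$ to a t distribution with
$n-1$ degrees of freedom. The same simulation gives ≈ 4% rejection, with
full power on a perfect-vs-constant biomarker contrast
($\Delta = 0.5$). A seeded paired-bootstrap p-value is available as a
cross-check. Because the original method's algorithm is unspecified,
p-values from this test should not be expected to reproduce published
comparison p-values exactly.

## The cohort simulator

`simulate_cohort()` draws a log-normal biomarker (matching the skewed
interquartile ranges typical of tumor-burden indices), event times from
an exponential baseline with log hazard linear in the biomarker
($T_i \sim \mathrm{Exp}(\lambda e^{\beta x_i})$), independent exponential
loss to follow-up, and administrative censoring at 5 years. The
exponential baseline was chosen for its closed-form checks (mean
$1/\lambda$, competing-risk censoring fraction
$\tfrac{\lambda}{\lambda+\mu}(1-e^{-(\lambda+\mu)h})$), which the tests
verify at $n = 10{,}000$ within Monte-Carlo error. Parameter-recovery
tests fit 50 replicates of $n = 500$ with $\beta = 0.5$ and ≈ 30%
censoring and require the mean estimate within $\pm 0.05$ and 95% Wald
coverage between 90% and 99%. Problem sizes throughout the suite (128³
phantom grids, 200 random labeling scenes up to 32³, 200 null replicates
for the type-I check) were chosen as the smallest sizes at which the
properties are sharp.

## Known limitations

* The rule-based HU-threshold bone mask (`baseline_bone_mask_from_ct()`)
  is a deliberately simple stand-in for a real skeletal segmentation; it
  will include calcified non-bone structures and contrast-filled vessels
  on clinical CT.
* SUV computation from raw counts, injected dose and body weight is out
  of scope; inputs must already be SUV-scaled, co-registered volumes.
* Only axis-aligned NIfTI geometries are handled faithfully; oblique
  acquisitions should be resampled upstream.
* The C-index comparison p-value is the package's own construction (see
  above), not a reimplementation of any published algorithm.
* Multivariable Cox models, competing risks and proportionality
  diagnostics are out of scope.
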