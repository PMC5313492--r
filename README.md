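# pettbi — skeletal tumor burden from NaF PET/CT

`pettbi` quantifies how much of the skeleton is involved by osteoblastic
metastases on an ^18^F-sodium-fluoride (NaF) PET/CT scan. It is aimed at
nuclear-medicine researchers who have a standardized-uptake-value (SUV)
PET volume and a co-registered CT bone segmentation and want an objective
volumetric tumor-burden biomarker — the 3D analogue of the Bone Scan
Index (BSI) — together with the statistics needed to evaluate such a
biomarker against overall survival.

## The index

Hotspots are connected regions of supra-threshold uptake in the
(Gaussian-smoothed) SUV volume. After removing hotspots with no overlap
with the segmented skeleton, and (in manual mode) hotspots a reader
classified as benign, the index is

```
index = 100 × 0.33 × Σᵢ vᵢ / V_bone   [percent]
```

where `vᵢ` are the metastatic hotspot volumes and `V_bone` the volume of
the segmented bones (thoracolumbar spine, pelvis, sacrum, ribs, scapulae,
clavicles, sternum). Those bones hold roughly 33% of total skeletal
volume, so the 0.33 factor rescales the measured fraction to the whole
skeleton: hotspot volume equal to the entire segmented skeleton maps to
an index of 33%.

Two variants are provided:

* **manual** — a reader-chosen detection threshold (typically SUV 6–9)
  plus per-hotspot metastasis/benign classification;
* **auto (PET15)** — fully automated with a fixed SUV 15 threshold and no
  manual selection.

Both smooth the SUV volume with a 2 mm Gaussian before thresholding.

The package also bundles the biomarker-evaluation toolkit used with this
kind of index: administrative 5-year censoring, median-split Kaplan-Meier
curves with log-rank tests, univariate Cox regression (per-unit hazard
ratios), Harrell's C-index with bootstrap confidence intervals and a
paired C-index comparison, and Bland-Altman agreement — plus synthetic
phantom and survival-cohort generators with analytic ground truth, so
every stage is testable without patient data.

## Worked example

A synthetic phantom with a tubular "bone" and two in-bone lesions, run
through the automated pipeline:

```r
library(pettbi)

spec <- phantom_spec(
  shape = c(64L, 64L, 64L), pet_spacing_mm = c(2, 2, 2),
  ct_spacing_mm = c(2, 2, 2),
  bones = list(list(type = "tube", from_mm = c(64, 64, 10),
                    to_mm = c(64, 64, 118), radius_mm = 24)),
  lesions = list(
    list(center_mm = c(63, 63, 41), radius_mm = 8,  suv_plateau = 20),
    list(center_mm = c(63, 63, 91), radius_mm = 10, suv_plateau = 20)))
ph  <- generate_phantom(spec)
res <- run_pipeline(ph$suv, ph$bone, mode = "auto", sigma_mm = 0)
res$index
#> PET/CT skeletal tumor-burden index (auto mode)
#>   threshold SUV 15, sigma 0 mm
#>   hotspots: 2 detected, 2 included
#>   hotspot volume 6176.0 mm^3 / bone volume 193536.0 mm^3
#>   index: 1.053% (skeletal fraction 0.33)
truth_index(spec, digitized = TRUE)
#> [1] 1.053075
```

The two plateau lesions (radius 8 and 10 mm) occupy 6176 mm³ of the
193536 mm³ bone; scaled by 0.33 this is 1.053% of the whole skeleton, and
it matches the phantom's voxel-counted ground truth exactly.

Evaluating a biomarker on a simulated 200-patient cohort whose log hazard
rises 0.5 per index unit:

```r
sim <- simulate_cohort(n = 200, beta_true = 0.5, seed = 42)
survival_report(sim$cohort, "biomarker", n_boot = 500, seed = 42)
#> Biomarker evaluation (censored at 5 years)
#>  biomarker c_index c_ci95_low c_ci95_high   hr hr_ci95_low hr_ci95_high p_value
#>  biomarker   0.629       0.57        0.68 1.64        1.44         1.86  <0.001
#>
#> Median-split Kaplan-Meier comparison:
#>  biomarker median_value n_high n_low median_survival_high median_survival_low
#>  biomarker        0.487    100   100                1.324                2.35
#>  logrank_chi2 logrank_p
#>          14.1    <0.001
```

Patients above the median index die sooner (median survival 1.3 vs 2.3
years), the hazard ratio is 1.64 per index unit, and the C-index of 0.63
says the index correctly orders 63% of comparable patient pairs.

## Command line

A thin CLI wraps the same functions
(`system.file("cli", "pettbi", package = "pettbi")`):

```sh
pettbi compute --pet pet.nii.gz --bone bone.nii.gz --mode auto --out out/
pettbi phantom --config spec.json --out phantom/
pettbi simulate-cohort --n 200 --beta 0.5 --seed 1 --out sim/
pettbi survival --cohort cohort.csv --biomarkers bsi,pet15 --out surv/
pettbi bland-altman --cohort cohort.csv --x bsi --y pet15 --out ba/
```

Every run writes a `provenance.json` with the configuration, input
checksums and package version.

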