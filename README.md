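# cathi — Computer-Assisted Testis Histology

Quantitative histomorphometric image analysis of testicular tissue
cross-sections, for reproductive-biology and andrology researchers who want
numbers instead of semi-quantitative scores. Given a calibrated RGB image of an
H&E-stained testis section (µm per pixel known), `cathi` delineates the
section, the seminiferous tubules and their lumina, and computes the standard
derived quantities of testis morphometry; given an H-DAB
immunohistochemistry field, it quantifies staining by colour deconvolution.
A built-in testis **phantom** generates synthetic sections with exact ground
truth, so every stage of the pipeline is verifiable without access to scanned
slides.

## What it computes

With tubule count *N*, spermatid-positive count *N⁺*, areas *A* in µm² and
diameters *d* in µm:

* Bergmann–Kliesch score (histomorphometric): `BK% = 100 · N⁺ / N`
* Average diameter: `d_avg = (d₁ + d₂⊥) / 2` (max Feret diameter and the
  perpendicular caliper extent), for the whole section, each tubule and each
  lumen
* Spermatogenic epithelium: `A_SE = A_tubule − A_lumen`,
  `SE% = 100 · A_SE / A_tubule`, and SE thickness as the mean of five
  random-ray measurements
* Section composition: `A_interstitium = A_section − Σ A_tubule`,
  `tubule area ratio % = 100 · Σ A_tubule / A_section`,
  `tubule number density = N / A_section` (pieces/µm²)
* IHC (after H-DAB deconvolution, dark-pass thresholds):
  `positive area % = 100 · A_DAB⁺ / A_counterstain⁺` and uncalibrated optical
  density `OD = log10(255 / mean pixel value)` over the DAB-positive pixels

## Worked example

```r
library(cathi)

spec  <- phantom_spec(seed = 7)          # 30 tubules, 10% longitudinal, 70% spermatid+
scene <- generate_scene(spec)            # seeded packing with ground truth
he    <- render_he(scene)                # calibrated H&E-like image + label masks

seg <- segment_image(he$image)
#> <segmentation_result> 30 tubules (3 longitudinal, 21 spermatid+)

report <- build_section_report(seg$section_mask, seg$tubule_labels,
                               um_per_px = 1, seg$flags,
                               n_sample = 100, seed = 7)
#> total_testis_area         6.36160e+05     # um^2; truth: pi * 450^2 = 636172
#> total_testis_perimeter    2.84238e+03     # um;   truth: 2 * pi * 450 = 2827
#> total_testis_diameter_avg 8.99992e+02     # um;   truth: 900
#> total_tubule_count        30
#> spermatid_positive_count  21
#> bergmann_kliesch_pct      70              # exactly the planted fraction
#> sum_all_tubule_areas      2.10877e+05
#> interstitial_area         4.25283e+05
#> tubule_area_ratio_pct     3.31484e+01
#> tubule_number_density     4.71579e-05     # pieces/um^2

ihc <- render_ihc(scene)                 # Beer-Lambert H-DAB field, DAB OD 0.8
m   <- measure_ihc(ihc$image, ihc$tissue_mask, counterstain_threshold = 240)
#>   positive_pct        od dab_threshold
#> 1     15.85104 0.8044802            40
```

The section geometry lands within a fraction of a percent of the analytic
truth, the Bergmann–Kliesch score and tubule count are exact, and the
uncalibrated OD recovers the planted DAB density of 0.8 up to 8-bit
quantization. `run_pipeline(run_config(...))` wraps the same steps and writes
per-tubule, section and IHC CSV reports plus a numbered overlay image and a
full parameter log; `inst/scripts/cathi.R` exposes everything as a
command-line tool (`phantom | segment | measure | ihc | run`).

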