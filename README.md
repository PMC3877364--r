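# neowmsa

Atlas-guided detection and quantification of **white matter signal
abnormality** (WMSA, also called DEHSI — diffuse excessive high signal
intensity) on T2-weighted brain MRI of very preterm infants around
term-equivalent age.

WMSA is the most common imaging finding in very preterm neonates, but its
T2 signal overlaps heavily with cerebrospinal fluid, so naive intensity
thresholding confuses the two, and qualitative readings are unreliable.
This package implements a fully automated pipeline for researchers in
neonatal neuroimaging:

1. **Probabilistic atlas construction** — two-pass group templating of
   segmented subject images plus averaged CSF/GM/WM tissue probability maps,
   behind a pluggable registration-backend contract (`identity`,
   `translation`, and a lightweight diffeomorphic `demons` backend are
   shipped).
2. **Prior-guided tissue segmentation** — per-class Gaussian mixtures
   (3 GM / 2 WM / 2 CSF / 5 other) combined with warped atlas priors by
   Bayes' rule, with a shared multiplicative bias field modelled on a
   3-D discrete-cosine basis (the unified-segmentation idea), estimated by
   EM with a guaranteed non-decreasing objective.
3. **Joint membership fusion** — the intensity-model membership
   μ_unified and the atlas membership μ_atlas are fused per voxel and class:

   μ_ij = μ_unified(ω_j|x_i)^p · μ_atlas(ω_j|x_i)^q / Σ_c μ_unified(ω_c|x_i)^p · μ_atlas(ω_c|x_i)^q

   with equal weights p = q = 1 by default.
4. **WMSA detection** — voxels whose intensity is **at or above
   mean + α·SD of cerebral tissue (WM + GM)**, restricted to voxels the
   joint segmentation calls WM or GM (this candidate domain is how the atlas
   guidance resolves the WMSA/CSF overlap).  The default α = 1.4 is
   calibrated by phantom simulation, and `calibrate_alpha()` reproduces that
   calibration end to end.
5. **Quantification & statistics** — volumes in mm³ for the entire WM, the
   periventricular slab, and the two-slice centrum semiovale; Pearson r,
   simple linear regression and one-at-a-time covariate-adjusted regression
   against developmental outcome scores.

A first-class **phantom simulator** generates preterm-like brains with known
WMSA ground truth (class mean intensities CSF 400, WM 260, GM 190, WMSA 340;
Rician noise at a stated SNR; a smooth multiplicative intensity-nonuniformity
field spanning 0.9–1.1), plus the seven confusion-matrix validation metrics
(TPR, TNR, FPR, FNR, precision, accuracy, Dice).

All volumes are read/written as NIfTI-1 (`.nii` / `.nii.gz`).

## Worked example

Simulate a phantom, run the full pipeline against its own anatomy-derived
priors, and compare against ground truth:

```r
library(neowmsa)

spec <- phantom_spec(shape = c(64, 64, 64), snr = 15, inu_level = 0.2, seed = 7)
ph <- generate_phantom(spec)
print(ph$labels)
#> <LabelVolume 64x64x64, spacing 1x1x1 mm>
#>     bg    CSF     GM     WM   WMSA
#> 201976  11420  18752  25604   4392

d <- tempfile(); dir.create(d)
write_nifti(ph$image, file.path(d, "image.nii.gz"))
write_nifti(ph$labels, file.path(d, "labels.nii.gz"))

cfg <- pipeline_config(image = file.path(d, "image.nii.gz"),
                       labels = file.path(d, "labels.nii.gz"),
                       output_dir = file.path(d, "out"), alpha = 1.4,
                       frontal_horn_first_slice = "auto",
                       midbody_last_slice = "auto")
res <- run_full_pipeline(cfg)
print(res)
#> <WMSAResult alpha=1.40 threshold=306.01 entire=4302 mm^3 pv=3040 mm^3 cs=334 mm^3>
```

The detected WMSA volume (4302 mm³) is within 2% of the 4392 mm³ of
ground-truth lesion; the threshold 306.0 is mean + 1.4·SD of the
bias-corrected WM+GM intensities.  `out/` now holds the hard segmentation,
the WMSA mask, the bias field, per-class membership maps, a `result.csv`
quantification row and a `run_log.json`.

Relating volumes to outcome scores (here on a simulated cohort table; any
CSV with the same columns works):

```r
tab <- simulate_outcome_table(n = 38, seed = 2)
simple_linreg(tab$centrum_semiovale_mm3 / 1000, tab$language)
#> Y = 98.15 + -3.979 X   (r = -0.4407, R^2 = 0.1942, p = 0.00562, n = 38)
```

i.e. each additional cm³ of centrum semiovale WMSA is associated with a
~4-point lower standardized language score in this synthetic cohort
(p < 0.05, two-sided).

## Command line

```sh
inst/cli/neowmsa simulate --out-dir phantom --snr 15 --seed 1
inst/cli/neowmsa detect --image phantom/image.nii.gz --labels phantom/labels.nii.gz \
    --out-dir run --alpha 1.4 --frontal-horn-slice auto --midbody-last-slice auto
inst/cli/neowmsa calibrate-alpha --snr 10,15,20 --out calibration.csv
inst/cli/neowmsa report-stats --csv outcomes.csv --out report.csv
```

Subcommands: `simulate`, `build-atlas`, `segment`, `detect`,
`calibrate-alpha`, `report-stats`.  A `--config file` of `key = value` lines
supplies defaults; explicit flags win.  Exit codes: 0 success, 1 user error,
2 internal error.

## Documentation

The methods vignette (`vignettes/wmsa-detection.Rmd`) describes the model
and its assumptions, the calibration world and what it does and does not
emulate, numerical choices, and known limitations.
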