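# llsmtrace

Quantitative live-cell analysis of ESCRT-III (Snf7, Vps24) and Vps4
recruitment dynamics on yeast endosomes imaged by lattice light-sheet
microscopy (LLSM).

The ESCRT machinery buds intraluminal vesicles into endosomes in seconds:
ESCRT-III filaments assemble abruptly, fluctuate with no net growth, and
release all at once, while the AAA+ ATPase Vps4 joins and leaves in
hexamer units.  Measuring this from movies means converting raw EMCCD
counts into molecule numbers per event.  `llsmtrace` implements the full
chain for whole-cell 3D time series (t × z × y × x):

* **Preprocessing** — flat-field correction, camera-offset handling,
  deskewing of stage-scanned stacks (500 nm stage step at 31.5° → 261 nm
  z-spacing), optional Richardson–Lucy deconvolution for visualization.
* **Detection** — difference-of-Gaussians candidates, 3D asymmetric
  Gaussian fits `A·G(σ_xy, σ_z) + c` with heteroscedastic (sandwich)
  parameter errors and a per-spot amplitude t-test against the local
  background.
* **Tracking** — exact linear-assignment linking with gap closing,
  merge/split flags, the strict validity rules (complete lifetime inside
  the series, ≥ 1.5 µm from every volume edge, significance-accepted
  spots only), and class I (mobile, diffraction-limited endosome) vs
  class II (bright static perivacuolar cluster) labels.
* **Calibration** — the single-eGFP intensity unit µ₁ from a constrained
  Gaussian mixture (component *k* has mean *k*µ₁ and variance *k*σ₁²),
  and conversion `N = A/µ₁` with propagated error
  `σ_N = sqrt((σ_A/µ₁)² + (A·σ_µ₁/µ₁²)²)`; Snf7 ×3 labeling correction
  and hexamer quantization `round(N/6)`.
* **Trace statistics** — truncated bi-exponential lifetime fits,
  maximum-accumulation mixture modes, lifetime cohorts, two-channel
  cross-correlation of intensities and their derivatives, fluctuation
  peaks by topographic prominence, productive-event classification
  (≥ 4 Vps4 hexamers), FRAP recovery fits, KS / permutation / bootstrap
  inference.
* **Synthetic data** — ground-truth scenes (recruitment events, mobile and
  perivacuolar emitters, two coupled spectral channels with mCherry
  photobleaching) rendered through an EMCCD forward model, so the whole
  pipeline is verifiable without microscope data.

See `vignettes/llsmtrace-methods.Rmd` for the models, parameter defaults
and numerical choices.

## Worked example

Simulate a cell, render it through the imaging model, and run the complete
analysis:

```r
library(llsmtrace)
res <- run_pipeline(run_config(seed = 11, n_volumes = 40))
res$calibration
#> calibration_curve: unit intensity 106.61 +/- 0.88 counts (200 spots, K = 3, 63 ms)
str(res$summary)
#> List of 8
#>  $ n_tracks             : int 9
#>  $ n_valid              : int 5
#>  $ n_persistent         : int 0
#>  $ n_rejected           : int 4
#>  $ unit_intensity       : num 107
#>  $ mean_lifetime        : num 10.5
#>  $ mean_max_accumulation: num 54.1
#>  $ productive_fraction  : num 1
res$events[, c("lifetime", "max_accumulation", "max_hexamers", "class_label")]
#>   lifetime max_accumulation max_hexamers class_label
#> 1     6.80             76.8           13           I
#> 2     5.95             49.4            8           I
#> 3    23.80             63.3           11           I
#> 4    12.75             44.2            7           I
#> 5     3.40             36.9            6           I
```

The calibration recovers the single-fluorophore unit from a rendered
coverslip field (106.6 counts at the 63 ms calibration exposure; the true
value for these settings is 105.4).  Nine tracks are linked; five survive
the validity rules as class I events.  Their lifetimes (3.4–23.8 s) fall
in the observed 3–45 s range, and the measured maximum accumulations
(37–77 molecules) scatter around the configured 60-molecule Snf7 burst —
each event's molecule trace is reconstructed within its propagated error.
Rejected tracks carry machine-readable reasons (`near_border`, `merged`,
`touches_series_start`, ...).

A thin command-line front end over the same functions lives at
`inst/scripts/llsmtrace.R`
(`Rscript llsmtrace.R simulate|prep|detect|track|calibrate|analyze|all
--seed N --out DIR`).

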