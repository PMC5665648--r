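---
title: "Counting ESCRT-III and Vps4 molecules on endosomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting ESCRT-III and Vps4 molecules on endosomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llsmtrace)
```

## The measurement problem

ESCRT-III filaments (Snf7, Vps24) and the AAA+ ATPase Vps4 assemble
transiently on yeast endosomes, bud intraluminal vesicles, and disassemble
within seconds.  Following single recruitment events across a whole cell
requires volumetric imaging fast enough to outrun the dynamics (sub-second
per volume) and gentle enough to watch for a minute, i.e. lattice
light-sheet microscopy (LLSM), plus a chain of quantitative steps that turn
raw EMCCD counts into molecule numbers:

1. geometric preprocessing of the stage-scanned (sheared) stacks,
2. 3D detection and Gaussian fitting of diffraction-limited spots,
3. frame-to-frame tracking with strict validity rules,
4. calibration of the single-eGFP intensity unit, and
5. trace-level statistics (lifetimes, accumulations, correlations).

`llsmtrace` implements this chain together with a synthetic-data module
that renders ground-truth scenes through the same imaging physics, so every
stage is tested against known truth without any microscope data.

## Acquisition geometry

The sample stage steps along the scan axis `s` at 500 nm per plane while
the sheet stays fixed, so a recorded stack is sheared: plane $k$ is
laterally displaced by $k\,s\cos\theta$ and axially advanced by
$k\,s\sin\theta$.  With $s = 500$ nm and $\theta = 31.5^\circ$ the axial
spacing is $\approx 261$ nm.  Sixty volumes at 850 ms spacing give a 51 s
series; each plane is exposed for 21 ms.  `deskew()` resamples each plane
onto a common orthogonal grid by linear interpolation along x (the exact
inverse of the shear applied by the `skewed = TRUE` rendering path, which
round-trip tests exploit), declares the 261 nm z-spacing, and refuses to
run twice.  Out-of-field voxels are filled with the plane median — a
local-background estimate — and the fill is recorded in the provenance log;
intensity-conservation tests use a zero fill instead.

Richardson–Lucy deconvolution (15 iterations, measured background
subtracted and clamped first) is available for visualization but is **off**
in the quantitative path: detection and fitting run on non-deconvolved
data, because deconvolution redistributes intensity and would break the
amplitude calibration.  The camera offset is subtracted (clamped at zero)
before any multiplicative step, since flat-fielding and RL assume
Poisson-scaled data.

## Imaging forward model

The renderer distributes the expected photons of each emitter —
`molecules x photon_rate x exposure x QE x bleach survival` — over voxels
with an anisotropic Gaussian PSF ($\sigma_{xy} = 110$ nm,
$\sigma_z = 380$ nm; typical LLSM values, configurable).  EMCCD counts are
`offset + gain x F^2 x Poisson(lambda / F^2) + read noise`, which
reproduces the mean and the excess-noise-inflated variance
($F^2 \approx 2$) of an EM register without simulating the gain cascade.

The default photon budget (4.5 detected photons per molecule per ms, QE
0.9, background 0.1 photons/voxel/ms) is set so that a 3-eGFP spot is
recorded at SNR $\approx 4$, the middle of the instrument's stated 3–5
sensitivity band; `snr_experiment()` measures this end to end.  The
mCherry channel carries half the photon budget and a bleach rate of
0.08/s, chosen so that over a typical event only roughly a third of
second-channel traces stay bright enough to analyze — the situation that
motivated restricting the two-channel correlation analysis.

## What the generator emulates — and what it does not

`build_scene()` reproduces the statistical structure the analysis assumes:

* **Class I** — 5–10 mobile diffraction-limited endosomes per cell,
  diffusing at 0.005 um^2/s (typical endosome mobility; ~90 nm RMS step
  per axis per 850 ms frame), each carrying one recruitment event.
* **Events** — abrupt onset to a quantized `Normal(burst, sd)` level
  (defaults 60 Snf7, 14 Vps24, 20 Vps4 molecules), a balanced birth–death
  exchange with zero mean drift ("patternless fluctuation"), and
  all-or-none release in a single frame.  Vps4 joins and leaves in units
  of six (hexamers).  Lifetimes follow a bi-exponential mixture
  ($w = 0.7$, $\tau_1 = 4$ s, $\tau_2 = 20$ s) truncated to the observed
  3–45 s range; the fit parameters are not printed in the source
  quantifications, so these defaults were chosen once to reproduce the
  reported range and short-lifetime dominance and are exposed as
  configuration.
* **Class II** — static perivacuolar clusters (frame-to-frame SD
  < 0.25 px) summing 3–5 asynchronous events.  Sub-events get long,
  mostly overlapping lifetimes so the summed plateau runs at 3–5x a
  single event while fluctuations stay of single-event magnitude.
* **Coupling** — an optional second channel proportional to the first
  (gain 1/3, independent noise SD 0.5 molecules), so the true
  cross-channel correlation peaks at lag 0 by construction.

It does **not** emulate vacuole autofluorescence, cytosolic pools with
spatial structure, optical aberrations or PSF depth-dependence, stage
drift, or chromatic offsets.  Passing tests therefore demonstrate that the
algorithms are correct under the stated noise model, not that real movies
are free of those artifacts.

## Detection and fitting

Candidates are 26-connected local maxima of a difference-of-Gaussians
response at the PSF scale, thresholded at 6 robust SDs of the response.
A 3-molecule spot sits at 9–15 response SDs, so this threshold keeps full
recall at the stated sensitivity floor; a truly permissive threshold would
instead select extreme noise peaks whose subsequent amplitude t-tests pass
disproportionately often, flooding the tracker with single-frame tracks.
Final acceptance remains the per-spot significance test.

Each candidate is fitted with `A\,G(\sigma_{xy}, \sigma_z) + c` over a
4-sigma window (lateral widths tied, matching the axially elongated PSF;
a constant local background).  Two numerical safeguards matter:

* **Width floor.**  Nothing images narrower than the PSF, so fitted widths
  are bounded below at 0.8x the PSF; without this, width collapse onto
  noise biases amplitudes upward at low SNR.
* **Sandwich errors.**  Shot noise concentrates at the spot peak, so the
  homoscedastic least-squares covariance understates the amplitude error
  about two-fold.  Parameter SEs use the leverage-corrected (HC3)
  heteroscedastic sandwich over the fit Jacobian; with it, the propagated
  molecule-number error covers the generator truth at the nominal rate.

Significance is a one-sided t-test of $A / \mathrm{SD}(A)$ against the
local residual noise (degrees of freedom = window voxels minus free
parameters), accepted at $\alpha = 0.05$ — the test is stated in the
source methods without a level, and 0.05 is the conventional choice.
Spots within 1.5 PSF sigma of a volume face are not fitted.  On
calibration fields (immobile in-vitro point sources of known PSF) the fit
pins the widths to the PSF (`fix_sigma = TRUE`), which removes the
remaining free-width amplitude bias at single-molecule SNR; the free-width
fit used in cells is unbiased within 5% from ~12 molecules up, i.e. over
the whole range of reported trace levels.

## Tracking and validity

Frame-to-frame linking solves the exact linear assignment problem
(Jonker–Volgenant) on squared displacements, gated at 800 nm/frame
(several times the diffusive step at 850 ms spacing), with gap closing
over up to 2 missing frames; competing gate memberships set merge/split
flags.  Valid tracks never merge or split, begin after the first and end
before the last frame, contain only significance-accepted spots, keep
every position at least 1.5 um from every volume edge (applied per spot —
stricter and unambiguous), and span at least 3 frames (about the shortest
reported lifetime).  Tracks spanning the entire series are routed to a
separate *persistent* set, excluded from lifetime fits but retained for
fluctuation analysis.  Class I/II labels follow fitted width (median
lateral sigma within 30% of the PSF = diffraction-limited), mobility
(mean step >= 100 nm/frame), and brightness (static objects at >= 3x the
class I median amplitude are class II); dim static point-like objects stay
unclassified.

## Calibration: counts to molecules

Spot amplitudes from a sparse single-eGFP field are fitted with a
*constrained* Gaussian mixture: component $k$ (a $k$-mer) is forced to
mean $k\mu_1$ and variance $k\sigma_1^2$, the distribution of $k$
independent fluorophores.  The constraint encodes the photophysics and
stabilizes EM; the component count (up to 4) is chosen by BIC, and
$\mathrm{SE}(\mu_1)$ comes from the observed information.  Because single
fluorophores are dim at the 21 ms live exposure, the calibration series is
rendered at 3x that exposure and $\mu_1$ rescaled linearly — the
calibration curve is linear in exposure by construction, which is also why
a curve recorded at several exposures can serve a single live setting.

Conversion propagates both uncertainties:
$N = A/\mu_1$, $\sigma_N = \sqrt{(\sigma_A/\mu_1)^2 +
(A\,\sigma_{\mu_1}/\mu_1^2)^2}$ — verified against Monte-Carlo
propagation.  Negative amplitudes (baseline noise) keep their sign.  The
x3 Snf7 labeling correction (only a third of Snf7 is tagged) is an
explicit function, never folded silently into reported counts, and hexamer
quantization rounds to the nearest integer (half up), consistent with the
quoted conversions 20 -> 3 and 11 -> 2.

## Trace statistics

* **Lifetimes** are occupied frames x 850 ms.  The bi-exponential fit is
  maximum likelihood with left truncation at the shortest observable
  lifetime; a likelihood-ratio test against the nested single exponential
  (5% chi-square level, 2 df) decides whether the second component is
  real.  CIs by nonparametric bootstrap.
* **Maximum accumulation** distributions are summarized by the lowest-mean
  component of an unconstrained Gaussian mixture fitted by multi-start EM
  (quantile-based plus random starts, best likelihood kept) with BIC
  collapse of redundant components.  Multi-start matters: off-the-shelf
  single-initialization EM lands in a local optimum about one molecule low
  on the Snf7-like mixture.
* **Cohorts** group traces by lifetime bins (defaults [3,5), [5,10),
  [10,51] s — the source figure does not print its bins; configurable),
  align at onset, and average with a percentile-bootstrap 95% bound;
  cohorts under 10 traces are dropped and logged.
* **Cross-correlation** is the per-pair Pearson correlation at each lag of
  mean-subtracted intensities and of their first differences (the
  estimator is not stated in the source; per-pair Pearson over the overlap
  window is the standard choice), averaged across pairs with SD; pairs
  shorter than 11 s are excluded.
* **Fluctuation peaks** use topographic prominence with defaults of one
  hexamer (6 molecules) for Vps4 and 10 for Snf7 — no prominence is stated
  in the source; these sit above the instrument noise floor (~2.5
  molecules SD on a 50-molecule bead) and below single-event magnitudes.
* **Productive events** reach >= 4 hexamers at some frame (per-frame
  quantization, then the maximum).
* **FRAP** traces are background-corrected, optionally bleach-corrected by
  a reference-region exponential, normalized to the first frame, and fitted
  with a single-exponential recovery; traces whose recovered amplitude is
  indistinguishable from the residual noise are flagged `no_recovery`.

Statistical comparisons use the two-sample KS test (asymptotic p, exact
behind a flag), a two-sided permutation test for means or medians that
switches to exhaustive enumeration automatically when feasible (making
small-sample p-values exact), and percentile-bootstrap CIs.

## Problem sizes and determinism

The test suite and worked examples run reduced fields (typically
80 x 80 x 24 voxels, 15–60 frames, 200-spot calibration fields, 2,000
lifetimes, 5,000-value mixture samples) — large enough for the quoted
tolerances, small enough to iterate on a laptop.  All randomness flows
through R's RNG, so a fixed seed reproduces scenes, renders and the whole
pipeline bit-identically; the test suite asserts this end to end.

## Known limitations

* The EMCCD model is a scaled-Poisson approximation; it matches mean and
  variance but not the exact EM output distribution, so extreme-tail
  false-positive rates are approximate.
* Free-width amplitude estimates retain a ~3% upward bias at the 3-molecule
  sensitivity floor (position freedom at SNR ~4); reported trace levels sit
  well above it.
* The tracker is frame-local (no track-segment stitching beyond gap
  closing); crossing trajectories are flagged rather than resolved, which
  matches the conservative validity rules but discards those events.
* Class II quantification inherits the single-Gaussian spot model; for
  clearly extended clusters the "amplitude" is an effective brightness,
  which is why class II objects are analyzed through fluctuation peaks
  rather than absolute totals.
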