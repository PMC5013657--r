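---
title: "Methods: height mapping, conformational classification and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: height mapping, conformational classification and the synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tqdf)
```

This vignette documents the models, assumptions and numerical choices
behind `tqdf`: how TIRF intensity becomes nanometre height, how reporter
clusters are segmented and classified, how cells and clusters are tracked,
and what the synthetic scene generator does and does not emulate.

## 1. Evanescent-field height mapping

Beyond the critical angle, excitation light forms an evanescent field
whose intensity decays exponentially with distance from the glass–medium
interface.  The decay length is

$$d = \frac{\lambda}{4\pi\sqrt{n_1^2\sin^2\theta - n_2^2}},$$

about 79.9 nm for the 488-nm line and 104.9 nm for the 641-nm membrane
channel at $\theta = 70^\circ$, $n_1 = 1.515$ (standard coverslip and
immersion oil; not instrument-specific), $n_2 = 1.338$ (aqueous medium).
A membrane patch at height $\Delta$ is excited by $e^{-\Delta/d}$ of the
interface intensity, so the membrane-dye channel inverts to

$$\Delta = d\,\ln\!\frac{I_0}{I - \mathrm{background}}.$$

Three conventions bound this inversion:

* **Validity range.** Heights are only reported within 200 nm of the
  interface; pixels mapping deeper are marked invalid rather than
  extrapolated, since the exponential has no practical contrast there.
* **Clipping.** Pixels brighter than $I_0$ (shot noise on near-interface
  membrane) clip to $\Delta = 0$.
* **Background subtraction before the log.** Whether camera background is
  subtracted before or folded into $I_0$ is underdetermined by the
  published method descriptions; subtracting first is the package's
  documented choice and the renderer uses the same convention, so round
  trips are exact.

**Reference-intensity estimation.** Without an instrument calibration,
`estimate_reference_intensity()` estimates the background as the centre of
the dark intensity population — from the 5th/20th-percentile dark tail,
which stays valid as long as roughly a fifth of the field is off-cell —
and takes $I_0$ as the 99.5th percentile of background-subtracted signal
pixels (those more than 5 noise SDs above background).  A frame with fewer
than 10 signal pixels is reported as containing no cell.  The estimator is
biased low by $e^{-\Delta_{\min}/d}$ when no membrane touches the
interface; with microvillus tips a few nm from the glass the bias is a few
nm of height.  A measured $I_0$ can always be supplied via `fixed_i0`.

**Footprint.** The footprint is the largest connected component with
$\Delta \le 95$ nm.  `min_px` (pipeline default 50) discards shot-noise
satellites in frames where no cell is present.

## 2. Cluster segmentation

Reporter channels are segmented by local-background pixel classification:
a pixel is signal when it exceeds the median-filtered local background
(window 15 px, larger than a cluster diameter) by more than $k = 3$ robust
noise SDs; signal pixels form 8-connected components and components under
4 px are dropped.  This reproduces the *behaviour* of the interactive
pixel-classification tool used for such data — comparing each cluster with
its local background — without its proprietary internals.

One addition proved necessary: **per-component amplitude refinement**
(`refine_fraction`, default 0.4).  Because cluster signal is far above the
noise floor, the Gaussian PSF spreads a halo that itself clears the
$k\sigma$ threshold, inflating a 25-px cluster to ~48 px and occasionally
bridging neighbours.  Each component therefore keeps only pixels above 0.4
of its peak (90th-percentile) background-subtracted intensity.  The value
0.4 sits between the halo level immediately outside a cluster edge
(≤ ~0.45 of peak) and the within-cluster attenuation across the height
range a single cluster typically spans (≥ ~0.5), restoring detected areas
(~26 px) and per-pixel topography statistics.  A cluster straddling a
large height step can still lose its deep part; across seeds this costs at
most one count per class.

**Hills and valleys.** The footprint is partitioned by maximizing the
between-class variance of the height histogram (Otsu's criterion) on
$\Delta$; hills are the low-$\Delta$ class because the membrane over
microvillus tips sits nearest the interface.  The published analyses do
not state whether the partition was computed on intensity or height, nor
the threshold rule; height + Otsu is the package's resolution of that open
question, and a fixed-quantile alternative is available via `method`.

## 3. Classification and tracking

Pixels positive in both reporter masks are E+H+, KIM127-only E+H−,
mAb24-only E−H+; the classes partition the reporter union by
construction, and exchanging the channels exchanges E+H− and E−H+ exactly
(the dye-switch control).  A connected component with mixed pixels is
counted once with its majority class, ties resolved toward the
double-positive state; the original colour-counting procedure was manual
and states no rule.

Cell velocity is the forward difference of footprint centroids, assigned
to the interval's first frame; arrest is the first frame whose velocity
falls below 0.1 µm/s and stays below it for 3 consecutive frames.  The
confirmation window is the package's guard against single-frame centroid
noise (the published definition states only the threshold); with the
forward-difference convention the first stationary frame is itself the
detected arrest frame.  A below-threshold run truncated by the end of the
movie still counts.

Clusters are linked frame-to-frame by greedy maximum pixel overlap after
compensating the cell's centroid motion (integer-pixel shifts), accepting
matches with overlap ≥ 0.3 of the smaller cluster.  A track's initial
class is its majority class at first observation; its duration is the time
to the first E+H+ pixel appearing anywhere in the tracked component,
matching the way cluster lifetimes are scored from colour images.  The
"fraction transitioned within 4 s" summary treats the window in seconds
(not frames), the natural reading at 1 frame/s.

## 4. Molecular quantification

Bead calibration is ordinary least squares of MFI on known
antibody-binding capacity; sites per cell invert that line with a zero
floor.  Footprint scaling divides by the spherical surface $\pi D^2$ —
microvillus excess area is ignored, a known downward bias on surface area
(hence an upward bias on footprint sites) documented rather than modelled.
FRET efficiency is donor quenching $E = 1 - F'_D/F_D$; baselines and
plateaus are means before the addition and within a 2–3-min
post-addition window.  The overlap integral is trapezoidal on the common
wavelength grid, in nm⁴ M⁻¹ cm⁻¹, and the Förster radius uses the
practical constant $R_0 = 0.02108\,(\kappa^2 Q_D \eta^{-4} J)^{1/6}$ nm,
validated in the test suite against a brute-force SI-unit evaluation of
$R_0^6 = 9000\ln(10)\,\kappa^2 Q_D J / (128\pi^5 N_A \eta^4)$ (agreement
0.02%).  The shipped spectra (`synthetic_fret_spectra()`) are synthetic
Gaussian shapes for exercising this machinery — they are not vendor
spectra, and the package makes no claim to reproduce measured
donor–acceptor distances or absolute molecule counts, which require
unpublished measured intensities; those published magnitudes serve as
worked-example scales only.

## 5. Statistics

`slope_test()` is the OLS F-test of a slope against zero (identically the
squared t statistic); `compare_slopes()` is the nested-model F-test of a
common slope.  Degenerate perfect fits are resolved exactly (flat ⇒ p = 1,
sloped ⇒ p = 0) instead of propagating 0/0.  Duration histograms (1-s
bins) are least-squares fitted with Gaussian, log-Gaussian and Lorentzian
peak models via Levenberg–Marquardt; "best" means lowest residual sum of
squares — the specific criterion used by the original graphing software is
unstated, and RSS is the package's documented choice.  Because a
log-Gaussian fitted to a monotone-decaying histogram pushes its peak
toward zero, each fit also reports `curve_mean`, the mean of the fitted
curve over the histogram support, which is the robust scale used to
compare cohorts.  Fits are refused below 5 non-empty bins (three-parameter
models would be underdetermined).

## 6. The synthetic scene generator

The generator defines the study conditions; its defaults are the
magnitudes reported for primary neutrophils wherever such values exist,
and fixed realism choices where they do not.

* **Topography.** A superposition of Gaussian bumps (microvilli) inside a
  circular contact disk, thresholded at the hill-fraction quantile
  (default 27%) and squashed through a sigmoid: a bimodal height field
  with hill tips near 5 nm and valley membrane near 82 nm, plus ~1.5 nm
  of smooth within-class variation, clipped to [0, 200] nm.  The valley
  level is deliberately more than two shot-noise SDs inside the 95-nm
  footprint cutoff so footprint membership does not flicker frame to
  frame; the published analyses measure topography but state no
  generative model, so these levels are the package's choice.
* **Clusters.** 9/9/3 E+H−/E−H+/E+H+ clusters of 25 px (~0.1 µm²) grown
  from seeds that land on hills with class biases 0.68/0.29/0.70; growth
  prefers the seed's terrain and seeds prefer patch interiors, so the
  pixel-level hill fraction of a cohort tracks its bias.  Clusters keep a
  3-px guard gap inside a 2.0-µm-radius disk — denser than a real
  footprint (a 64×64 px field at 64 nm/px cannot hold a 25-µm² footprint),
  which is the main respect in which passing recovery tests understates
  difficulty on real data with touching clusters.
* **Kinetics.** Discrete-time per-frame Markov transitions over the four
  allowed edges; probabilities are *per step* of the frame interval and
  are not rescaled with `dt` (recorded in the output metadata).  The
  extension pathway default $q = 1-(2/3)^{1/4}$ makes one third of E+H−
  clusters complete activation within four 1-s steps; the bent-open exit
  rate 0.11/step gives a mean E−H+ lifetime ~9 s, and `cis_block`
  multiplies it by 5 (mean ~1.8 s), meeting the >5 s / <2 s contrast while
  keeping the blocked-duration histogram fittable.  A side effect of
  running the 4-s rate for 30 s of rolling is that most clusters are fully
  activated by arrest — steeper kinetics than the published per-cell
  counts suggest; recovery tests therefore always compare against the
  generator's own ground truth.
* **Motion.** Constant-velocity drift (default 1.0 µm/s) along x ending
  at the image centre at arrest, then stationary; centroid jitter 0.02 µm
  while rolling and a tenth of that after arrest.
* **Rendering.** Membrane channel $bg + I_0 e^{-\Delta/d}$ inside the
  contact zone, reporter channels per-cluster amplitudes (log-normal ±10%
  labelling variation) attenuated by the same evanescent factor and
  blurred by a 0.6-px Gaussian PSF; the membrane channel is rendered
  unblurred so the height inversion is exactly invertible (membrane
  structure varies on scales well above the PSF).  Noise is Poisson shot
  noise plus 3-count Gaussian read noise.  Amplitudes and gain are free
  parameters chosen for realistic SNR; no fluorophore-level blinking or
  bleaching is modelled.
* **Not emulated.** Shear mechanics and bond kinetics, channel
  mis-registration, bleed-through, uneven illumination, cell shape change
  and spreading after arrest.  Passing tests on these scenes shows the
  analysis is correct under its stated model, not that it is robust to
  those artefacts.

## 7. Problem sizes and determinism

The test-bed sizes used by the test suite and the acceptance script —
64×64 px × 60 frames for the default scene, 80×352 px for rolling-arrest
scenes, 625-cluster cohorts for transition statistics, 500-cluster
cohorts per lifetime arm, 100 calibration replicates, 500 type-I-error
replicates — are the package's standard demonstration sizes; they give
binomial confidence intervals tight enough for the recovery checks while
keeping a full run in minutes on one core.  Every stochastic stage draws
from an explicit seed (scene stages use fixed offsets from
`rng_seed`), so identical configurations reproduce byte-identical
artifacts; the pipeline writes the effective configuration, its MD5 and
the package version next to its outputs.
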