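---
title: "Quantifying presynaptic potentiation at mossy fiber boutons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying presynaptic potentiation at mossy fiber boutons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonquant)
```

## What this package measures

Hippocampal mossy fiber boutons (hMFBs) are large presynaptic terminals whose
potentiation — for example after raising cAMP with forskolin — is expressed
presynaptically. Three imaging readouts triangulate the mechanism:

1. **Glutamate-sensor movies.** High-speed (1.6 kHz) two-photon movies of a
   membrane-bound, low-affinity glutamate sensor (Kd = 600 uM) report evoked
   cleft glutamate. Potentiation could act by releasing *more glutamate per
   site* (higher mean amplitude) or by *recruiting more release sites*
   (larger suprathreshold area at constant mean amplitude).
2. **gSTED coupling distances.** Two-color super-resolution imaging of
   presynaptic Cav2.1 calcium-channel clusters and Munc13-1 release-site
   markers, gated by a postsynaptic Homer1 spot, measures the
   channel-to-release-site coupling distance (tens of nm). Potentiation could
   tighten this coupling.
3. **Serial-section EM morphometry.** 3D reconstructions quantify active
   zone (AZ) density, vesicle pool geometry (density, pairwise dispersion,
   nearest-neighbor distances), docked/tethered vesicles (an anatomical
   proxy of the readily releasable pool), bouton complexity, and
   mitochondrial volume fraction.

Because the raw laboratory data are not recomputable from published numbers
alone, every analysis here is paired with a seeded synthetic-data generator
that emulates the statistical structure the analysis assumes, with full
ground truth. All tests and the acceptance script run on these generators.

## Transient quantification

Pixel traces are low-pass filtered and expressed as dF/F in percent of each
pixel's mean over the 50 ms before the first stimulus. A pixel is *active*
at a frame when its dF/F exceeds 3 x its own baseline SD. Per frame we
report: active area (um^2 and fraction of the bouton mask), cumulative
amplitude (the spatial integral of dF/F over active pixels, in % x pixel),
mean amplitude and maximal amplitude. Per-stimulus peaks are taken inside
the window from each stimulus to the next (50 ms after the last one,
matching the interstimulus interval); the paired-pulse ratio (PPR) is
peak2/peak1. The decay time constant comes from a least-squares
monoexponential fit, `A exp(-(t - t_peak)/tau) + c`, from the cumulative
trace's peak after the last stimulus to the end of the recording; the
offset `c` is free by default because real recordings carry residual drift.

Numerical choices:

- The filter is a zero-phase second-order Butterworth at 100 Hz. Zero-phase
  filtering avoids shifting peak times, which would bias the PPR windows.
  Because forward-backward filtering has edge transients, traces are
  odd-reflection padded (up to 150 frames) before filtering. Zero-phase
  filtering also smears the response a few ms *backwards*, so the last
  `filter_guard_ms` (default 10 ms) of the baseline window are excluded from
  the baseline mean and SD; without the guard, the smear inflates the
  suprathreshold threshold.
- The baseline SD is per pixel; a pooled (`sd_scope = "global"`) option
  exists for sensitivity analysis. The threshold is applied to the same
  filtered signal the SD was computed on; pass `filter_cutoff = NULL` to
  threshold unfiltered dF/F.
- Frames with no active pixel report cumulative 0 (a sum over an empty set)
  but mean and maximal amplitude as missing, not zero, so trace averages are
  not dragged toward zero.
- Units are ms, percent dF/F, and um^2 throughout; cumulative amplitude is
  % x pixel with the pixel size recorded so % x um^2 is derivable.

### The bouton generator

`simulate_bouton_movie()` draws release events per site and stimulus as
independent Bernoulli trials, spreads glutamate as an isotropic 2D Gaussian
(sd `spatial_sigma`, default 0.3 um), applies a linear-rise (1 ms) /
monoexponential-decay (10 ms) time course, and saturates the sensor as
`dff_max * G/(G + Kd)`. Fluorescence is `baseline * (1 + dFF/100) *
bleach(t)` plus Gaussian noise; bleaching is a single multiplicative
exponential, off by default (longitudinal experiments showed a roughly 50%
monotone decline, which this reproduces when enabled).

Two modelling decisions matter for testability:

- The Gaussian footprint is truncated at 3 sigma, so pixels outside a site's
  footprint stay *exactly* at baseline. This makes "the true active mask" a
  well-defined object and lets the noise-free recovery test demand exact
  equality.
- The per-stimulus truth mask is cumulative over events up to that stimulus:
  with a 10-ms decay and 50-ms interstimulus interval, the first response's
  tail is still strictly positive in the second window, and any positive
  signal is suprathreshold when noise is zero.

Per-site release probabilities and quantal cleft glutamate concentrations at
hMFBs are not established numbers. The defaults (`site_release_prob = 0.5`,
`glut_peak_conc = 3000` uM — a millimolar cleft peak that saturates the
low-affinity sensor near the release point) are documented placeholders, not
calibrated values. What the tests show on these synthetic movies is
correctness of the *measurement pipeline* (masks, integrals, fits), not
biological fidelity of release statistics; real data add motion, optical
blur between pixels, and non-Gaussian noise that the generator deliberately
omits.

## Entropy and non-triviality of 2D patterns

To quantify whether release is spatially homogeneous or structured, each
frame's dF/F field is reduced to ordinal patterns: every 2 x 2 window
(stride 1) is encoded by the rank permutation of its four values, ties
broken by raster position, giving 24 possible patterns. We report

- normalized entropy `H = -sum(p log p)/log 24` of the pattern
  distribution: 0 for constant or globally monotone fields, near 1 for
  i.i.d. noise;
- non-triviality `C = H * Q_JS`, with `Q_JS` the Jensen-Shannon divergence
  between the pattern distribution and the uniform one, normalized to
  [0, 1]. `C` vanishes in both the fully ordered and the fully random limit
  and is larger for anisotropic, oriented structure at intermediate entropy.

The 2 x 2 cell, raster tie-break, and bounding-box masking (windows touching
pixels outside the dilated bouton mask are dropped; margin default 2 px) are
configuration options. The time course reports amplitudes from the
pre-stimulus baseline mean to the frame of peak cumulative response, signed
so the canonical evoked effect — entropy falls, non-triviality rises — is
positive in both.

A caveat on the homogeneity contrast: with only a handful of discrete
release sites on a 13 x 13 grid, the field at the response peak is dominated
by smooth inter-site gradients and is *more* ordered than a single-site
response. The pattern statistics read release as homogeneous only when
saturating footprints actually tile the analysis region (sites dense enough
and noise non-negligible); the corresponding test therefore contrasts one
site against a tiling configuration (30 sites) rather than against 8
scattered ones.

## STED coupling distances

The measurement chain mirrors the bench procedure: Richardson-Lucy
deconvolution with a unit-sum 2D Lorentzian PSF (FWHM 40 nm; profile
`1/(1 + (r/gamma)^2)`, `gamma = FWHM/2`), prominence-gated intensity maxima,
triads of juxtaposed Cav2.1/Munc13-1/Homer1 signals, then a 1-pixel straight
line through both maxima extended 10 px past each end; the distance is
between the two channels' intensity maxima along that line, with no subpixel
interpolation (an optional bilinear mode exists for sensitivity analysis).

Decisions and defaults:

- The Lorentzian has no finite integral in 2D, so the kernel is truncated at
  10 x FWHM and renormalized; convolutions use replicate padding so a flat
  field is a Richardson-Lucy fixed point and flux is conserved to ~1%.
- The iteration count is not a published quantity; the default is 30,
  a conventional operating point at which the two-spot recovery test
  resolves 100-nm separations.
- Triad gating replaces manual synapse selection: Cav-Munc candidate pairs
  are matched greedily by ascending distance, one-to-one, accepting a pair
  only if both members lie within `homer_radius` (200 nm) of a common Homer
  spot; `pair_radius` defaults to 250 nm, beyond the largest distances seen
  in the data. Both radii are echoed in every result table.
- The prominence threshold is defined on the deconvolved intensity scale and
  is therefore instrument- and pipeline-specific; 20 is the default
  (with 10 exposed as the documented alternative used for a dim subset).
  On the synthetic fields, true deconvolved peaks reach ~10^3 counts while
  Richardson-Lucy noise speckle stays below ~50, so analyses of generator
  output use a gate of 50 — comfortably between the two populations rather
  than tuned against either.

The generator places triads with uniformly random orientation, separation
drawn from a configurable family (point mass, truncated normal, uniform),
and the Homer spot displaced perpendicular to the Cav-Munc axis (the cleft
is trans-synaptic); point sources are rendered by evaluating the PSF at
pixel centers, which is exactly the convolution of a delta with the PSF.
Distances quantize to the 20-nm pixel grid; the quantization is unbiased, so
a 500-synapse mean recovers the generative mean within one standard error,
and a 10-nm generative shift is recovered as 10 +/- 2 nm — the scale of the
CA3-vs-CA1 regional contrast.

## EM morphometry

All inputs are segmented geometries (polygons, polylines, vesicle centers)
in the documented JSON schema; no pixel segmentation is performed. The
statistics follow the study's definitions: complexity = perimeter/area of
the largest presynaptic profile (1/um); volume = sum of profile areas x
70-nm section thickness; AZ density = distinct AZ count per um^3 with AZ
identity explicit via `az_id` (deterministic, rather than inferred from
overlap); per-AZ area = trace length x thickness summed over sections;
vesicle density = count/volume.

Two estimators needed a decision:

- *Pairwise dispersion* ("distance from each vesicle to all others,
  normalized by stack volume") is ambiguous between the sum, the per-vesicle
  mean, and the pair mean — all dimensionally consistent with nm/um^3. The
  default is the mean over unordered pairs divided by volume; `"sum"` and
  `"per_vesicle"` variants sit behind a flag, and all reports state the
  default. Group contrasts (uniform vs clustered) are invariant to the
  choice at fixed n and volume.
- *Docked/tethered cutoffs* are not numeric in the source: docked = gap
  (center distance to the nearest same-section AZ membrane segment minus
  vesicle radius) <= 2 nm; tethered = not docked with center <= 60 nm,
  following the stated readily-releasable-pool approximation. Both are
  arguments.

Vesicle z is the section mid-plane; the z-projection bias this creates in
the 2D MNND (a slight underestimate) is reproduced, not corrected, to match
the published estimator. The generator reuses one rough-edged profile across
sections (a prism) so the ground-truth volume is exact; mitochondria are a
centroid-scaled copy of the profile with exactly the configured area
fraction; AZ arcs occupy disjoint perimeter segments; docked vesicles sit at
exact membrane contact and tethered ones are rejection-sampled into the open
shell (gap > 4 nm, center <= 58 nm) so generated labels are unambiguous
under the classification defaults; free vesicles keep a hard-core distance
(one diameter) within sections and stay out of the 60-nm AZ shell so the
ground-truth docked/tethered counts are exact.

## Group statistics

`compare_groups()` reproduces the reporting logic: samples are gated by the
D'Agostino-Pearson omnibus normality test (implemented from the standard
skewness and kurtosis Z-transforms; the omnibus statistic needs n >= 8, so
smaller groups are conservatively routed to the nonparametric branch, with a
note). Two normal groups get an unpaired two-tailed t test, upgraded to the
Welch correction when an F test rejects variance equality at alpha = 0.05
(the gate the source leaves unnamed); otherwise the two-tailed Mann-Whitney
U test is used, exact for min(n) <= 8 without ties. Distribution-level
questions use the two-sample Kolmogorov-Smirnov test; longitudinal designs
force a paired t test with a logged normality caveat. Stars follow strict
thresholds: * < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001. Pooled
(per-observation) and per-animal summaries are always both computed; no
multiple-testing correction is applied, matching the source reporting — a
known limitation, as is the absence of mixed-effects modelling for the
nested animal/synapse structure.

## Problem sizes and limitations

The test and acceptance runs use desk-scale problem sizes chosen to make the
statistical checks sharp without waste: 13 x 13 x 320-frame movies; 256^2
noise fields for the entropy limits; 25 STED fields of 320 x 320 px with 20
triads each (n = 500 synapses, the order of the study's per-condition n) for
distance recovery, run twice for the shift contrast; 100-seed power and
ordering checks; 2,000-seed null calibration at n = 20 per group. The
generators emulate the statistical structure the analyses assume — they do
not model optics beyond the stated PSF and saturation, photon budgets,
section-alignment artifacts, or motion. Passing tests therefore demonstrate
correctness and power of the estimators under the stated models, not
end-to-end validity on any particular microscope's data.
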