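---
title: "Methods: Raman spore-sorting gates and envelope morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Raman spore-sorting gates and envelope morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporesort)
```

## The problem

Bacteria of five taxa survive adverse conditions by differentiating into
specialized resting cells: endospores (Firmicutes), exospores
(Actinobacteria), myxospores (Myxococcales), cysts (Azotobacteraceae) and
akinetes (Cyanobacteria). Two single-cell readouts make these cells
tractable without culturing: confocal Raman microspectroscopy, which gives
each cell a chemical fingerprint, and cryo-electron micrographs of the cell
envelope, whose thickening is the one morphological feature the resting-cell
types share. This package implements the computational side of both
readouts:

1. a **two-threshold sorting gate** that routes a measured particle to
   waste, a vegetative compartment, or an endospore compartment from its
   Raman spectrum, as used in Raman-activated cell sorting (RACS);
2. **marker-band scoring** against a catalog of phenotype-specific Raman
   bands;
3. **envelope morphometry**: width-averaged grey-value line profiles across
   a cell envelope and half-depth width measurements, with hierarchical
   (per-cell, then overall) averaging;
4. fully seeded **synthetic generators** for both data types, so the whole
   pipeline is testable end to end without any proprietary acquisitions.

## The sorting gate

Spectra are pairs $(\tilde\nu_i, I_i)$ of Raman shift (cm$^{-1}$) and
intensity (arbitrary detector units). Two scalar statistics drive the gate.

**Cell statistic.** With $A_W(S)$ the trapezoidal integral of spectrum $S$
over window $W$,

$$P_c = \frac{A_{[1620,1670]}(\text{cell})}{A_{[1620,1670]}(\text{medium})},$$

the ratio of the particle's integrated intensity over the 1620–1670
cm$^{-1}$ "cell region" to that of the suspension medium (0.2 M glycerol in
the validation experiments) acquired under identical settings. The region is
specific to cellular material without corresponding to one molecular bond;
it is preferred over the stronger ~2900 cm$^{-1}$ CH band because the latter
is highly variable between cells and sits near the detector edge. Particles
with $P_c$ below the cell threshold (default 1) are routed to waste.

**Endospore statistic.** On the same cell spectrum,

$$P_{CaDPA} = \frac{M_{[1370,1420]}(\text{cell})}{M_{[1620,1670]}(\text{cell})},$$

where $M_W$ is by default the in-window maximum (`mode = "max"`) and
optionally the integrated intensity (`mode = "integrated"`). The numerator
window contains the strong 1395 cm$^{-1}$ band of calcium dipicolinate
(CaDPA), a chelate abundant in endospore cores and absent from vegetative
cells and from the other resting-cell types. Cells at or above the endospore
threshold (default 1.1 — deliberately above parity, trading sensitivity for
purity of the endospore compartment) are called endospores; the rest are
vegetative.

Tunable parameters, with defaults:

| parameter | default | unit | meaning |
|---|---|---|---|
| `pc_threshold` | 1.0 | ratio | stage-1 cell/debris cut |
| `pcadpa_threshold` | 1.1 | ratio | stage-2 endospore cut |
| `cell_window` | [1620, 1670] | cm$^{-1}$ | denominator region |
| `cadpa_window` | [1370, 1420] | cm$^{-1}$ | CaDPA region |
| `mode` | `"max"` | — | window statistic for $P_{CaDPA}$ |

Design choices where the procedure was genuinely underdetermined:

* **Raw intensities.** Both ratios are computed on raw detector counts.
  Min–max normalization ($\,(I - I_{min})/(I_{max} - I_{min})\,$,
  `minmax_normalize()`) is provided for display and export only: normalizing
  the cell and medium spectra independently to $[0,1]$ would destroy the
  commensurate scale the $P_c$ ratio requires.
* **Cell window 1620–1670.** Published descriptions of the region's upper
  bound vary between 1670 and 1720 cm$^{-1}$; the formula-level statements
  consistently use 1670, so that is the default, and the window is a plain
  argument for users who prefer otherwise.
* **Max vs integrated.** The $P_{CaDPA}$ statistic is described both as a
  maximum-intensity ratio and as an integrated-intensity ratio in different
  passages of the literature this gate follows. Both are implemented; `max`
  is the default; batch reports record the mode used.
* **Boundary ties pass.** "Below threshold → waste" leaves equality
  undefined; `>=` passes each gate so a particle indistinguishable from the
  medium ($P_c = 1$ exactly) is analysed rather than discarded.
* **No preprocessing.** No smoothing, despiking or baseline subtraction
  anywhere — window statistics see the spectrum as acquired.

Numerical details: window bounds are closed (a sample exactly at a bound
belongs to the window); the trapezoid rule runs on the native, possibly
non-uniform axis, with linearly interpolated knots inserted at the window
edges so the integral spans the window's exact breadth — this makes a flat
spectrum integrate to $\text{value}\times\text{breadth}$ regardless of how
the sampling grid falls, and hence makes the flat-spectrum $P_{CaDPA}$
exactly 1 in both modes (the two windows have equal 50 cm$^{-1}$ breadth).
The in-window maximum uses samples only, no interpolation. When cell and
medium axes differ, the medium is resampled linearly onto the cell's window
knots; extrapolation is always refused.

## Marker catalog and signature scoring

`default_catalog()` records the discriminating bands: endospore 1017, 1395,
1446 cm$^{-1}$ (CaDPA); exospore 1342, 1586 (amino-acid bands); myxospore
1120, 1149 (trehalose) and 1550; cyst 830 (trehalose), 1150, 1350; and 2295,
present in vegetative cyanobacterial filaments but not in akinetes. Repeat
readings of the same physical bands have been reported at 1443 (vs 1446) and
1505 (vs 1550); the 1446/1550 readings are the primary entries, the 1505
alias is retained under a separate tag, and the default matching
half-window of 10 cm$^{-1}$ — about 3× the 3.5 cm$^{-1}$ spectral
resolution of the source acquisitions — absorbs the 1443 variant. The
~2900 cm$^{-1}$ CH$_2$/CH$_3$ stretch appears in nearly all cell spectra
(exospores being a notable exception) and is therefore catalogued under the
generic `vegetative` tag, outside the five spore-type signatures.

`signature_score()` is the fraction of a phenotype's bands matched by a
detected peak within the band's half-window. Peak detection
(`detect_peaks()`) takes local maxima, computes topographic prominence, keeps
peaks with prominence at least `min_prominence` (default 0.05) times the
spectrum's intensity range — making scores invariant under positive
rescaling — and greedily thins maxima closer than `min_separation` (default
8 cm$^{-1}$), keeping the taller. The defaults recover every noiseless
preset signature perfectly.

One caveat is chemistry, not implementation: myxospores (1149) and cysts
(1150) share a trehalose band, and the exospore 1342 and cyst 1350 bands lie
8 cm$^{-1}$ apart — inside the matching tolerance. Cross-scores between
those phenotype pairs therefore equal the shared-band fraction (e.g. 1/3)
rather than 0; all other cross-pairings score 0 on the noiseless presets.

## Envelope morphometry

`extract_profile()` reimplements the micrograph line-profile convention:
samples at 1-pixel spacing along a user-drawn line, each sample the mean of
23 bilinear interpolations taken at integer pixel offsets along the unit
perpendicular (23 parallel 1-pixel profiles — the width-averaged line that
reduces noise). Coordinates are continuous with pixel centers at integers;
samples outside the grid raise an error rather than being padded. Distances
convert to nm through the image's pixel size. The operation is exactly
affine-covariant in grey value.

`measure_envelope_width()` uses a half-depth (FWHM-style) criterion: the
baseline grey is averaged over a user-designated region outside the feature;
the envelope is the largest excursion from the baseline (dip or rise); the
width is the distance between the two crossings of the level halfway between
baseline and extreme, located by linear interpolation between samples.
Half-depth was chosen because it is affine-invariant in grey, scales
linearly with pixel size, and reduces to the edge-to-edge distance for
step-like envelopes (a rectangle's half-depth width is its breadth; a
Gaussian dip's is its FWHM, $2\sqrt{2\ln 2}\,\sigma$). If a second
half-level excursion reaches 80% of the main one the measurement aborts as
ambiguous, listing the candidates; features touching the profile ends raise
an error since no crossing pair exists.

The published per-cell width averages that this package's summaries
reproduce were measured manually on micrographs that are not distributed;
`summarize_widths()` therefore reproduces them at the summary-statistics
level from the shipped per-cell table (`envelope_width_reference()`): the
arithmetic mean per cell, then the mean of cell means — e.g. 44.72 nm for
vegetative *B. subtilis* against 213.70 nm for its endospores. Values are
unrounded internally and displayed at 2 decimals.

## Synthetic generators

`phenotype_preset()` + `generate_spectrum()` build spectra as baseline
polynomial (degree ≤ 2) + Gaussian/Lorentzian bands + seeded additive
Gaussian noise, on a 400–3300 cm$^{-1}$ axis at the 3.5 cm$^{-1}$
acquisition resolution. The presets place each phenotype's catalog bands;
every cell preset shares a 1650 cm$^{-1}$ "cell band" (amplitude 2, FWHM 30)
over baseline 0.8, the medium preset is a flat baseline 1.0 with weak broad
glycerol bands, debris a 0.4 baseline. Fingerprint bands default to FWHM 15
cm$^{-1}$, the broad CH band to 60. No published numeric intensities exist
for these spectra, so amplitudes are phenomenological stand-ins fixed once
to satisfy documented separability margins, verified by direct computation
in the test suite: the endospore preset's $P_{CaDPA} \ge 1.3$ (CaDPA 1395
amplitude 6 also keeps the integrated-mode ratio above 1.1), every other
cell preset $\le 0.9$, every cell preset's $P_c \ge 1.5$ against the medium,
debris $\le 0.5$. Noise defaults to sd 0.12, 2% of the largest preset
amplitude. `generate_population()` adds per-spectrum lognormal amplitude
multipliers (mean 1, relative sd `jitter`, default 0.1), emulating the
several-fold cell-to-cell variation of marker-band intensity seen between
strains and individual cells; each spectrum draws from its own RNG
sub-stream derived from the root seed by a stable counter, so membership
order never changes an individual spectrum.

`generate_band_image()` renders a straight band of known physical width
through the image center at a chosen angle — background grey 160, band grey
60 by default — with area-coverage anti-aliasing along the perpendicular,
separable Gaussian blur (default $\sigma$ = 8 nm, emulating point-spread and
defocus softening of envelope edges; replicate edge padding), and seeded
Gaussian noise (default 5% of the contrast). Default geometry is 256×256 px
at 2 nm/px, which holds bands up to ~250 nm plus blur support and baseline
margins. The ground-truth record accompanies every image.

**What the generators do not emulate** — and hence what passing tests do not
show about real data: fluorescence baselines and cosmic-ray spikes,
detector-edge noise inflation, resonance-Raman lineshapes (the akinete
carotenoid bands are phenomenological Gaussians), curved or layered
envelopes (real envelopes have multi-layer substructure: cortex, coat,
intermembrane layers), sectioning artefacts, and spatially correlated
micrograph noise. Classification accuracy of 100% on the synthetic
populations demonstrates the gate logic and the configured preset
separability, not expected field performance on environmental samples.

## Problem sizes and runtime posture

The shipped validation uses populations of 50 spectra per phenotype over 20
root seeds (8 000 classifications), 100 synthetic band images spanning
30–250 nm truths for the morphometry sweep, and 100 random spectra for the
exact-invariance checks — sizes at which every stochastic summary
(median recovery error, agreement rate) is stable to well inside its
acceptance margin while the whole suite runs in well under a minute.

## Known limitations

* The gate assumes a medium spectrum acquired under the same optical
  settings as the cells; no inter-session intensity calibration is provided.
* `measure_envelope_width()` expects a single dominant feature; profiles
  crossing several envelope layers of comparable depth are rejected as
  ambiguous by design and must be re-drawn over a cleaner stretch.
* The manual layer-boundary conventions behind the published per-cell width
  values are unknown, so agreement with them is demonstrated at the
  summary-statistics level, not by re-measuring micrographs.
* Peak detection is deliberately simple (prominence + thinning); it is a
  scoring aid, not a band-fitting engine, and does not deconvolve
  overlapping bands.
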