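---
title: "Quantifying radial spread of PKA activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radial spread of PKA activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rspa)
```

## The phenomenon and the measurement model

In a confluent epithelial monolayer imaged with a ratiometric PKA
biosensor, a calcium transient in one cell occasionally triggers a
switch-like discharge of prostaglandin E2. The secreted ligand activates
Gs-coupled receptors in the neighbours, and PKA activity rises in a
firework-like disc that expands at roughly 100 µm/min before relaxing to
baseline within a few minutes. The quantity imaged is the per-pixel ratio
of two fluorescence channels (numerator reporting the active-state
emission, denominator the reference), which cancels expression-level
differences between cells.

The detection pipeline makes four modelling commitments, each with a
configurable parameter:

1. **Baseline removal.** Because absolute ratios differ between positions
   and days, every pixel's time course is divided by its minimum over the
   acquisition (minimum-intensity projection along time). After this step
   a pixel's baseline is exactly 1 and an event is a fold-change. The
   normalization is idempotent, and its fixed point (per-pixel time
   minimum equal to 1) is asserted in the test suite.
2. **Thresholding.** A normalized ratio strictly above 1.3 is foreground.
   The inequality is strict, which the acceptance suite pins down by
   bisection: a uniform frame at exactly 1.3 yields no foreground.
   Binarized frames are cleaned by morphological opening then closing with
   1 px disc elements — the minimal pair that removes single-pixel noise
   without reshaping event discs. Element sizes are configurable.
3. **Sizing.** Each 8-connected foreground component is summarized by the
   equivalent radius r = sqrt(area/pi) of the circle with its area.
   8-connectivity is deliberate (a radially expanding front rasterizes
   into corner-touching pixels); the labelling is checked against a
   brute-force flood-fill oracle.
4. **Linking and calling.** Components in successive frames whose
   centroids are less than 100 µm apart are the same event; conflicts are
   resolved greedily by smallest distance, each component linked at most
   once per frame pair, and there is no gap closing across skipped frames.
   An event is a positive call when its fitted radius exceeds 15 µm
   (strictly) in at least one frame of its lifetime.

The radius *time course* of an event is measured independently of the
binary masks: concentric annuli are laid around the event centre, the
median normalized ratio in each annulus is compared with the threshold,
and the event radius is the outer radius of the outermost annulus in the
contiguous passing run from the centre outward. We stop at the first
failing annulus rather than accepting any distant passing ring, because a
radially spreading wave is contiguous by nature and distant supra-threshold
rings are almost always unrelated events. The innermost annulus radius is
the detection limit of this measurement: 6.4 µm for the standard setting,
with a 26 µm preset for lower-magnification optogenetic acquisitions (both
exposed as presets; their instrumental provenance is not derivable from
the imaging parameters, so neither is computed from pixel size).
Expansion speed is the least-squares slope of radius against time from the
frame preceding the first nonzero radius through the first frame attaining
the peak; a constant-radius course yields slope 0.

### A note on threshold monotonicity

Raising the binarization threshold can only shrink foreground — mask
nesting is exact and tested. The number of *called events*, however, is
not guaranteed to fall monotonically: a higher threshold can erase the
middle frame of one track and split it into two events, both still above
the positive-call radius. The test suite therefore asserts mask nesting
exactly and count monotonicity only between well-separated thresholds.

## Calcium transients

Indicator traces are converted to F/F0 with three baseline conventions,
matching the three experimental modes:

- **Rolling minimum** (spontaneous activity): F0 at time t is the minimum
  intensity over [t − 5 min, t). Before 5 min of history exists the window
  shrinks to the available history and the transient is flagged `warmup`.
  A slow drift (10% over 20 min) never approaches the calling threshold,
  while a step change reads out at its full fold-change until the window
  slides past — both behaviours are tested against a brute-force sliding
  minimum.
- **Pre-stimulus mean** (ligand-addition experiments): F0 is the mean
  intensity before the stimulus.
- **Per-flash** (repeated optogenetic stimulation): F0 is the last sample
  before each flash, and the peak F/F0 is taken between that flash and the
  next.

Transients are supra-threshold excursions (strictly above 3 by default;
a documented preset of 4 matches the chemogenetic-stimulation convention —
the two printed conventions coexist and neither is privileged, so both are
exposed). Excursions in the same cell separated by at most 1 min are one
transient; simultaneous (time-overlapping) excursions in cells within
20 µm — about one epithelial cell diameter, standing in for visual
adjacency — are merged into a single transient with its member cells
recorded.

## Coupling, lag, thresholds, frequencies

A transient is *coupled* to an event when a positive event's onset falls
within 2 min after it and within 20 µm of its cell. The published
one-tenth figure was obtained by comparing aggregate frequencies; the
per-event matched estimator here is a refinement, so the window and
distance are explicit parameters (defaults documented above) rather than
reproductions. Each event can couple to at most one transient (nearest in
time), so a burst of transients cannot all claim a single event.

ERK/PKA lead–lag is measured by normalized cross-correlation: both traces
are linearly interpolated to the finer sampling grid (ERK is typically
sampled every 5 min, PKA every 1 min), mean-subtracted, variance-scaled
and correlated at every lag up to ±10 min. Positive peak lag means ERK
leads PKA. The peak is refined by a parabola through the three
correlations around the argmax; at the printed precision of the lead time
this refinement is cosmetic, but it makes the estimate continuous in the
inputs.

Per-cell secretion thresholds from graded optogenetic series are
interval-censored order statistics: the midpoint between the largest
non-firing and smallest firing calcium peak, with one-sided intervals for
all-fired or never-fired cells and a flag for non-monotone cells.

Welch's t-test (unequal-variance, Satterthwaite degrees of freedom, p <
0.05 rule) is delegated to `stats::t.test`; the test suite verifies the
wrapper against the textbook formulas to 1e-10 on random samples.

## Dose–response

The whole-field response to an agonist concentration is the ratio of the
channel means over the 20–30 min post-addition window — channels are
averaged first and divided second, which matters: on a crafted two-pixel
field (100/1 and 1/100) the stated convention gives 1.0 while the mean of
pixelwise ratios gives 50.005. Titration curves are fitted with the
four-parameter Hill model by Levenberg–Marquardt least squares,
initialized from data quantiles. The model form is the package's choice of
the standard dose–response family (no functional form is printed in the
source experiments, and no absolute EC50s), so only the *fold* between
conditions is treated as a reproduction surface; the fold is invariant to
concentration units and response scaling, both asserted as properties.

## The synthetic scene generator

The generator's defaults are the study conditions, chosen once:

| Parameter | Default | Basis |
|---|---|---|
| cell density | 2.4 × 10⁵ cells/cm² | seeding density of the confluent condition |
| transient→event probability | 0.1 | about one transient in ten discharges an event |
| stimulated (chemogenetic) probability | 0.76 | stimulated-mode trigger rate |
| expansion speed | 100 µm/min | reported propagation speed |
| event amplitude | 1.5 (normalized ratio) | comfortably above the 1.3 threshold, matching displayed event contrast |
| decay constant | 2 min | "decays within several minutes" |
| per-cell opto threshold | U(1.5, 2.1) in F/F0 | reported threshold range |
| epidermal areal event rate | 300 cm⁻² hr⁻¹ | reported in-vivo frequency |
| titration EC50s | 1.0 / 0.1 µM | tenfold separation is the target; absolute values are assumptions |
| channel noise | 5% of basal, additive Gaussian per channel | assumption; ratio analysis is scale-free |
| basal intensity | 1000 AU | assumption (not stated per field) |

Events are rendered as top-hat discs with a 5 µm linear edge (the simplest
profile whose fitted radius has a closed form; the true radial profile is
not published), growing at the configured speed to the peak radius and
then relaxing exponentially. Channels receive independent additive
Gaussian noise; with zero noise the rendered numerator/denominator ratio
equals the true ratio field exactly. Calcium transients are 30 s
triangular F/F0 pulses whose times are snapped to the frame grid so the
pulse peak is always sampled — only peak amplitude and timing matter
downstream. Per-event peak radii get a ±30% uniform jitter so recall can
be studied as a function of true size. Cell positions are a jittered
hexagonal packing with the count fixed to round(density × area);
transient times are a homogeneous Poisson process per cell.

What the generator does **not** emulate: optics (PSF, photobleaching,
shot noise), cell motility and division, sub-cellular structure, and the
density→rate law (the transient rate is a direct parameter, with the
three-density series exposed as a preset, because the published
density dependence is qualitative). Passing recovery tests therefore
demonstrates that the pipeline measures what the model renders — linear
radial growth, Poisson timing, switch-like thresholds — not that it is
robust to every artifact of real microscopy (debris, misregistration,
drift), which the original analysis handled by manual inspection and
which is out of scope here (a max-rise-rate artifact filter was
considered and rejected as untestable without real artifacts).

## Numerical choices and problem sizes

- Strict inequalities at both printed constants (ratio > 1.3, radius >
  15 µm); both boundaries are located by bisection in the acceptance
  suite.
- Background subtraction uses a constant per channel (configurable;
  estimated as the first-frame histogram mode when unspecified). Pixels
  whose denominator falls to or below background become invalid (`NA`)
  and are excluded everywhere downstream rather than propagating NaNs.
- The median filter delegates to a constant-time algorithm that quantizes
  to 2¹⁶ levels after exact power-of-two rescaling; the error (≈10⁻⁵
  relative) is negligible against the 1.3 threshold.
- Scenes are written as 32-bit float TIFFs scaled by 1/65536 (an exact
  binary scaling recorded in the sidecar JSON), so round trips are exact
  at single precision.
- Greedy linking resolves conflicts by global smallest distance within
  each frame pair; ties are broken by scan order. Events touching the
  field border are flagged and excluded from radius statistics but kept
  in counts.
- Test and acceptance problem sizes are deliberately modest — fields of
  300–1200 µm, 13–61 frames, 20–100 Monte-Carlo seeds — chosen so each
  recovery target's sampling error is well inside its tolerance; all
  statistical tolerances are stated in the tests in SE units of the
  quantity checked.

## Known limitations

- Two simultaneous nearby events can merge into one track (the 100 µm
  linking gate does not distinguish them), and a fading track can split —
  both inherent to the published linking rule.
- The concentric-ROI radius is quantized to one annulus width, so
  expansion speeds inherit a bias of up to roughly half an annulus per
  rise time (about 3% at defaults).
- The coupling estimator depends on its window/distance parameters; the
  defaults are documented choices, not published values.
- No drift correction, registration, or cell segmentation: per-cell PKA
  quantification from images is out of scope.
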