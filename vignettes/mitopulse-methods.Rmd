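---
title: "mitopulse: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitopulse: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package analyzes

An all-optical experiment couples two genetically encoded tools inside the
same mitochondria: a photosensitizer (KillerRed-class, excited at 561 nm)
that generates superoxide — and hence, after dismutation, hydrogen peroxide
— when a fixed diffraction-limited spot is pulsed, and a ratiometric H2O2
biosensor (HyPer7-class) read out at 488 nm (and 405 nm for ratio imaging).
Recordings are two-channel time-lapse movies, typically >220 frames at 5 s
intervals with a 1.5–3 min baseline followed by two 5-s stimulation pulses,
sampled at 19.3 px/µm.

`mitopulse` turns such movies into per-mitochondrion biology:

1. **Segmentation and tracking** of individual mitochondria per frame.
2. **Trace extraction**: summed channel intensity, normalized first to the
   object's area in that frame (guards against focal drift and size
   changes), then to the pre-stimulation baseline (F/F0, dF/F = F/F0 − 1,
   or R/R0 for dual-excitation ratios).
3. **Subpopulation classification** by distance to the stimulation point.
4. **Morphometry**: area and form factor FF = P²/(4πA) over time.
5. **Kinetics**: half-rise time T½, plateau-then-single-phase decay, AUC,
   and nested-model comparison via the extra sum-of-squares F test.
6. **Calibration**: microdomain-specific sigmoid standard curves against
   exogenous H2O2, inverted to express any response as an
   exogenous-H2O2-equivalent concentration.

Because the raw microscopy data behind this class of experiment is not
deposited, the package carries a first-class synthetic generator
(`simulate_movie()`, `simulate_trace()`, `simulate_dose_response()`) whose
defaults are the stated experimental world, with machine-readable ground
truth for every quantity the pipeline estimates.

## The synthetic world

Mitochondria are capsules (rectangle plus semicircular caps), 0.8–2 µm long
and 0.5–0.8 µm wide, placed with a hard minimum clearance and moved by
Brownian steps (σ = 0.02 µm/frame) with reflecting boundaries; steps that
would violate the clearance are rejected, so the segmentation oracle stays
well defined. Scenes that cannot be packed at the requested density raise
an error rather than rendering overlapping objects.

The biosensor response of a mitochondrion at distance *d* from the spot
rises instantly at the pulse frame by a fraction

A(d) = A0 · max(0, 1 − d/d_max),

holds a plateau, then relaxes exponentially toward baseline at rate K
(units F/F0 per minute). Defaults: A0 = 0.65 (the observed ~65% immediate
rise), d_max = 12/6/1 µm for matrix/IMS/OMM-targeted sensors (the observed
extinction distances), plateau 60 s, K = 0.54 for the first pulse and
0.085 for the second (the measured slowing as antioxidant machinery is
overwhelmed). The linear-with-cutoff attenuation is the simplest form
consistent with a finite extinction distance; the experiments report only
the extinction distances, not a functional form. The rise is modeled as a
single-frame step because the observed rise is immediate at 5-s framing;
sub-frame kinetics are deliberately not modeled.

The photosensitizer channel photobleaches: at each pulse its density is
multiplied by 1 − b·max(0, 1 − d/d_max) with b = 0.6 at the spot.
Mitochondria within 5 µm of the spot (the approximate proximal distance)
transiently elongate after a pulse — a half-sine stretch of the major axis
up to 1.3× over 120 s, at constant width and constant signal density, so
area and form factor rise while area-normalized intensity does not. Fusion
is modeled *only* as elongation, never as track merging, keeping tracking
ground truth single-valued.

The camera model is Poisson shot noise on the signal plus Gaussian read
noise (σ = 5 counts) on top of a 100-count background, quantized to 16
bits — the standard fluorescence CMOS/PMT model. Baseline in-object signal
density is 300 counts/px in both channels.

Two stated-world choices deserve emphasis:

* The first mitochondrion is placed at the stimulation point, because the
  experimental protocol targets a predetermined spot *on* a mitochondrion;
  this also guarantees the "spot" subpopulation (d < 1.5 µm) exists.
* The `standard` fixture is noiseless. Segmentation/tracking equivalence
  against ground truth is checked exactly there; the noisy model is
  exercised by the `tiny` fixture and unit tests. A green test on the
  noiseless fixture establishes correctness of the measurement chain, not
  robustness to arbitrary SNR; real data add shading, debris, and
  out-of-focus light that the generator does not emulate.

The simulator does not model reaction–diffusion chemistry, 3-D optics/PSF,
network graph dynamics, or the rare (~1–3% of stimulations) rapid
trafficking events, for which no quantitative motility model is reported.

## Segmentation and measurement

Each frame is background-subtracted by a rolling-ball equivalent
(grayscale opening with a disk, radius 50 px — removes any constant offset
exactly) and smoothed with a Gaussian (σ = 2 px). Detection is Otsu
thresholding of the smoothed image plus 8-connected labeling and a
0.1 µm² minimum area.

Detection alone is not measurement-grade: the global threshold rises when
stimulated objects brighten, eroding dim objects past their half-maximum
contour and biasing areas by up to ~8%. Each detected object is therefore
re-thresholded locally at half its own robust maximum (98th percentile),
computed on the *unsmoothed* background-subtracted channel inside an
expanded bounding box, keeping the raw-image components that overlap the
detection. The half-maximum contour of an object sits on its true edge for
a straight boundary; doing this on the unsmoothed image also avoids the
curvature bias (≈σ²/R) that pulls the blurred half-max contour inward at
the capsule caps. On the noiseless standard fixture this bounds per-object
area error at ~3%.

Perimeters use a 4-direction Crofton estimator (intercept counts along
rows, columns and diagonals, weighted by line spacing) rather than raw
pixel-edge counting; worst-case anisotropic bias is about 6–7% for
axis-aligned elongated shapes, ~1% for disks. Axes come from the second-moment ellipse
(4·√eigenvalue convention). A frame whose whole-image median jumps >5 MAD
from its neighbours can be dropped — at most one per recording, mirroring
how rare technical artifacts are handled upstream.

## Tracking

Greedy mutual-nearest-centroid linking, gated at 2 µm per frame step, with
gaps up to 2 frames bridged by linear extrapolation of the track head. The
gate and gap defaults are declared, not inferred — the original TrackMate
settings are unpublished. Mutual-nearest assignment is order-free, making
linking invariant to detection ordering. At the motion scale of these
recordings (<1 px/frame) identity accuracy on ground truth is 100%; the
acceptance bound is ≥95%.

## Populations

Distances are measured per frame from each object centroid to the fixed
stimulation point. Because cell size varies, classification is relative:
with M the maximum object-to-spot distance in the cell, objects below
30% (HEK preset; 20% for MEF) of M are proximal, above 70% (50%) distal,
and objects within 1.5 µm are "spot" (a subset of the proximal side,
reported separately). Labels are frozen at the first stimulation frame:
the figures this reproduces report fixed groups, and re-labeling per frame
would let objects drift across group boundaries mid-analysis. Whether the
original analysis took M over all frames or one frame is not stated; the
reference-window choice here is declared.

The default baseline window is all frames before the first pulse minus the
first four frames (recordings sometimes have 15–20 s of settling drift),
falling back to all pre-stimulation frames for short recordings. Display
smoothing (centered moving average, window 3) is emitted as a separate
column; analysis always runs on raw series.

## Kinetics

The decay model is piecewise: f(t) = plateau for t ≤ t0, then
baseline + (plateau − baseline)·exp(−K(t − t0)/60). K is reported per
minute (the field convention) while time is in seconds. The changepoint t0
defeats naive gradient fitting, so the fit grids t0 over the distinct
sample times, solves (plateau, baseline) in closed form for fixed (t0, K)
— the model is conditionally linear — optimizes K one-dimensionally, and
then refines t0 continuously between the neighbouring samples. The
asymptote is free by default but bounded below by zero (the original fit
settings are unpublished; forcing the asymptote to the pre-stimulation
baseline is *not* assumed). Noiseless traces are recovered to ≤1e−6 in K;
a flat trace returns a flagged, unconverged fit rather than an error.

One identifiability caveat matters in practice: when a slow decay is
observed over less than about one time constant (K ≈ 0.085 min⁻¹ over a
10-min recording), the free asymptote and K lie on a nearly flat ridge of
the RSS surface and neither is precisely estimable — at 5% multiplicative
noise the median relative error in K is ~50%, an information limit, not an
optimizer defect. When the asymptote is known — baseline-normalized traces
expected to relax back to F/F0 = 1, as the synthetic world does —
`fit_plateau_decay(..., asymptote = "fixed")` conditions on it, and the
median error drops to ~5% for both reported rate constants. The recovery
tests use the conditioned fit; analyses of real traces, where the decay
may genuinely not return to baseline, should keep the default.

T½ is the first time the trace crosses baseline + (peak − baseline)/2
after stimulation, linearly interpolated between samples (the estimator
used upstream is undefined; first-crossing is the simplest monotone
choice and scales exactly under time rescaling). AUC is the trapezoidal
integral of value − reference over a window, with interpolated endpoints.

Conditions are compared with the one-sided extra sum-of-squares F test:
one shared 4-parameter fit to the pooled data versus independent fits,
F = ((RSS_sh − RSS_sep)/Δdf)/(RSS_sep/df_sep). Empirical type-I error at
p < 0.05 over 1000 null replicates is 0.057, inside the 0.05 ± 0.02
calibration band.

## Calibration

Dose–response data are averaged per concentration (the convention used
for these standard curves; per-cell fitting remains available by passing
unaveraged data) and fit with a 4-parameter logistic in *concentration*,
S(c) = bottom + (top − bottom)/(1 + (EC50/c)^h), with S(0) = bottom taken
as the c → 0 limit. Fitting in linear concentration avoids a log(0)
dialect for the 0 µM anchor; whether the original fits fixed the Hill
slope or used a log axis is not stated, so both EC50 and h are free.
Fit quality below R² = 0.99 raises a recorded warning and marks
downstream equivalents as provisional.

Inversion is closed-form: c = EC50·((r − bottom)/(top − r))^(1/h).
Responses at or below the fitted bottom are excluded as `below_baseline`
(the upstream exclusion rule for cells that decreased below baseline);
responses above top − 1% of span are `above_saturation` (the curves
saturate sharply beyond ~2.5 µM; no numeric gate is published, so 1% of
span is the declared cutoff). The result is explicitly an *exogenous
equivalent* — the bath concentration producing the same response in that
microdomain — not an in-situ concentration, and no attempt is made to
convert it to absolute intracellular levels.

## Numerical and interface choices

* Coordinates: µm, origin at the top-left pixel centre; pixel indices are
  0-based in all on-disk records; conversion via pixel_size (µm/px).
* Movies: multi-page TIFF (frame-major, channel-interleaved, 16-bit
  little-endian, uncompressed) plus a JSON sidecar for pixel size, frame
  interval, stimulation point/events and channel roles. The reader
  supports exactly this dialect and rejects foreign TIFF variants.
* All tabular outputs are tidy CSV with fixed column order; manifests and
  curves are JSON. Reruns under an identical config are byte-identical.
* Determinism: every stochastic step is governed by a single integer seed.
* KR-expression normalization for whole-cell work divides the response
  amplitude by the cell's pre-stimulation photosensitizer mean; the
  functional form used upstream (divide vs regress) is unpublished, so the
  simplest ratio is the declared choice.

## Known limitations

Segmentation assumes bright objects on a removable background; it is
threshold-based by design (the original trained-classifier stage cannot be
reproduced — its training ROIs are not published) and will underperform on
low-contrast or densely packed data that the classifier handled. Linking
is nearest-neighbour, not LAP: adequate below ~1 px/frame motion, known to
fail under fast crossing trajectories. The Crofton perimeter carries a
small anisotropic bias for extremely elongated shapes. The F test assumes
independent Gaussian residuals on the fitted traces; applying it to
averaged traces with correlated residuals (as mean ± SEM figures do)
yields nominal, not exact, p values.
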