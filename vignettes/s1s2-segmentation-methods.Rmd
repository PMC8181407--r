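---
title: "Automated S1S2 protocol segmentation: models, parameters and design choices"
author: "s1s2seg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated S1S2 protocol segmentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(s1s2seg)
```

This vignette explains the science behind `s1s2seg`: what each stage of
the pipeline assumes, which tunable parameters matter, what the synthetic
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## The measurement problem

An S1S2 restitution protocol paces the atrium with trains of `n` stimuli
at a fixed basic cycle length (S1, default 600 ms here) followed by one
premature stimulus (S2) whose coupling interval decreases train by train
(500 ms down to 180 ms in the default, first in 50 ms then in 10 ms
steps) until the tissue stops responding — the coupling interval has
fallen inside the effective refractory period (ERP). The analysis has to
work without any a-priori protocol knowledge, remain robust at clinical
noise levels, and recover atrial activities that lie in close temporal
proximity to the pacing artifact, which exceeds them in both amplitude
and slope.

## Protocol inference

**Stimulating channel.** The pacing artifact is largest in the
stimulating bipole and decays with distance, so the top-ranked channel by
peak-to-peak amplitude should be spatially adjacent to the runner-up.
`findStimChannel()` walks down the amplitude ranking until that adjacency
condition holds, which makes the choice immune to a single high-amplitude
artifact in an unrelated channel. Ranking is computed on wander-detrended
traces (below).

**Stimulation detection.** A zero-phase 450 Hz high-pass isolates
stimulation content from physiological components; the detection series
is the sum of absolute undecimated bior1.5 wavelet detail coefficients on
the two finest dyadic scales at 1 kHz (the band of the steep stimulus
edges — the only waveform assumption made). The threshold is `k` times
the standard deviation of the detection series, so segmentation is
invariant under amplitude rescaling. Because the zero-phase filters ring,
one stimulus can split into several threshold runs; a non-maximum
suppression step keeps only the strongest peak within any 50 ms window,
far below any plausible coupling interval.

**S1 cycle length.** `k` starts at 0.01 and grows in steps of 0.01. At
each step the histogram of all inter-peak intervals (1-sample bins,
merged within ±10 samples) is inspected; the estimate is accepted when
the second and third most frequent intervals are integer multiples of the
first within 10 samples — the signature of a periodic S1 grid, stable
even with many extra beats. Because the detection series itself does not
depend on `k`, the iteration only re-thresholds, and the cap is set
generously (1000 iterations): noisy records legitimately need `k` well
above 1 before the threshold clears the noise floor.

**Trains and trust conditions.** Inter-peak intervals are clustered by a
deterministic 2-means (initialized at the extreme values); the long
cluster marks train boundaries, and a warning is raised when its centroid
falls below 1.2× the cycle length, where the separation becomes
unreliable. Candidate stimuli — consolidated across channels with a
width-bounded grouping so that dense noise peaks cannot chain-merge —
must then pass: C1, synchronous wavelet detection in at least half the
channels (±5 ms); C2, agreement with an energy-operator detection on the
high-passed trace; C3, a first-principal-component peak of at least 90 %
of the reference PC1 amplitude; C4, an interval to a neighboring stimulus
within 10 samples of the cycle length (or a valid S2 position: a short
interval followed by an inter-train gap); C5, the analogous 90 % rule on
the channel derivatives. C3 is computed on the 450 Hz high-passed traces
(the condition tests the stimulus amplitude pattern, and that band is
essentially free of physiology, wander and band-limited noise), and the
90 % threshold is applied against the *median* in-window peak of the
quorum-passing candidates: a reference that equals the global maximum on
clean data but neither rejects genuine stimuli whose peak sits a few
percent below the luckiest beat nor gets inflated by a one-off artifact
spike.

## Artifact removal and atrial detection

Per channel, the stimulation template is the first S2 stimulus counting
upward from the shortest coupling interval whose window is free of QRS
fiducials: once the ERP is reached that window contains no atrial answer
at all. The template is trimmed to its contiguous active support
(smoothed envelope above 10 % of its maximum, edges refined on the raw
trace) so that the correlation is not diluted by surrounding silence, and
subtracted at each stimulus after least-squares amplitude scaling at the
best alignment within ±10 ms; a normalized correlation below 0.5 leaves
the stimulus in place, flagged. The interval from the annotated window
start through the artifact peak is then linearly interpolated.

Atrial activity is detected on the cleaned trace with the Teager–Kaiser
operator `E[n] = x[n]² − x[n+1]·x[n−1]` after a zero-phase 150 Hz
low-pass (the atrial band ends well below that; broadband noise above it
would only enter the operator), rectified and smoothed with a 5 ms
moving average. The search window runs from the end of the artifact's
active support — where subtraction and interpolation leave residuals — to
the next event onset, capped at 250 ms (a generous bound on activation
delays at catheter scale). Among the threshold-crossing segments, the one
with the highest energy defines the activity, and the **LAT is the
half-peak centroid of the energy pulse**: the pulse's top is almost flat,
so its bare argmax dithers by samples under noise while the centroid is
stable. A detection whose energy peak lies within 6 ms of the window
start is reported *undetected* (`stim_overlap`): its maximum is clipped
by the artifact window, the regime in which activities majority-covered
by the stimulus become unrecoverable. On the default geometry this
flags exactly the bipole adjacent to the pacing site, whose activity
overlaps the artifact by 57 %.

Baseline wander is removed before all of this by a zero-phase 4th-order
6 Hz Butterworth high-pass: wander (≤5 Hz, up to twice the atrial
amplitude) is suppressed to ~0.2 mV while the 35 ms biphasic atrial wave
loses only ~0.5 % of its peak-to-peak amplitude — the dominant term in
the pipeline's noise-free amplitude error.

**ERP.** A train is refractory when its S2 response amplitude falls below
20 % of the mean S1 response amplitude of the same train (per channel,
majority across channels; a missing detection counts as refractory). The
reported ERP is the longest refractory coupling interval: 190 ms on the
default protocol, whose generator ERP of 200 ms lets the 200 ms train
capture and the 190/180 ms trains fail.

## Distances and curves

Within one catheter, bipole distances are Euclidean (bipole position =
electrode-pair mean); across catheters the wave travels along the atrial
wall, so a triangulated surface mesh (ASCII PLY/OFF) is used and the
distance is the shortest vertex path over mesh edges — exact continuous
geodesics would be out of proportion to catheter-scale accuracy, and the
optional spline refinement stays off by default. Propagation speed is the
scalar surrogate `p = distance / LAT` — not the true wavefront velocity,
but directly comparable across pacing rates. Curves omit refractory
trains, the stimulating bipole, and (by default) its adjacent bipoles;
points beyond three standard deviations of a channel's curve are flagged,
never removed. The data contract (per-beat LATs, windows, amplitudes and
geometry) deliberately supports plugging in other velocity estimators.

## The synthetic generator

The generator emulates: biphasic stimulation artifacts (4.7 mV
peak-to-peak, 8 ms, 2 ms positive first phase; per-phase exponential
decay) whose amplitude decays with distance from the pacing bipole as
`1/(1 + d/20 mm)`; atrial activities (2 mV, 35 ms) as a smooth two-lobed
Gaussian-derivative-like wave with the steepest downstroke at 60 % of the
duration (clinical bipolar activities lead with the longer lobe);
activation times from an elliptic anisotropic wavefront (anisotropy 1.5,
conduction velocity 650 mm/s baseline) over a planar circular catheter
(radius 10 mm, 10 equidistant electrodes, 9 adjacent-pair bipoles) plus
four CS bipoles at 35–50 mm along the fiber axis; saturating-exponential
restitution `q(s2) = q0 (1 − 0.5 e^{−(s2−ERP)/60 ms})` for amplitude and
velocity of S2 responses; uniform-random extra beats with atrial
morphology; spectrum-shaped noise; and baseline wander (0.001–5 Hz grid,
random phases, peak amplitude twice the atrial amplitude).

Open geometry choices were fixed once: the fiber axis sits at 162° in the
catheter plane, which (i) gives two circular bipoles (3 and 5) identical
anisotropic stretch factors and hence one shared speed-restitution curve,
(ii) produces exactly one bipole with more than 50 % artifact overlap
(the channel-2 analogue, 57 %) and one with ~11 %, and (iii) leaves all
CS bipoles overlap-free. The restitution depth (0.5) and time constant
(60 ms) are configurable; the validation compares pipeline output to
whatever ground truth was generated, so their exact values are not
load-bearing. The ground-truth LAT anchor of the atrial waveform is
defined through the same functional the detector reports (low-pass →
energy operator → smoothing → half-peak centroid), so truth and detection
share one annotation convention and a fixed convention offset cannot
masquerade as error; the anchor sits within two samples of the physical
steepest downstroke.

**Noise model.** The clinical noise segment that would define the
reference spectrum is not shipped; the declared stand-in is `1/f` (α = 1)
over 1–250 Hz plus a white floor at −20 dB (relative to the 1/f power)
over the same band and a 50 Hz mains line at −10 dB. The 250 Hz band
limit reflects that clinically recorded electrograms — the source of any
measured reference spectrum — are low-pass filtered by the recording
chain. Phases are drawn uniformly at random, so realizations differ by
seed while the power is fixed by the magnitudes. SNR scaling uses the
amplitude factor `n = 10^((SNR_current − SNR_target)/20)` with both
signal and noise powers measured over the whole record; on a
mostly-silent S1S2 record this makes 0 dB correspond to a noise standard
deviation of ~0.16 mV against 2 mV activities — noise peaks become
comparable to the atrial amplitude a few dB further down. An
active-support power definition is available via
`signalPower(active_only = TRUE)` and yields roughly 4× stronger noise at
the same nominal SNR. Wander is added after SNR scaling and excluded
from the noise power, as an always-present deterministic-amplitude
nuisance.

What the generator does **not** emulate: ventricular far field (QRS
windows enter only as a fiducial table), fractionated or double
potentials, catheter motion (electrode positions are static), beat-to-beat
morphology variability, and non-stationary noise. Passing tests therefore
show correct mechanics and noise robustness under these idealizations,
not clinical-grade performance on pathological signals.

## Numerical choices and degenerate inputs

* Sample indices are 0-based with half-open windows; 1 kHz default makes
  one sample one millisecond.
* At 1 kHz, LAT quantization alone moves short-path speeds by up to ~3 %
  (half a sample on an 18 ms delay); speed-curve comparisons should use
  curve-level statistics, as the tests do.
* Thresholds are std-relative throughout, so every detector is invariant
  under amplitude rescaling of its input.
* Exactly-silent search windows (below-ERP trains on noise-free data)
  are guarded against floating-point dust by requiring the selected
  energy peak to exceed `1e-8` of the channel's global detection maximum.
* 2-means is initialized at the extreme interval values and is fully
  deterministic; ties in non-maximum suppression resolve toward the
  stronger, earlier peak.
* Degenerate cases raise errors or flags rather than guessing: zero-power
  noise, non-causal (non-positive) LATs, stimulating-bipole distance 0,
  disconnected meshes, templates overlapping every QRS window,
  correlation below the 0.5 floor.

## Problem sizes used in the shipped validation

The test-suite and the acceptance script run the default protocol
(21 trains, 105 stimuli, 13 channels, ~69 s at 1 kHz), a BCL grid
{400, 500, 800} ms at reduced train counts, and a reduced noise sweep of
five SNR levels {40, 20, 10, 0, −10} dB × three seeds; these sizes keep a
full validation run in the minutes range on one core while covering every
operating regime, and the generator scales to arbitrary protocols.

## Known limitations

* The matched filter assumes a stable artifact morphology per channel;
  drifting artifact shapes (catheter motion) would degrade subtraction.
* Activities whose energy peak is hidden under the artifact are reported
  undetected by design; recovering them would need model-based
  deconvolution rather than subtraction.
* The ERP amplitude rule inherits noise in the S2 amplitude estimate;
  under heavy noise the refractory boundary can blur by one train.
* Geodesic distances are vertex-path lengths, accurate to the mesh edge
  length.
* HDF5 recording IO is not built in; the package's plain-text CSV bundle
  is the reference format, with exact round-tripping.
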