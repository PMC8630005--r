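---
title: "Models and methods behind smPET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smPET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smPET)
```

This vignette is the package's own account of the science it implements:
the generative model of coupled conformational dynamics, the trace
idealization and kinetic analysis, the parameters that matter, and the
numerical and design choices made where the method description left room.

## The measurement and its idealization

A PET (photoinduced electron transfer) reporter quenches a fluorophore on
contact with a tryptophan, so a local conformational change toggles the dye
between a bright state (structural element "open") and a dark state
("closed"). A surface-tethered molecule carrying two spectrally separated
reporters yields a pair of two-level intensity time traces; concerted
conformational changes appear as same-direction intensity steps in both
colour channels within a short window, taken throughout as **six frames
(1.8 s at the two-colour frame interval of 0.3 s)**. The analysis reduces
each trace to a two-level step sequence, classifies steps as synchronous or
non-synchronous across channels, converts inter-step intervals into dwell
times, and summarizes dwell-time distributions by exponential fits to their
cumulative sums.

## The generative model

The simulator draws, in continuous time, a single hidden clamp coordinate
that alternates between open and closed with exponential sojourn times:
closure rate `kClose` (default 1.0 min⁻¹) and opening rate `kOpen` (default
5.0 min⁻¹), the regimes reported for the system this emulates. Each closure
is independently re-assigned, with probability `pUncoupled` (default 0.12),
as an **uncoupled excursion**: a single randomly chosen channel quenches
alone and reopens after an `Exp(1/kOpen)` sojourn of its own. Uncoupled
events are therefore quench-initiated only — matching the observation that
non-synchronous transitions go only from fluorescent to quenched — while
their reopening necessarily appears in the event log as an uncoupled
recovery. With these defaults the expected non-synchronous share is
`100·p/(1−p) ≈ 13.6%` relative to the synchronous count, inside the
reported 10–18% band.

Two subtleties are worth stating explicitly:

* **Closures defer to running excursions.** If the clamp attempted a
  coupled closure while one channel is mid-excursion, the event would be
  visible in only one channel and would violate the model's defining
  property that coupled events appear in both channels. The closure clock
  therefore restarts (memorylessly) when the excursion ends.
* **Photobleaching consumes fluorescent time only.** A PET-quenched dye is
  dark and thus protected from photobleaching; bleach budgets (default
  0.05 min⁻¹ per channel, a photostable-dye regime in which most traces
  outlive the 9-min observation) are drawn as exponential *fluorescent-time*
  budgets and mapped to wall-clock time. A consequence used downstream is
  that every bleach is a visible terminal intensity loss.

Event times are binned to the camera frame grid (state sampled at frame
start); sojourns shorter than a frame alias away exactly as they would in a
recorded movie. Apo mode emits only uncoupled closures plus bleaching; the
one-colour AMP-PNP mode closes each molecule irreversibly once, applies
oxygen at `o2ApplicationS` (default 600 s) and recovers quenched molecules
after an exponential DSPO delay (`dspoMeanDelayS`, default 30 s — a value
chosen to put recoveries well inside a 15-min trace).

Traces are rendered from states either directly (open = PSF peak-pixel
photon level, closed/bleached = background; Poisson shot noise times gain
plus Gaussian read noise) or through full image stacks: molecules are 2-D
Gaussian spots (PSF sigma 1.3 px at 130 nm/px) of integrated intensity
`photonsPerFrameOpen` (default 2000 photons/frame, a typical detected flux
for bright rhodamine-family dyes at ~10 W/cm² and 0.3 s integration) on a
uniform background of 20 photons/px. The channel-2 spot positions can be
warped by a configurable affine misalignment so that registration is
exactly testable.

What the generator does **not** emulate: EMCCD gain-register statistics
(folded into a gain scalar plus Gaussian read noise), dye blinking (the
experimental conditions suppress it; no blinking rate is on by default),
stage drift, chromatic PSF differences, elastic (non-affine) channel
distortions, and FRET cross-talk. Passing tests therefore demonstrate
correctness of the analysis logic under the stated noise model, not
robustness to every artifact of real recordings.

## Image pipeline

Spots are local maxima above `median + 5·(1.4826·MAD)` of the frame,
merged within 4 PSF sigma (brighter wins) and refined by a
background-subtracted intensity-weighted centroid in a window of half-width
`ceil(3σ)`. Channel registration fits a least-squares affine transform to
mutually-nearest bead pairs and reports the residual RMS; co-localization
maps channel-2 spots through that transform and matches greedily by
ascending distance with a 2 px default tolerance, using a maximum-intensity
projection of the first 10 frames as the reference (both channels start
fluorescent before quenching accumulates). ROI read-out takes the maximum
pixel in a window of half-width 3 px per channel and frame. Note the
resolution limit this implies: two spots closer than the 4σ merge radius
cannot be separated by construction, so synthetic fields for co-localization
tests are rendered sparse (8σ minimum separation), as real single-molecule
surfaces are prepared to be.

## Step detection

The idealizer Gaussian-smooths the trace (sigma 1.5 frames, kernel
truncated at 4σ, reflective boundaries), convolves with
first-derivative-of-Gaussian edge detectors at dyadic scales {1, 2, 4}
frames, and multiplies the detail signals pointwise. True steps respond
coherently at all scales while noise decorrelates, and with an odd number
of scales the product's sign encodes the step direction. Candidates are
signed local extrema of the product above `thresholdC = 3` times the
product's robust noise floor (1.4826·MAD about zero). Numerical choices:

* **Localization at the finest scale.** The product detects best at coarse
  scales but localizes best at the finest; each candidate snaps to the
  scale-1 detail extremum within ±2 frames.
* **Boundary guard.** Steps within `max(scales)` frames of either trace end
  are discarded (wavelet edge artifacts).
* **Minimum separation 3 frames.** Closer candidates are pruned keeping the
  larger |product| (ties: earlier frame); an *opposite-direction* pair
  below the limit is a dwell too short to resolve and keeps its earlier
  edge deterministically, so the two colour channels agree on it. Dwells of
  one or two frames are thus fundamentally unrepresentable — the dominant,
  and quantified, source of recall loss in the ground-truthed tests.
* **Amplitude filter.** Step amplitudes are differences of level medians
  over flanking inter-step windows (capped at 50 frames); candidates below
  `0.25 ×` the trace's 5–95 percentile range are removed iteratively,
  weakest first.
* **Two-level consistency.** Surviving steps define segments; a
  length-weighted deterministic 2-means on segment medians fixes the two
  levels. A short (≤ 8 frame) interior segment whose median is
  incompatible with *both* levels (z > 4 using the noise sigma of the
  nearer level — per-level sigmas matter because shot noise scales with
  intensity) is a mid-level artifact (e.g. a FRET-like excursion or a noise
  spike) and sheds its spurious bounding step(s); between same-level
  neighbours both steps go unless the segment genuinely reaches the
  opposite level.
* **Degenerate traces.** If the two fitted levels are closer than two noise
  sigmas the trace is labeled single-level and flagged. The two-sigma
  threshold is deliberate: a 2-means split of a *single* noise population
  already separates its cluster means by ≈1.6 sigma, so a one-sigma test
  could never fire. Constant traces short-circuit to zero steps for any
  threshold.

All thresholds are noise-relative, never absolute, because absolute photon
yields vary between molecules and alignment sessions.

## Kinetics

Per molecule, same-direction steps across channels within the six-frame
window are matched greedily one-to-one by ascending frame difference (tie:
earlier green frame); unmatched steps are non-synchronous, and an unmatched
terminal quench with no later recovery is a **bleach candidate**. Because a
bleach ends a recording's usable part, all events after a molecule's first
bleach candidate (in either channel) are excluded from counts, and
molecules with a flagged (single-level, no-signal) channel are excluded
altogether — the synthetic analogue of selecting molecules co-localized in
both colours. The non-synchronous percentage is reported under both
conventions, `100·N_ns/N_s` (headline: only this convention reproduces the
published 10–18% band from the published counts) and
`100·N_ns/(N_s+N_ns)`.

Dwells between consecutive steps become records with censoring flags;
intervals abutting the trace start or end, and open intervals terminated by
a bleach candidate, are censored and excluded from fits (no survival
correction — the simplest defensible choice, matching rather than
correcting the fast-event bias of finite observation windows). Cumulative
sums of uncensored dwell times are fitted as
`N(t) = N_tot·Σ a_i (1 − e^{−t/τ_i})` with `Σ a_i = 1`, multi-start
(τ at 0.5×, 1×, 2× the sample mean) bounded Levenberg–Marquardt; mono vs
bi-exponential is chosen by BIC (`n·log(RSS/n) + k·log n`), requiring at
least 10 dwells for mono and 25 for bi. The amplitude-weighted mean rate is
`1/Σ a_i τ_i`, converted to min⁻¹; amplitudes are re-normalized before this
step so the formula is well defined. Bulk decays are fitted as
`I(t) = I_∞ + A₁e^{−t/τ₁} + A₂e^{−t/τ₂}` with amplitudes normalized over
the decaying part, and rate-ratio free energies use
`|−RT ln(k/k′)|` with `R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹`.

One estimator choice deserves a note: the mean of *completed* open dwells
in a 9-min window is biased low by ~12% when the true mean is 60 s, so
ground-truth checks of the simulator use the censoring-consistent
exponential estimate (total open time / number of closures) instead of the
naive mean; the analysis-side rate constants inherit the same finite-window
bias as the experimental procedure they mirror, by design.

Uncertainties in the report stage are bootstrap standard deviations over
molecules (B = 200 by default) — a different estimator than experimental
repeat-to-repeat scatter, which has no synthetic analogue.

## Problem sizes and determinism

Every stochastic stage is a pure function of its configuration and seed
(the RNG stream is isolated and restored). The test suite runs, among
others: 500 ground-truthed telegraph traces (250 molecules × 2 channels,
1800 frames) for step-detection recall/false-positive measurement; a
150-molecule full-pipeline parameter recovery; a 12-molecule, 300-frame
64×64 px image-pipeline recovery with an injected (3.2, −1.5) px + 0.5°
affine misalignment; 2000-dwell exponential-mixture fits; and a
120-molecule one-colour DSPO classification — sizes chosen so statistical
assertions have adequate power while the whole suite remains quick on a
single CPU.

## Known limitations

* The idealization is strictly two-level; multi-level photophysics or
  partially quenched intermediate states would be misassigned.
* Sub-resolution dwells (< 3 frames) are unrecoverable by design of the
  separation constraint; recall saturates accordingly.
* Censored-dwell exclusion biases rate constants at dwell scales comparable
  to the trace length; no survival correction is applied.
* The affine registration cannot represent elastic field distortions; the
  misalignment it is tested against is affine by construction.
* Greedy synchronicity matching is not globally optimal for pathological
  step pile-ups inside one window, though it coincides with the exhaustive
  assignment on all tested instances.
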