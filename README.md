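# smPET

Simulation and kinetic analysis of **two-colour single-molecule PET
(photoinduced electron transfer) fluorescence** experiments, as used to watch
the ATPase-driven conformational clamp cycle of the Hsp90 chaperone one
molecule at a time.

In a PET reporter, a fluorophore is quenched on van-der-Waals contact
(~1 nm) with an engineered tryptophan, so a local conformational change
switches the dye between a fluorescent ("open") and a quenched ("closed")
state. Surface-tethered molecules imaged by TIRF microscopy therefore
produce two-level intensity time traces; with two spectrally separated
reporters on one molecule, the *time order* of two remote conformational
changes can be read out directly. The analysis questions this package
addresses are the ones such data pose:

* Are transitions in the two colour channels **synchronous** (same direction
  within a 6-frame / 1.8 s window) or not?
* What are the rate constants of clamp closure and opening? Dwell times in
  the open (fluorescent) state give the closure kinetics, dwell times in the
  quenched state the opening kinetics. Cumulative dwell-time curves
  `N(t) = N_tot * sum_i a_i (1 - exp(-t/tau_i))` (sum a_i = 1) are fitted
  mono- or bi-exponentially (BIC selection), and the **amplitude-weighted
  mean rate** is `k = 1 / sum_i a_i tau_i`.
* Is an irreversible intensity loss a PET quenching event or photobleaching?
  In one-colour AMP-PNP experiments, dye-sensitized photo-oxidation (DSPO)
  of the tryptophan after applying oxygen-rich buffer recovers fluorescence
  of genuinely PET-quenched molecules — the package implements this
  confirmation logic.

Because every stage must be testable without downloading raw microscopy
data, the package includes a first-class **synthetic-data generator**: a
coupled two-state (telegraph) clamp model with exponential sojourn times
drives both reporters in concert, a configurable minority of closures are
channel-independent quench-only excursions, photobleaching consumes
fluorescent time, and frames are rendered either as per-molecule traces or
as full two-channel TIFF stacks with Poisson + read noise, fiducial-bead
frames and an injectable affine channel misalignment.

## Components

| Stage | Functions |
| --- | --- |
| Simulation | `SimulationConfig`, `simulateClampTrajectories`, `renderTraces`, `renderImageStack`, `makeBeadFrames` |
| Image pipeline | `detectSpots`, `registerChannels`, `colocalize`, `extractTraces`, `maxProjection` |
| Trace idealization | `gaussianSmooth`, `multiscaleProduct`, `detectSteps`, `idealizeTraces` |
| Kinetics | `pairSynchronous`, `classifyTransitions`, `extractDwells`, `dwellCumSum`, `fitExponentialCdf`, `meanRate`, `analyzeKinetics`, `identifyPetEvents`, `fitBulkDecay`, `deltaDeltaG` |
| Orchestration | `readPipelineConfig`, `runPipeline`, `pipelineReport` (plus `inst/scripts/smpet.R`) |

Step detection follows the multiscale-product idea: the trace is
Gaussian-smoothed, convolved with first-derivative-of-Gaussian edge
detectors at dyadic scales {1, 2, 4}, and the pointwise product across
scales is thresholded against a robust (MAD-based) noise floor; an odd
number of scales preserves the step sign. Steps then define a strictly
two-level idealization.

## Worked example

Simulate 60 two-colour molecules for 9 min at 0.3 s/frame with closure rate
1.0 min⁻¹, opening rate 5.0 min⁻¹ and 12% uncoupled closures, then run the
trace-level analysis:

```r
library(smPET)
cfg    <- SimulationConfig(nMolecules = 60, durationS = 540,
                           frameIntervalS = 0.3, kClose = 1.0, kOpen = 5.0,
                           pUncoupled = 0.12, seed = 7L)
traj   <- simulateClampTrajectories(cfg)
traces <- renderTraces(traj, seed = 8L)
ideal  <- idealizeTraces(traces)
kin    <- analyzeKinetics(ideal$steps, ideal$nFrames, AnalysisConfig(),
                          flagged = ideal$flagged)
kin
#> KineticResult
#>   synchronous pairs: 464, non-synchronous: 87
#>   % non-synchronous: 18.8 (ratio to sync) / 15.8 (of total)
#>   k_c = 0.949 min^-1, k_o = 4.43 min^-1
```

The detected closure rate `k_c = 0.95 min⁻¹` and opening rate
`k_o = 4.4 min⁻¹` recover the generative 1.0 and 5.0 min⁻¹; the
non-synchronous share (here 18.8% relative to the synchronous count) tracks
the generative 12% uncoupled-closure probability (13.6% in the same ratio
convention) plus a small detection contribution. The underlying open-dwell
fit is a mono-exponential with `tau = 63 s` (green channel, 257 dwells):

```r
kin@perChannel$green$openFit
#> ExponentialFit (1 component): a=1.000 tau=63.28 s
#>   n = 257 dwells, RSS 4501, BIC 741.3
```

A two-fold change of such a rate constant corresponds to a free-energy
increment of only `deltaDeltaG(2, 298.15)` = 0.41 kcal/mol.

The same analysis can start from images instead of traces (`runPipeline`
with `pipeline: use_images: true` localizes spots, registers the channels
from bead frames, pairs co-localized molecules and reads out max-pixel ROI
traces), and `pipelineReport()` writes the per-channel summary table and
cumulative-sum plots.

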