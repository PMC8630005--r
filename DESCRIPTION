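Package: smPET
Title: Simulation and Kinetic Analysis of Two-Colour Single-Molecule PET
    Fluorescence Time Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-molecule photoinduced-electron-transfer (PET)
    fluorescence microscopy of coupled conformational dynamics, as used to
    probe the ATPase-driven clamp cycle of the Hsp90 chaperone. Includes a
    ground-truthed simulator of two-state (telegraph) clamp dynamics with
    concerted two-channel quenching, camera noise and photobleaching; a TIRF
    image pipeline (spot localization, fiducial-bead channel registration,
    co-localization, ROI trace extraction); trace idealization by Gaussian
    smoothing followed by multiscale-product step detection; and dwell-time
    kinetics (synchronicity classification, cumulative-sum plots, mono- and
    bi-exponential fits, amplitude-weighted mean rate constants, bulk decay
    fits and free-energy conversion).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
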