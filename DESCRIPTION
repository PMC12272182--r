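Package: rifttag
Title: Rapid Invisible Frequency Tagging (RIFT) Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying rapid invisible frequency tagging (RIFT) of
    visual stimuli with MEG. Generates the four canonical RIFT tagging
    waveforms at projector frame rate, reconstructs phase-corrected tagging
    reference signals from light-sensor traces and missed-flip logs, computes
    boxcar-taper Fourier spectra with inter-trial coherence and
    brain-to-tagging (phase-corrected) coherence plus a decibel SNR statistic,
    disentangles two simultaneously presented stimuli tagged at orthogonal
    phases, fits equivalent current dipoles in a spherical conductor, and runs
    hierarchical Bayesian logistic and linear models with Savage-Dickey Bayes
    factors for the behavioural invisibility test and condition contrasts. A
    fully seeded synthetic MEG and behaviour generator with ground-truth
    bookkeeping supports end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
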