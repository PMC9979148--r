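Package: flickerkit
Title: Audio/Visual Flicker Stimulus Synthesis and Neural Entrainment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes millisecond-precise audio and visual flicker
    stimulation waveforms (periodic square waves, carrier-modulated click
    trains, randomized aperiodic flicker, single pulses), builds blinded
    experiment schedules, and analyzes steady-state neural entrainment:
    FIR band-pass filtering, polyphase downsampling, Laplacian
    re-referencing, multitaper power spectral density with discrete prolate
    spheroidal tapers, channel- and subject-level modulation criteria,
    detection latency, spike phase locking (vector strength, Rayleigh test),
    and open-field behavioral measures (inactivity bouts, center-zone
    occupancy). Includes seeded synthetic generators for 1/f background
    EEG/LFP with steady-state responses, phase-modulated Poisson spike
    trains, and open-field trajectories, so the full analysis chain is
    testable without recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
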