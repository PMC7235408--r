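Package: cltus
Title: Closed-Loop Transcranial Ultrasound Stimulation: Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for closed-loop transcranial ultrasound stimulation (CLTUS)
    of hippocampal circuits: online theta (4-12 Hz) peak/trough prediction with
    a Hamming-window FIR band-pass and period/amplitude validation, online
    seizure detection from the amplitude standard deviation and coastline
    (line-length) statistics against a calibrated baseline, a closed-loop
    controller that schedules timestamped ultrasound trigger events with the
    pulsed-ultrasound protocols, short-time Fourier transform band-power
    outcome metrics (absolute and relative theta power, per-window means and
    percent changes), seizure latency/duration outcomes, acoustic exposure
    bookkeeping (Isppa, Ispta, mechanical index), and a seeded synthetic LFP
    generator with ground-truth phase and seizure intervals so the full loop is
    testable without hardware or animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
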