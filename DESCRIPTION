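Package: s1s2seg
Title: Automated Segmentation of S1S2 Stimulation Protocols for Amplitude
    and Conduction-Speed Restitution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated segmentation of rate-varying S1S2 intracardiac
    stimulation protocols from multichannel electrograms. Infers the pacing
    protocol (S1 basic cycle length, pacing trains, S2 coupling intervals)
    from the signal alone, detects stimulation artifacts with a biorthogonal
    wavelet detector, removes them by matched-filter template subtraction,
    segments atrial activities with the Teager-Kaiser non-linear energy
    operator, estimates the effective refractory period, and assembles
    per-channel amplitude and propagation-speed restitution curves. Includes
    a fully annotated synthetic S1S2 protocol generator with clinical-spectrum
    noise, baseline wander and SNR scaling for validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
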