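Package: stimlimit
Title: Charge-Limited Microelectrode Stimulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for subretinal microelectrode stimulation
    within electrochemical safety limits. Computes charge storage capacity
    from cyclic voltammetry and charge injection capacity from biphasic
    pulse voltage transients; solves the static volume-conductor field of a
    current-injecting disk electrode (closed forms and an axisymmetric
    finite-volume solver) to obtain activation depths at a field criterion;
    reduces per-trial spike recordings to peristimulus time histograms,
    spontaneous-corrected spike counts, interpolated charge thresholds,
    half-max and dynamic range; and generates synthetic electrochemistry
    records and heterogeneous retinal ganglion cell populations so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
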