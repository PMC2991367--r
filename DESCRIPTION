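Package: pscdetect
Title: Matched-Filter Detection and Measurement of Postsynaptic Currents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated detection, localization and measurement of
    photostimulation-evoked postsynaptic currents (EPSCs/IPSCs) in
    whole-cell voltage-clamp recordings using a bank of approximate
    matched filters. A training stage fits L1-normalized polynomial
    templates to user-marked events and pools their convolution-peak
    statistics; the detection stage convolves zero-phase high-pass
    filtered traces with the bank, localizes events from suprathreshold
    convolution segments, splits overlapping events, and measures peak
    amplitude, rise time, summed input and latency. Includes a
    Monte-Carlo simulator (Poisson event trains with refractory period,
    synthetic template and noise libraries), ROC-based performance
    evaluation against simulated ground truth, and per-site input-map
    aggregation for laser-scanning photostimulation circuit mapping.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
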