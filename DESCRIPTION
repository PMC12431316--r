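Package: spikecardio
Title: Energy-Aware Spiking Neural Network Detection of Cardiovascular
    Disease from Multimodal ECG and PCG Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A low-power cardiovascular-disease detection pipeline that
    fuses synchronously recorded electrocardiogram (ECG) and
    phonocardiogram (PCG) signals.  A differential signal-level fusion
    builds an EPCG channel, the fractional adaptive superlet transform
    renders high-resolution time-frequency spectrograms, and spiking
    convolutional networks with integrate-and-fire neurons and arctangent
    surrogate gradients classify each modality.  A confidence-based
    dynamic decision rule fuses the two model branches.  The package also
    accounts for per-layer spike rates, synaptic operation counts, and
    CMOS energy estimates of the spiking network against its isomorphic
    conventional network, and ships a synthetic paired ECG/PCG generator
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pROC,
    signal,
    stats
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
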