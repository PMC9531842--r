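Package: neorespire
Title: Respiratory Cessation Classification from RFID Backscatter with
    Quantized and Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting respiratory cessation (apnea)
    in infants from passive RFID backscatter collected by a wearable antenna.
    Simulates interrogation streams from a programmable breathing protocol
    using a radar-cross-section forward model, derives de-oscillated signal
    strength and RSSI-from-minimum features over one-second windows, trains a
    small one-dimensional convolutional neural network, quantizes its weights
    and activations to k bits with model-size accounting, converts the trained
    network to a rate-coded integrate-and-fire spiking network, and explores
    the accuracy/energy design space with a spike-count energy model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
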