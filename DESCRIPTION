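Package: synckit
Title: Analysis Pipeline for Optogenetically Induced Syncope Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multimodal recordings of vagally induced
    syncope in head-fixed mice: Morse-wavelet EEG/LFP spectrograms with
    baseline normalization and cluster-based Monte Carlo permutation tests,
    band-power syncope onset/offset detection, Poisson spike-train statistics
    for silence periods and laser-response latencies, a behaviour-to-neural
    encoding network with nearest-neighbour latent prediction and residuals,
    facial motion-energy SVD and pupillometry features, and ECG, respiration
    and laser-Doppler flowmetry metrics. Includes a synthetic-session
    generator with programmable ground truth so every stage can be validated
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
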