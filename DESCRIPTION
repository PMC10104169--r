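Package: circuitsync
Title: Prefrontal-Hippocampal Circuit Neurophysiology Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-site extracellular recordings from the
    medial prefrontal cortex and dorsal hippocampus of freely moving mice.
    Provides local field potential preprocessing (detrend, notch, anti-aliased
    decimation), multi-unit activity extraction by robust threshold crossing,
    accelerometer-based rest-epoch detection, multitaper power spectra and band
    power over the canonical rodent band scheme, theta-gamma phase-amplitude
    coupling comodulograms (entropy-based modulation index), phase slope index
    directed connectivity with shuffle surrogates and t-test significance,
    spike-field pairwise phase consistency, novel object recognition scoring
    (discrimination index, five-second visit concatenation, early/late splits),
    and auditory evoked potential / oddball mismatch negativity quantification.
    Includes a synthetic-session generator with known ground truth (coupled
    oscillations, directional lags, phase-locked spiking, scripted behavior and
    tone protocols) used to validate every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
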