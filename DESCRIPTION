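Package: arousalwave
Title: Brain-Body Co-Fluctuation Analysis of Global fMRI, EEG and Autonomic Signals
Version: 0.1.0
Authors@R: person("Arousalwave", "Developers", email = "dev@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify low-frequency (0.01-0.1 Hz) co-fluctuations
    between global fMRI signals, EEG power and autonomic physiological
    recordings. Implements physiological and EEG feature extraction
    (systolic peak detection, heart rate, PPG amplitude, Hilbert-based
    respiratory volume, tonic skin conductance, Morlet wavelet power,
    alpha envelope), principal and complex principal component modeling of
    voxel time series with phase-delay maps and phase-binned temporal
    reconstruction, lagged cross-correlation and Gaussian-process
    deconvolution of impulse responses, multi-set canonical correlation
    with distributed-lag spline bases and subject-block permutation
    inference, event-related averaging with cluster-bootstrap errors,
    volume-wise multi-echo T2*/S0 decay fitting, and cardiac RETROICOR
    regressors. A seeded synthetic-data generator with known latent
    arousal structure makes every stage testable without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
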