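Package: bmconn
Title: Linear and Nonlinear Brain-Muscle Connectivity from EEG and EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pipeline for assessing linear and nonlinear brain-muscle
    connectivity from simultaneous EEG and surface EMG recorded during
    graded isometric shoulder-abduction tasks. Implements cross-spectral
    connectivity (CSC), a coherence-like statistic defined over integer
    n:m frequency pairs via higher-order auto-spectra, together with the
    summary indices built on it: an EEG-power Laterality Index, a
    nonlinear-over-linear (N-L) index, maximum-voluntary-torque
    estimation with a consistency rule, and a flexion-synergy ratio.
    Includes zero-phase preprocessing (band-pass, notch, EMG
    rectification and normalization, overlapping epoching, amplitude
    based epoch rejection), a permutation null for CSC, assumption-gated
    group statistics, and a synthetic EEG/EMG/torque generator with a
    lateralized cortical source, a linear direct-pathway coupling and a
    cascaded static-nonlinearity indirect-pathway coupling with
    load-dependent gain.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    car,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
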