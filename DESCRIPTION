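Package: chewEF
Title: Cortical Electric Fields Generated by Chewing-Muscle EMG
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how electromyographic (EMG) activity of the masticatory
    muscles propagates through the head volume conductor to the cerebral cortex.
    Provides a parametric layered head phantom with craniotomy defects, skull-base
    foramina and an insulating subdural grid; event-related spectral and amplitude
    analysis of simultaneous scalp and intracranial recordings (sliding-window FFT
    relative spectra, exact sign tests with false-discovery-rate correction, and
    percentile-based chewing-burst amplitude statistics); a quasi-static finite
    element forward solver on regular hexahedral meshes with St. Venant dipole
    sources and a multilayer concentric-sphere analytic oracle; electrode-grid
    surface reconstruction by geodesic-preserving planar embedding; and the
    calibration pipeline that converts intracranial burst amplitudes into
    per-trial dipole strengths, predicts peak cortical electric fields in an
    intact (healthy) head model, rescales them to chewing conditions of different
    hardness, and summarises the fraction of chewing events exceeding the
    0.2 V/m neuromodulation threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    igraph,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
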