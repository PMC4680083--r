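Package: dcnvoc
Title: Cochlear Distortion Products and Selective Spike Responses to
    Ultrasonic Vocalizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how auditory brainstem neurons
    with low-frequency tuning can respond to ultrasonic vocalizations via
    cochlear distortion products. Provides a phenomenological nonlinear
    cochlea model (reverberation comb filter followed by a Boltzmann
    nonlinearity) that introduces low-frequency distortion products into
    ultrasound-band stimuli; a Bayesian detector of stimulus-evoked
    deflections in spike rate (four-parameter response model, Metropolis-
    Hastings posterior estimation, Hellinger-distance significance
    criterion); a rate-independent spike-train similarity measure;
    selectivity-index population summaries; and seeded synthetic-data
    generators (vocalization-like waveforms, renewal-process spike rasters,
    model neurons with inhibitory sidebands) for end-to-end simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
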