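Package: contextmdp
Title: Active-Inference Simulation of Contextual Emotion Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Discrete-state active-inference machinery for multi-factor,
    multi-modality partially observable Markov decision processes, together
    with a simulated mental-state-attribution task in which an ambiguous or
    unambiguous target face is embedded in a happy, sad or incoherent social
    context. Perception is variational state estimation under
    precision-weighted likelihood mappings; saccades are selected by expected
    free energy (epistemic plus extrinsic value). Precision (inverse
    temperature) parameters on the likelihood mapping implement contextual
    perception and the local/global viewing strategies used to model
    schizophrenia-like visual search. Includes batch simulation, behavioural
    summaries (decision time, accuracy, scan paths), condition comparisons,
    and configuration/serialisation helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
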