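Package: eegram
Title: Recurrent Hard-Attention Model for EEG Signal Classification
Version: 0.1.0
Authors@R:
    person("eegram", "developers", email = "eegram@example.org", role = c("aut", "cre"))
Description: A reinforcement-learning hard-attention classifier for
    multichannel signal epochs and images. A multi-scale foveated glimpse
    sensor extracts patches around a focal location, a gated recurrent unit
    (GRU) core integrates glimpses over time, a stochastic Gaussian location
    policy (trained by REINFORCE with a learned state-value baseline) decides
    where to look next, and a softmax action head (trained by
    backpropagation) classifies at the final step. Includes seedable
    synthetic-data generators (translated glyph images and EEG-like
    oscillatory-burst epochs shaped like the BCI Competition IV-2a dataset),
    evaluation protocols (session-wise subject-dependent and
    leave-one-subject-out splits, accuracy, Cohen's kappa, confusion
    matrices), and a command-line interface for dataset generation, training
    and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    rhdf5
Config/testthat/edition: 3
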