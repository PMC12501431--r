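Package: ssvepmix
Title: SSVEP Decoding with Background-EEG Mixing Augmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for decoding steady-state visually evoked potential
    (SSVEP) brain-computer interface recordings. Provides an epoched-EEG data
    model with Chebyshev band-pass preprocessing and trial-level
    cross-validation; a synthetic SSVEP generator with known ground truth;
    the BGMix data augmentation strategy that swaps background-EEG residuals
    between stimulus classes (with a Mixup comparator); a compact Transformer
    decoder combining a spatial fully connected filter, a frequency-domain
    convolution and a multihead self-attention encoder, trained with a
    two-stage protocol, early stopping and optional knowledge distillation;
    the eTRCA and TDCA filter-bank decoders; and balanced-accuracy and
    information-transfer-rate metrics, wired together by a YAML-configured
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
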