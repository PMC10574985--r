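Package: fatiguenet
Title: Multi-Level Driver-Fatigue Classification from Physiological Signals
    with Type-2 Fuzzy Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for EEG-based multi-level driver-fatigue detection.
    Generates seeded synthetic multichannel physiological recordings (EEG,
    ECG, EMG, respiration) whose class structure follows the physiological
    signatures of rising fatigue (occipital alpha-to-theta shift, declining
    blink rate, slowing heart rate, sparser steering-wheel EMG bursts,
    clipped respiration); implements a deterministic preprocessing chain
    (middle-window extraction, 50 Hz notch, first-order Butterworth
    band-pass, template-based blink suppression, min-max normalization);
    augments epoch datasets with a generative adversarial network; trains a
    seven-block one-dimensional convolutional classifier whose activations
    are learnable interval type-2 fuzzy units (three parameters per channel);
    and evaluates models with a full metric suite (confusion matrix,
    sensitivity, specificity, precision, F-score, Cohen's kappa, one-vs-rest
    ROC/AUC) including a white-Gaussian-noise SNR robustness protocol.
    Includes EDF reading/writing for recordings and a portable epoch-dataset
    container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
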