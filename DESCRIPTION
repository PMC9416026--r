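Package: hsigan
Title: Deep Convolutional GAN Synthesis and Validation of Hyperspectral
    Skin-Lesion Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to synthesize labeled hyperspectral skin-lesion image
    cubes with a deep convolutional generative adversarial network (GAN)
    trained on small datasets, and to validate the synthetic data. Includes
    hyperspectral data handling (white/dark reference calibration, band
    trimming, ENVI input/output), a parametric phantom generator with known
    class spectral signatures, generator/discriminator architectures with a
    conditional variant and a segmentation-mask output channel, a two-phase
    training recipe (RGB pretraining with channel-mapped weight transfer,
    then conditional adversarial training with label smoothing, label
    swapping, equalized learning rate and two time-scale updates), and an
    evaluation suite: Frechet distance between feature moments,
    confusion-matrix metrics, Jensen-Shannon spectral divergence, spectral
    signature envelopes, and a train-on-synthetic/test-on-real classifier
    fidelity protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
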