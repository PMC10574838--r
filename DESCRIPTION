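Package: foggan
Title: Generative Adversarial Synthesis of Freezing-of-Gait Accelerometer Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for synthesizing wearable-accelerometer freezing-of-gait
    records with a fully connected generative adversarial network (GAN), and
    for judging the synthetic data. Includes a reader/writer for
    whitespace-delimited nine-channel sensor recordings, a seeded simulator of
    gait-like fixture data, per-class GAN training on a self-contained dense
    network engine, real-versus-synthetic similarity diagnostics (correlation
    matrices, cumulative sums, log mean/SD, PCA, per-feature distribution
    divergences), and a train-on-real test-on-synthetic utility evaluation
    with a small dense classifier.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
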