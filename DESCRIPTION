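Package: fundusgrade
Title: Attention-Based Bilinear Convolutional Grading of Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fine-grained five-grade classification of diabetic retinopathy
    fundus images with a two-stream (non-homologous) convolutional model.
    Implements exact bilinear pooling and its compact randomized
    approximation (count sketch + circular convolution, the tensor-sketch
    realization of the second-order polynomial kernel), squeeze-and-excite
    channel attention with heatmap visualization, and the complement
    cross-entropy objective for long-tailed class distributions, together
    with a seeded synthetic fundus-image generator, a CPU training loop with
    hand-written backpropagation, macro-averaged evaluation metrics, an
    ablation harness and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
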