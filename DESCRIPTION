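Package: xylospec
Title: Multimodal Hyperspectral Wood Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identifying wood species from hyperspectral images of
    cross-sections. Implements reflectance calibration and ENVI cube I/O,
    band selection by fused similarity metrics (frequency-domain difference,
    difference hash, mutual information, structural similarity) with two
    Max-Min selection strategies, multi-band wavelet image fusion,
    multi-feature interest-point extraction with frequency-domain degridding,
    a three-modality texture feature space (Sobel, second-order moments,
    Gabor), a spectral-derivative transformer classifier, a saliency-guided
    windowed-attention texture classifier, and per-class learnable late
    fusion of the two branches. Includes a synthetic wood-cube generator so
    the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    png,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
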