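Package: morphoprompt
Title: Morphology-Enriched Prompt Building for Histopathology Image Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structured text captions for histopathology image patches
    from automatically extracted image features, for conditioning text-to-image
    generative models when only coarse binary labels are available. Patches are
    embedded with a pluggable feature extractor, clustered with k-means, and the
    number of morphology clusters is chosen by minimizing the SD validity index;
    captions combine the class label with the cluster index. The package also
    implements the surrounding evaluation protocol: near-uniform prompt
    balancing with train/validation splitting, Frechet Inception Distance and
    improved precision/recall on embedding sets, projection-based coverage of
    the real data distribution, and a mixed real/synthetic classifier
    augmentation benchmark reporting AUC distributions. Synthetic stain-like
    patch and feature-mixture generators make every stage runnable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
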