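Package: synappose
Title: Apposition-Based Quantification of Synapse Density and Subcellular
    Protein Localization in Confocal Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies synaptic bouton and synapse densities on neuronal
    compartments (soma, axon initial segment, labeled axons) from multichannel
    confocal fluorescence images using mask-overlap apposition criteria, and
    scores the subcellular distribution (soma versus neuropil) of tagged
    proteins. Provides channel conditioning (histogram matching, background
    subtraction, blurring, smoothing, contrast rescaling), IsoData
    thresholding, watershed-based puncta detection with size and circularity
    filters, soma/AIS/neuropil segmentation, linear-density conversion,
    hierarchical (cell to animal to group) statistics with normality-gated
    test selection, and a synthetic-scene generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
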