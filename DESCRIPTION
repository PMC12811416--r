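Package: axoquant
Title: Quantitative Fluorescence Image Analysis of Axonal Outgrowth and
    Microtubule Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable, tested implementations of the image-analysis
    procedures used to quantify axonal regeneration in microfluidic
    cultures: Sholl analysis of binarized axon fields by concentric
    semicircles, growth-cone morphometry from actin-outline masks
    (area, perimeter, elongation ratio, longest shortest path,
    filopodia count), axial fluorescence intensity profiles with
    background subtraction and baseline correction, kymograph-based
    quantification of microtubule plus-end comet dynamics after
    temporal difference-of-Gaussians separation of mobile and static
    fluorescence, Manders colocalization coefficients, and puncta
    counting within a mask. A synthetic-microscopy generator provides
    ground truth for every stage so the whole pipeline is testable
    without raw microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
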