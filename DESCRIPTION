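Package: ftuseg
Title: Instance-Level Evaluation and Density Analysis for Functional
    Tissue Unit Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating instance segmentations of functional
    tissue units (FTUs) such as renal glomeruli and colonic crypts on
    whole-slide images. Reads and writes polygon annotations
    (GeoJSON-style feature collections), run-length-encoded prediction
    masks and label-image TIFFs; separates merged FTUs with
    marker-controlled watershed or manual split lines; matches predicted
    to ground-truth instances by per-object Dice overlap into
    true-positive, false-positive and false-negative sets; computes
    pixel- and object-level performance metrics (Dice, Jaccard,
    precision, recall, F-measure, accuracy, Matthews correlation,
    Hausdorff distance) and FTU density per square millimeter of cortex.
    A synthetic-scene generator produces WSI-like ground truth with
    perturbed predictions and known confusion counts so the whole
    pipeline can be validated without image downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
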