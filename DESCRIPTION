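Package: saltpheno
Title: Salt-Tolerance Phenotyping of Rice Seedlings from Leaf Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pixel-level evaluation of salt-stress damage in rice seedling
    images: colour-based segmentation of green versus dead (yellowed) leaf
    tissue, per-leaf instance extraction, leaf death rate and ordinal
    salt-tolerance grading (grades 1/3/5/7/9), cohort-level survival and
    green-leaf statistics, and detection metrics (precision, recall, F1,
    mAP at IoU 0.5, FLOPs). Includes a synthetic seedling-image generator
    with exact ground truth, Labelme polygon-annotation ingestion,
    stratified dataset splitting, and the structural re-parameterization
    algebra that merges a Diverse Branch Block (KxK, 1x1, 1x1-KxK and
    1x1-average-pool branches with batch normalization) into a single
    equivalent KxK convolution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
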