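Package: rpswap
Title: Random Pixel Swap Data Augmentation for Medical Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the Random Pixel Swap (RPS) data augmentation for 2D
    medical images: two congruent, disjoint rectangular patches within a single
    image exchange contents, so the intensity histogram and global intensity of
    the image are preserved exactly while local structure is perturbed. Also
    provides the standard comparator augmentations (Cutout, Random Erasing,
    MixUp, CutMix, flips, quarter-turn rotations), a threshold-and-morphology
    lung region-of-interest segmentation pipeline for chest CT slices, a
    synthetic chest-CT phantom generator with ground-truth masks, and
    cumulative-score ranking plus paired t-test machinery for benchmarking
    augmentation techniques across models. A command-line interface exposes all
    operations for batch processing of image directories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
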