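Package: jointALE
Title: Joint-Condition Anatomical Likelihood Estimation for Coordinate-Based Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coordinate-based meta-analysis of voxel-based morphometry foci
    from two diagnostic conditions merged into a single anatomical likelihood
    estimation (ALE) analysis. Per-study likelihood maps built with an
    isotropic Gaussian kernel are averaged within condition, summed into a
    joint likelihood map, and tested against a pooled permutation null with
    Benjamini-Hochberg false-discovery-rate thresholding. Each retained
    cluster is attributed to the two conditions by the intensity ratio of the
    condition mean maps over the cluster. Includes Brett mni2tal/tal2mni and
    Lancaster icbm2tal coordinate transforms, a synthetic foci generator with
    ground-truth manifests for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
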