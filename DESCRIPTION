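Package: voxelRFE
Title: SVM-RFE Consensus Mapping of Discriminative Regions in Segmented Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-as-feature classification of segmented tissue-probability
    brain volumes with a linear support vector machine, recursive feature
    elimination (SVM-RFE) ranking, and a sliding-window multi-subset consensus
    scheme for locating discriminative regions of interest. Includes a
    synthetic phantom generator with planted regions and known ground truth,
    a voxelwise Student's t-test baseline selector, leave-10-out
    cross-validated accuracy evaluation, a binomial null reference for
    consensus selection counts, and NIfTI import/export of rank, count and
    mask volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'features.R'
    'svm.R'
    'stats_eval.R'
    'rfe.R'
    'consensus.R'
    'phantom.R'
    'pipeline.R'
    'voxelRFE-package.R'
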