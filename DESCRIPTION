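Package: BlockCS
Title: Block-Based Compressive Sensing Image Codec with CNN Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Block-based compressive sensing (CS) for RGB images: 8x8 block
    splitting, orthonormal 2-D DCT sparsification, Gaussian random acquisition
    and orthogonal matching pursuit (OMP) reconstruction, together with a
    convolutional image classifier trained by stochastic gradient descent and
    confusion-matrix evaluation (precision, recall, F1, accuracy), so that the
    accuracy-versus-compression-ratio trade-off can be studied end to end on
    synthetic labelled image sets. Includes a serialized compressed-image
    container (.bcs), a four-class synthetic image generator, and a
    command-line interface for fixture generation, compression, training and
    compression-ratio sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'BlockCS-package.R'
    'RcppExports.R'
    'classifier.R'
    'metrics.R'
    'cs_core.R'
    'fixtures.R'
    'codec.R'
    'cli.R'
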