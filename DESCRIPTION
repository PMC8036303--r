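Package: ssdmix
Title: Shifted-Scaled Dirichlet Mixture Models and Generative SVM Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite mixtures of shifted-scaled Dirichlet distributions for
    compositional (simplex-supported) feature vectors, fitted by
    expectation-maximisation with a numerical M-step, with Minimum Message
    Length selection of the number of components. From fitted mixtures the
    package derives three generative kernels for support vector machines --
    the Fisher kernel, a symmetrized Kullback-Leibler kernel, and a
    Bhattacharyya (probability product) kernel -- and provides a bag-of-features
    image classification pipeline built on gray-level co-occurrence (Haralick)
    texture descriptors, cross-validated with a precomputed-kernel SVM.
    Includes a synthetic-data module so the whole pipeline is testable
    end-to-end without external image collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    kernlab,
    mclust,
    pracma,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    tiff
Config/testthat/edition: 3
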