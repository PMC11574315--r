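Package: lcpipe
Title: Annual Land-Cover Mapping from Irregular Satellite Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for annual land-cover mapping from
    irregular optical satellite time series. Provides weekly temporal encoding
    of dated, cloud-gapped reflectance observations into fixed-length 52-week
    feature matrices, a 1-D temporal-convolution classifier with
    augmentation-hardened training and a hierarchical 8-to-18-class prediction
    scheme (crop types and peat-bog subtypes), rule-based mining of training
    pixels from multi-year reference-product stacks, three post-classification
    noise filters (spatial majority, temporal, and spatio-temporal), and
    stratified accuracy and area estimation with confidence intervals. A
    synthetic-scene generator simulates class-specific double-logistic
    phenologies at year-dependent observation densities, crop rotations, and
    peat-bog exploitation dynamics so the full pipeline can be exercised and
    validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
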