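Package: asymjaw
Title: 3D Craniofacial and Temporomandibular Morphometry with Jaw-Kinematic
    Analysis for Facial Asymmetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement and statistical analysis of deviated- versus
    non-deviated-side differences in patients with mandibular asymmetry.
    Implements 3D cephalometric reference planes (Frankfurt horizontal,
    midsagittal, coronal), craniofacial and temporomandibular joint
    morphometric parameters from landmark coordinates, terminal hinge-axis
    estimation from rigid-body jaw-motion recordings with extraction of the
    seven dynamic condylar-path parameters, and the downstream statistics
    (Dahlberg method error, paired t comparison, Pearson correlation tables,
    principal components with varimax rotation, and paired-design
    noncentral-t power analysis). A synthetic generator of asymmetric skulls
    and rigid-body motion recordings with known ground truth makes every
    stage verifiable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
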