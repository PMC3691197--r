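Package: swellvol
Title: Volumetric Analysis of Soft-Tissue Swellings from Photogrammetric Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the volume of landmark-poor soft tissues (such as the
    perineal swellings of female Old World monkeys) from 3D landmark clouds
    exported by photogrammetric reconstruction. A small set of homologous
    "primary" landmarks defines an anatomical orientation frame via their
    spatial principal components; physical scale is restored from one known
    inter-landmark distance; volume above the base plane is obtained from a
    cubic-interpolated height grid by prism summation. Includes landmark file
    I/O (NTSYS-pc matrices and point lists), bootstrap subsampling of
    landmarks, distance-accuracy and replication statistics, and synthetic
    shape generators of known volume for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deldir,
    interp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
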