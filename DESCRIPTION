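Package: lodgepipe
Title: Digital Assessment of Crop Lodging from UAV Elevation Models with
    Genetic Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies plot-level crop lodging from pre- and post-event
    digital elevation models (DEMs) acquired by unmanned aerial systems.
    Two digital lodging measures are provided: the plot mean of the
    differential DEM (DLmean) and a mixture index (DLmix) obtained from a
    two-component Gaussian mixture whose first component mean is anchored
    at zero, fitted by expectation-maximisation.  The package also
    implements the downstream genetic validation toolchain: entry-mean
    heritability from REML variance components in alpha-lattice designs,
    genotype BLUEs, marker-based genetic correlations, mixed-model
    genome-wide association scans with Storey q-value FDR control, an
    alien-segment tag-ratio caller, and whole-genome prediction
    (ridge-regression BLUP, BayesC-pi, and reproducing-kernel Hilbert
    space regression) under leave-one-trial-out cross-validation.  A
    seeded synthetic-field generator emulates the full study design so
    that every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
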