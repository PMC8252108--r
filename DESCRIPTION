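Package: aacsia
Title: Compound-Specific Amino Acid Isotope Analysis for Trophic Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for compound-specific stable isotope analysis of amino
    acids (AA-CSIA) in trophic ecology, with an emphasis on mixotrophic
    symbioses such as reef corals and their Symbiodiniaceae. Provides an
    amino acid classification registry (essential/nonessential carbon,
    trophic/source nitrogen), validated long-format isotope tables,
    glutamic acid-phenylalanine trophic position with first-order error
    propagation, inverse-variance weighted mean delta-15N, the summed
    variance (Sum-V) resynthesis index, two-end-member percent-heterotrophy
    mixing models with propagated uncertainty, mean-normalized essential
    delta-13C fingerprinting, PERMANOVA on Euclidean distances with seeded
    or exhaustive permutation, correlation-matrix PCA, linear discriminant
    classification with leave-one-out cross-validation, standard-deviation
    ellipses, per-amino-acid two-factor linear models, a synthetic data
    generator emulating host/symbiont/plankton isotope structure, and a
    config-driven pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
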