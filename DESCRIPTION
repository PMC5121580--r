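Package: dartchemo
Title: Chemometric Classification of DART Mass Spectra for Parchment
    Conservation Treatments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying conservation treatments on
    parchment from ambient-ionization (DART) mass spectra. Centroided peak
    lists are aligned onto a common m/z grid, range scaled row- and
    column-wise, and reduced by principal component analysis; classes are
    modelled by Bayesian linear discriminant analysis on a forward-stepwise
    selected subset of principal components, validated by repeated stratified
    splitting with bootstrap cross-validation; canonical discriminant roots
    are back-projected through the PCA loadings to rank individual m/z
    signals as treatment markers. A synthetic peak-list generator with the
    statistical structure of the treated-parchment study (shared lipid
    backbone, glycerol marker ions, ion-source temperature effects) makes
    every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
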