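Package: libsionome
Title: Elemental Profiling of Fungal Biomass by Laser-Induced Breakdown
    Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible chemometrics pipeline for laser-induced breakdown
    spectroscopy (LIBS) ionomic profiling of axenic fungal cultures. Provides a
    seeded synthetic-spectrum generator with known element concentrations and
    class structure (species by growth medium), spectral preprocessing
    (cropping, shot averaging, normalization), local-baseline peak-intensity
    extraction against a reference emission-line library, element
    identification, Pearson correlation profiling with magnitude
    categorization, principal component analysis of full spectra, and linear
    discriminant classification of species and growth-medium labels in
    principal-component space, including a shot-averaging ablation.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
biocViews: Spectrometry, Classification, PrincipalComponent, Software
RoxygenNote: 7.3.3
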