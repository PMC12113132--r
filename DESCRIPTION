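Package: lipidnet
Title: Molecular Networking and Rule-Based Lipid Dereplication for
    Untargeted LC-MS/MS Metabolomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for feature-based molecular networking and rule-based
    dereplication of lipids from untargeted LC-MS/MS experiments.
    Provides elemental-formula algebra and monoisotopic ion m/z
    computation, readers and writers for MGF spectra and feature
    quantification tables, modified-cosine spectral similarity with
    GNPS-style network topology constraints, a diagnostic-ion rule
    engine annotating glycerophospholipids, ceramide phosphoinositols
    and prostaglandin-type oxylipins at the LIPID MAPS species level,
    an in-silico MS/MS spectrum simulator for end-to-end testing, and a
    pipeline that exports annotated GraphML networks and per-extract
    abundance summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
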