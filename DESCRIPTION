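Package: mzscreen
Title: Post-Targeted Accurate-Mass Screening of Fatty Acids, Amides and
    Cinnamates with Presence/Absence Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Post-targeted screening workflow for high-resolution
    LC-MS(E) data: accurate-mass target extraction within a ppm tolerance,
    bounded CHNO molecular-formula decomposition, ring-and-double-bond
    equivalent (DBE) and diagnostic-fragment classification of
    monocarboxylic and dicarboxylic fatty acids, fatty acid amides and
    cinnamic acid derivatives, and presence/absence chemometrics (PCA,
    Ward clustering, Pearson correlation, Venn partitioning) across
    extraction conditions.  Ships a transcribed 166-compound
    identification table from a supercritical-CO2 leaf-extract study as a
    fixture, plus a seeded synthetic MS(E) run generator with ground
    truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
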