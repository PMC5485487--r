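Package: sipcall
Title: Labeling Calls for DNA Stable-Isotope-Probing Experiments
Version: 0.1.0
Authors@R: person("sipcall", "maintainers", email = "sipcall@example.org",
    role = c("aut", "cre"))
Description: Detects isotopically labeled taxa in DNA stable-isotope-probing
    (DNA-SIP) amplicon experiments. Gradient fractions are classified into
    light and heavy pools by CsCl buoyant density, per-taxon enrichment in the
    heavy pool is quantified by an odds ratio, and labeling is called from the
    ratio of odds ratios (RoOR) between 13C incubations and their paired 12C
    controls, with a read-count eligibility filter. Also provides the
    descriptive companions used in such studies (relative-abundance profiles,
    correlation-distance Ward clustering with bootstrap node support, Newick
    export) and a seeded synthetic CsCl-gradient read-count generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
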