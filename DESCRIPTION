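Package: fermstoich
Title: Fermentation Stoichiometry and Community Response in Anoxic Gut Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for anoxic gut-content microcosm fermentation
    experiments. Provides degree-of-reduction electron bookkeeping and carbon /
    reducing-equivalent recovery tables for supplemented substrates, headspace
    gas partitioning with carbonate equilibrium, the time- and control-corrected
    net-increase screen for substrate-responsive 16S rRNA phylotypes with
    greedy group-phylotype clustering and alpha/beta diversity indices, and
    seeded synthetic-data generators (product time courses from known
    stoichiometries, communities with planted responders, divergent marker
    sequences) so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
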