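Package: pctrace
Title: Stable Isotope Tracer Simulation and Pyruvate Carboxylation
    Inference in Mixed Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates steady-state 13C mass isotopomer distributions (MIDs)
    over a carbon atom-transition network covering lower glycolysis, pyruvate
    dehydrogenase, pyruvate carboxylase, malic enzyme and the TCA cycle, using
    an elementary metabolite unit (EMU) decomposition with a brute-force
    isotopomer oracle for verification.  Models label incorporation into
    slow-turnover protein (end-product biomass labeling) that survives cell
    sorting, couples multiple cell-type compartments through shared medium
    pools, corrects raw GC-MS mass isotopomer distributions of
    TBDMS-derivatized amino acids for natural isotope abundance, and infers
    cell-type-specific pyruvate-carboxylation activity (including pyruvate
    carboxylase and malic enzyme knockout scenarios) from sorted-population
    protein hydrolysate labeling.  Includes a synthetic-experiment generator
    emulating tracer studies in cancer-cell/fibroblast co-cultures and tumors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
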