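Package: suprafit
Title: Fluorescence and NMR Analysis of Self-Assembling Host-Guest Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative analysis chain for self-dimerizing fluorescent
    hosts such as aromatic-clipped cyclodextrins: time-correlated
    single-photon-counting (TCSPC) decay fitting by iterative
    reconvolution, exact mass-action speciation for monomer-dimer and
    host-guest equilibria, a lifetime-based dimerization isotherm,
    Stern-Volmer quenching analysis, van't Hoff enthalpy/entropy
    regression, 1:1 NMR chemical-shift titration models, and the
    induced-circular-dichroism sign rule. Includes seeded synthetic-data
    generators emulating every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
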