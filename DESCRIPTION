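Package: bvfit
Title: Bond-Valence Parameter Fitting and Metal-Site Validation
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the bond-valence model of metal coordination
    chemistry: bond-valence sums, closed-form homoleptic R0 derivation,
    simultaneous nonlinear least-squares fitting of R0 parameters over
    homoleptic and heteroleptic coordination sites, oxidation-state
    assignment from compound names and ligand-template charge balance,
    site-level filtering with an audit ledger, low-spin/high-spin
    population splitting for Fe-N bonds, uncertainty estimation from
    per-site parameter shifts, a synthetic site-population generator for
    testing parameter recovery, and bond-valence-sum validation of
    metal-binding sites extracted from macromolecular coordinate files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
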