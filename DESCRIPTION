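Package: BundleForge
Title: Parametric Design of Obligate ABC Helical-Bundle Heterotrimers
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational design pipeline for obligate ABC-type heterotrimeric
    coiled coils and six-helix bundles. Generates poly-alanine backbones from a
    generalized Crick supercoil parameterization, enumerates backbone parameter
    grids and runs the staged (stepwise) six-helix search, assigns heptad
    register and core/boundary/surface layers, searches for inter-chain
    hydrogen-bond networks by Monte Carlo rotamer placement with satisfaction
    filtering, enumerates alternative (off-target) oligomeric species for
    negative design bookkeeping, and performs rigid helical splice fusions with
    cyclic ring closure filtered on chain length, internal clashing and ring
    closure error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
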