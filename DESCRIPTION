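Package: baxdm
Title: Analysis of Small-Molecule Modulation of the Inactive BAX Dimer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational workflow used to characterize
    small-molecule modulators of the autoinhibited cytosolic BAX dimer:
    structure-derived pharmacophore modelling and conformer-library
    screening by correspondence enumeration and rigid superposition,
    HSQC chemical-shift-perturbation analysis with per-region summaries,
    conformational-ensemble metrics (RMSD, RMSF, residue-pair distances
    and a two-triangle Heron decomposition of the canonical-site area),
    constrained curve fits for binding isotherms, competitive
    fluorescence-polarization and thermal-shift assays, Bliss
    independence synergy scoring, size-exclusion chromatography
    quantification and mitochondrial depolarization normalization.
    Seeded synthetic-data generators emulate each input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
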