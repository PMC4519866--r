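Package: somcyp
Title: Mechanism-Based Prediction of CYP3A4 Sites of Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts sites of metabolism (SoM) on cytochrome P450 3A4
    substrates by combining binding accessibility with chemical reactivity.
    Candidate carbons (aliphatic hydroxylation, N-dealkylation) are qualified
    from an ensemble of docked ligand poses by their distance to the heme iron
    and by key active-site interaction features (hydrogen bonds to
    Arg105/Arg106/Ser119/Ile301/Glu308 and ordered waters, lipophilic contacts
    with the Phe-cluster or the heme), then ranked by the hydrogen-abstraction
    reaction energy of their attached hydrogens computed with a self-contained
    CNDO/2 semi-empirical SCF engine (closed-shell parents, spin-unrestricted
    radicals). Includes SDF V2000 and MOL2 molecule input, PDB active-site
    extraction, a top-k evaluation protocol, and deterministic synthetic
    fixtures for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    ChemmineR,
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
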