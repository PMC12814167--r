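Package: TwoStateDesign
Title: Two-State Stability Design for Dynamic Two-Lobe Binding Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conformation-aware stability design for proteins that alternate
    between open and closed states, such as periplasmic binding proteins.
    Builds Gaussian network models of both conformations to locate hinge and
    lobe-interface residues, restricts the design alphabet to evolutionarily
    tolerated identities via an MSA-derived position-specific scoring matrix,
    filters candidate point mutations by the sign of their predicted stability
    change in both conformational states, and assembles combinatorial design
    variants at discrete energy cutoffs into four design tiers. Includes a
    transparent surrogate stability calculator and a synthetic two-lobe
    fixture generator so the whole workflow is exercisable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    bio3d,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'TwoStateDesign-package.R'
    'aa-data.R'
    'pssm.R'
    'structure-io.R'
    'surrogate.R'
    'gnm.R'
    'fixtures.R'
    'constraints.R'
    'design.R'
    'cli.R'
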