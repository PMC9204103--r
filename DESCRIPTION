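Package: footprintr
Title: Covalent-Labeling Mass-Spectrometric Protein Footprinting
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for lysine-directed covalent-labeling
    (NHS-biotin) protein footprinting by mass spectrometry. Provides
    monoisotopic mass arithmetic for residues, modifications and charged
    species; modification-aware in-silico tryptic digestion in which a
    biotinylated lysine blocks cleavage; peptide-mass-fingerprint matching
    of theoretical digests against MS1 peak lists; b/y fragment-ion ladder
    generation and Ascore-style cumulative-binomial localization of the
    modified lysine; aggregation of per-state modified-lysine evidence into
    surface-accessibility maps with differential (cis vs trans conformer)
    comparison annotated by protein domain; a synthetic-experiment
    generator with ground-truth recovery scoring; and a small omega-dihedral
    utility classifying cis/trans peptide-bond geometry.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
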