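Package: stabiliforge
Title: Automated Design of Thermostable Multiple-Point Protein Mutants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational design of stabilizing protein mutations from a
    tertiary structure and a homolog alignment. Annotates the target protein
    with Jensen-Shannon conservation, consensus coevolution calls, solvent
    accessibility and per-residue B-factors; proposes single-point mutations
    by saturation mutagenesis under free-energy thresholds, by
    back-to-consensus rules and from ancestral sequences; and assembles
    non-antagonistic multiple-point designs by removing antagonistic pairs
    from a pair-energy graph and selecting the best Bron-Kerbosch maximal
    clique. Includes file adapters for external ddG tables, a deterministic
    surrogate energy evaluator, confusion-matrix validation metrics and
    synthetic generators for structures, alignments and energy landscapes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
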