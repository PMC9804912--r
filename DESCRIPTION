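Package: zincsites
Title: Zinc-Binding Site Discovery on Protein Structure Models and
    ICP-MS Metalloprotein Stoichiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate zinc-coordination clusters on a protein
    structure model by combining per-column conservation scores from a
    multiple sequence alignment with coordination-shell geometry: conserved
    histidine/cysteine seeds are grouped by functional-atom proximity,
    augmented with conserved aspartate/glutamate/serine residues, screened
    for crossed-disulfide ZnC4 (redox switch) arrangements, classified as
    structural-like or catalytic-like from side-chain burial, and scored for
    hydrophobic contrast on the Eisenberg consensus scale. Also maps
    zinc-finger-like C2H2 motifs and literal sequence motifs, and reduces
    ICP-MS measurements of a purified metalloprotein to a molar Zn:protein
    stoichiometry with blank-derived detection limits and a nonparametric
    group comparison. A synthetic-data module generates structures with
    planted tetrahedral sites, alignments with controlled conservation, and
    ICP-MS tables with known true ratios so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
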