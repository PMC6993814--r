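Package: kojimosaic
Title: Clade Structure, Chromosomal Mosaicism and Domestication
    Mutation Spectra in Koji Mould Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for clonally domesticated
    filamentous fungi such as Aspergillus oryzae. Builds degapped
    concatenated alignments of single-copy orthogroups, computes
    p-distances, clusters strains into clades at a dissimilarity
    threshold, infers neighbor-joining trees, types the MAT mating-type
    locus and checks MAT-by-clade linkage, paints chromosomes by the
    closest clade in a sliding window to reveal recombination
    mosaicism, classifies codon-level synonymous, non-synonymous and
    gap mutations within and between clades with Fisher exact odds
    against a baseline species, and estimates gene copy number from
    normalized read depth. Ships a forward simulator of recombinant
    mosaic genomes with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
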