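Package: crpkit
Title: Discovery and Characterization of Plant Cysteine-Rich Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A peptidomics toolkit for discovering and characterizing
    disulfide-rich plant peptides (knottins and relatives) from MALDI-TOF
    data and sequence databases. Counts cysteines by the reduction and
    carbamidomethylation mass shift between native and alkylated peak
    lists, performs in-silico complete and partial protease digestion,
    interprets b-/y-ion MS/MS ladders into de novo sequence candidates,
    assembles overlapping digest fragments into full-length peptides with
    enzymatic resolution of the isobaric Lys/Gln and Leu/Ile pairs,
    annotates cysteine-loop architecture and putative cystine-knot
    connectivity, classifies peptides by the P1 residue of loop 1,
    computes EMBOSS-Needle-style pairwise similarity and neighbor-joining
    trees, and mines six-frame-translated nucleotide data for homologous
    precursors. Seeded simulators generate peak lists, fragment spectra
    and precursor-bearing genomes so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
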