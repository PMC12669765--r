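Package: origamir
Title: Motif-Based Design of Co-Transcriptional RNA Origami
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable design engine for co-transcriptional RNA origami
    nanostructures. Parametric structural motifs (stems, tetraloops, dovetail
    crossovers, 180-degree kissing loops, aptamers) are placed on a 2D grid and
    assembled into a multi-strand text blueprint with a layered base-pair map
    that supports pseudoknots. From the blueprint the package derives a
    sequence-constraint/dot-bracket target, designs a concrete sequence by
    constraint-respecting stochastic search with sequence-symmetry
    minimisation (optionally guided by a ViennaRNA folding oracle), builds a
    rigid 3D model from ideal A-form helix geometry, and reads/writes
    oxDNA-format topology and configuration files. Downstream utilities
    prepare the wet-lab hand-off: DNA template construction with a T7
    promoter, GC content, IUPAC subsequence search, dimer prediction,
    nearest-neighbor melting temperatures with salt correction, and automatic
    end-anchored PCR primer design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
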