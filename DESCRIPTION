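Package: trmloci
Title: Annotation and Comparative Characterization of Cluster-Organized
    T Cell Receptor Mu Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discover and characterize the gene segments of
    cluster-organized antigen-receptor loci, in particular the marsupial and
    monotreme T cell receptor mu (TRM) locus. Implements recombination signal
    sequence (RSS) detection with consensus-weighted scoring, seed-and-extend
    homology search for V/C gene segments, motif-based J segment annotation,
    D segment inference from V-D-J junction transcripts, assembly of
    [V-D-J-Vj-C]-style clusters with completeness and duplication-pattern
    calls, pairwise nucleotide-identity matrices over framework regions with
    threshold class assignment, and a seeded synthetic-locus generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
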