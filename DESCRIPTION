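Package: transqc
Title: Reference-Free Quality Assessment of De Novo Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free quality assessment of de novo transcriptome
    assemblies from paired-end read-mapping evidence. Computes four
    per-contig score components (per-base read support, read coverage,
    read-pair order consistency, and the posterior probability that the
    coverage profile represents a single transcript, obtained by Bayesian
    change-point segmentation of the coverage depth), combines them into a
    contig score and an assembly score, learns the contig-score cutoff
    that maximizes the assembly score, and filters assemblies accordingly.
    Includes expectation-maximization assignment of multi-mapping read
    pairs, inference of the library fragment-size model, reciprocal
    best-hit accuracy evaluation against a reference transcript set, and
    a paired-end read simulator (with transcript fusion and assembly
    corruption generators) for end-to-end validation without an external
    aligner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
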