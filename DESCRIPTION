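Package: gridmsa
Title: Progressive Multiple Sequence Alignment with Dual-Mode Distance
    Storage and Dynamic Task Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage progressive multiple sequence aligner for protein
    and nucleic-acid families: (1) all-against-all pairwise distances by
    affine-gap global alignment, with the symmetric distance matrix held
    either in memory or in a fixed-layout disk file so the phase scales past
    RAM; (2) neighbor-joining guide trees with per-join checkpointing; (3)
    weighted profile-profile progressive alignment with sum-of-pairs
    scoring.  The pairwise workload can be distributed by an idle-worker
    self-scheduling policy (one task per request, the moment a worker goes
    idle) or by static fixed-size chunks, and a discrete-event simulator
    compares the two policies' makespan, speedup and idle fraction on
    arbitrary task-cost sets.  Includes a seeded generator of synthetic
    sequence families for end-to-end testing, a catalogue of more than 34
    protein weight matrices, and readers/writers for FASTA, Clustal .aln
    and Newick.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    parallel
Config/testthat/edition: 3
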