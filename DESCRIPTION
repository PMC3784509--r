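Package: mitoDuplex
Title: Duplex Consensus Sequencing and Somatic Mitochondrial Mutation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements the Duplex Sequencing consensus-calling pipeline
    (tag extraction, read-family grouping, single-strand and duplex
    consensus construction, end clipping, near-tag deduplication, and
    NUMT decoy filtering) together with the downstream somatic
    mitochondrial DNA mutation statistics: de novo mutation frequency
    under a clonality cutoff with Wilson score intervals, the
    six-class substitution spectrum normalised by wild-type base
    exposure, D-loop versus coding-region comparisons, light-strand
    reciprocal-mutation asymmetry, and synonymous/non-synonymous
    accounting under the vertebrate mitochondrial genetic code. A
    seeded simulator generates duplex-tagged paired-end libraries with
    stage-specific error classes (true mutations, single-strand
    damage, late PCR errors, sequencing errors) and a ground-truth
    ledger, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    seqinr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
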