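Package: domcons
Title: Consensus Assignment of Protein Structural Domains from Multiple Methods
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compares structural domain assignments produced for a single
    protein chain by multiple algorithmic methods, decides pairwise agreement
    using a residue-overlap criterion, groups agreeing methods greedily, and
    reports a consensus partition with a reliability score.  Supports a simple
    (equal-vote) and a weighted consensus in which each method's vote is scaled
    by its prior benchmark performance and adjusted by context rules that look
    at predicted domain counts, domain fragmentation, and the chain's
    secondary-structure class.  Includes readers for a native assignment table
    format, CATH Domall files and classic DSSP output, an analysis of how
    domain and fragment boundaries cut alpha-helices and beta-strands, a
    synthetic-assignment simulator for testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
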