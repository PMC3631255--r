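Package: submotif
Title: Exact Enumeration of Typed Subgraph Motifs in Large Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact enumeration of all instances of a small query motif in a
    large network whose edges carry types (directed or undirected).  The
    search engine orders motif nodes dynamically using type-indexed candidate
    sets so that the narrowest candidate set is always expanded first, and it
    exploits the motif's automorphism group (reflection and cyclic-rotation
    symmetries, plus canonical-form elimination of residual duplicates) to
    report each instance exactly once.  A naive fixed-order recursive matcher
    and a brute-force oracle are included for verification, together with a
    per-type edge-list reader and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
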