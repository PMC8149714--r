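Package: deljunct
Title: Deletion Breakpoint Microhomology and Repair-Mechanism Analysis for
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes large chromosomal deletions between a reference and
    a rearranged bacterial genome assembly. Detects deletions with unique
    k-mer anchor chaining, identifies the maximal exact direct repeat
    (microhomology) at each breakpoint with canonical leftmost placement,
    re-enacts deletions in silico and verifies the reconstructed junction in
    the rearranged assembly, and classifies the compatible double-strand-break
    repair mechanism (alternative end-joining, single-strand annealing, or
    non-homologous end-joining) from the junction features. Also computes the
    supporting genome statistics: genome coverage by exact repeat pairs of a
    given length, GC content, GC3s, synonymous codon usage order (SCUO), COG
    category tabulation for a region, and replichore-balance terminus
    prediction. Includes a synthetic-genome simulator that plants repeats and
    deletion events with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
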