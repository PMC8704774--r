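Package: p74tools
Title: Conservation Profiling, Domain Chimeras and CRISPR Knockout
    Annotation for Baculovirus P74
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in-silico toolkit for the baculovirus per os infectivity
    factor P74 (PIF0) and related protein families. Derives Clustal-style
    consensus lines from protein multiple alignments and turns them into
    windowed sequence-similarity profiles; computes alignment-wide
    hydropathy profiles with a standard-deviation variability track;
    locates the conserved tryptophan-aspartate-proline (WDP) triad in
    coding sequences, introduces the minimal synonymous edit that creates
    a BamHI site at the triad, splits ORFs into amino- and
    carboxyl-terminal domains and assembles in-frame chimeric ORFs;
    annotates CRISPR/Cas9 NHEJ indel outcomes (frameshift, premature
    stop, truncated product); and computes pairwise identity/similarity
    matrices for complete proteins and their domains. A seeded synthetic
    data generator produces protein families and ORFs with planted,
    auditable ground truth for testing every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
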