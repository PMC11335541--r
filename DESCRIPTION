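Package: vlrbkit
Title: Long-Read Sequencing Analysis of Variable Lymphocyte Receptor B Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for immune-repertoire analysis of the leucine-rich-repeat
    based variable lymphocyte receptor B (VLRB) antibodies of jawless
    vertebrates from long-read (HiFi) amplicon sequencing. Covers primer and
    barcode demultiplexing, UMI-based molecule collapsing and one-mismatch
    UMI neighbor removal, translation and stalk-motif filtering, structural
    subunit annotation (signal peptide, LRR-NT, LRR1, variable LRRv units,
    connecting peptide, LRR-CT with core and extended loop, invariant stalk),
    consensus length filtering with stepwise accounting, greedy identity
    clustering, cross-animal sharing analysis, and amino-acid hydropathy and
    polarity analytics. Includes a synthetic repertoire and read simulator
    that emulates the cassette-assembled VLRB architecture so the entire
    pipeline is testable without access to deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
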