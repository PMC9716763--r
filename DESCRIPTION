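Package: igstyper
Title: Tephritid Fruit Fly Identification from Mitochondrial Intergenic Spacer Lengths
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies five tephritid fruit fly pest species (Ceratitis
    capitata, C. cosyra, C. rosa, C. quilicii and Bactrocera dorsalis) from
    the length of mitochondrial intergenic region I between tRNA-Ile and
    tRNA-Gln. Provides in-silico PCR with the Mito_F/R primer pair on linear
    or circular templates, dissection of the amplicon into its three tRNA
    anchor segments and two intergenic spacers by semi-global alignment, a
    length-signature species classifier with a percent-identity fallback and
    confounder reporting, a seeded synthetic amplicon and mitogenome
    simulator with substitution/indel noise for validation, and readers for
    FASTA and GenBank flat files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
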