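Package: xrfrag
Title: Analysis of Organellar XR-Seq Excision Fragments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing UV-damage-derived DNA fragments captured by
    excision repair sequencing (XR-seq), with a focus on reads originating
    from small circular organellar genomes (mitochondrial and plastid DNA).
    Provides uniqueness-aware alignment and filtering with explicit handling
    of nuclear insertions of organellar DNA (NUMTs/NUPTs) and plastid
    inverted repeats, read-length spectra with inter-sample correlation,
    anchored positional nucleotide and di-pyrimidine frequency profiles
    tested against a genome-wide null expectation, RPKM coverage by genome
    and annotated region with template/coding strand comparisons, and a
    synthetic-data generator that emits damage-anchored fragment libraries
    with full ground truth so the whole pipeline can be exercised without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
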