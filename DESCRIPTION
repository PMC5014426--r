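Package: teloci
Title: Comparative Transposable Element Annotation and Allelic Inheritance
    Analysis for Related Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural annotation of LTR retrotransposons, solo LTRs and
    LINE fragments from raw sequence (terminal inverted repeats, target-site
    duplications, LTR pairs, primer binding sites, polypurine tracts, ORF
    layout); partition of annotated genomes into interval loci (iLoci);
    reciprocal-best allelic mapping between two related assemblies with
    per-kb mismatch/insertion/deletion densities; naive-site reconstruction
    and the allelic versus non-allelic flanking-density contrast used to
    distinguish chromosomal inheritance of transposable elements from
    post-cross transposition; plus a synthetic hybrid-strain generator with
    planted elements and known truth so the whole pipeline is testable
    without external data. Includes in-silico nickase digest utilities with
    tandem-period detection for optical-map style repeat localization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
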