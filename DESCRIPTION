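Package: ltrclass
Title: Structural Annotation and Lineage Classification of LTR-Retrotransposons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for characterizing and classifying plant LTR-retrotransposons
    from DNA sequence. Detects long terminal repeat (LTR) pairs, target site
    duplications and TG/CA termini; locates polyprotein domains (GAG, PROT, RT,
    RH, aRH, INT and chromodomains) by six-frame translated search against a
    REXdb-style reference database with frameshift-tolerant hit chaining; types
    the primer binding site (full tRNA, half-molecule tRNA, fuzzy tRNA match or
    self-primer); detects extra open reading frames with tandem-repeat
    filtering; assigns hierarchical lineages (chromovirus clades, OTA, Tat
    subclades and Ty1/copia lineages) with structural-feature consistency
    checks; and supports redundancy reduction by identity clustering plus
    observed-distance matrices and neighbor-joining trees. A deterministic
    synthetic-element generator with ground-truth manifests makes every stage
    testable without external data.
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
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
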