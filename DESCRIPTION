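Package: indelmapr
Title: InDel Marker Design and Bulked Segregant Mapping for Inbred Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-variant-calling toolkit for forward genetics in selfing
    crops. Catalogues SNP/InDel/SV polymorphisms between two inbred
    accessions (zygosity, Ts/Tv, length classes, windowed densities),
    annotates variant effects against gene models (synonymous/missense,
    frameshift, splice-region and other large-effect classes), screens
    InDels into agarose-resolvable PCR markers by polymorphism information
    content (PIC) across an accession panel with nearest-neighbor primer
    design, and positionally clones a recessive locus by bulked segregant
    analysis: coarse mapping with a recessive bulk, recombinant-count fine
    mapping, 3:1 segregation testing and BSA-seq style candidate SNP
    nomination. Includes a seeded simulator of divergent genomes, gene
    models, accession panels and F2 populations so every stage is testable
    end to end.
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
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
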