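Package: eetscan
Title: Detection and Quantification of Putative Extracellular Electron
    Transfer Genes in Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens annotated (meta)genome assemblies for putative
    extracellular electron transfer (EET) genes: multiheme c-type
    cytochromes (MHCs) detected by CXXCH heme-binding-motif scanning,
    porin-cytochrome c conduit (PCC) gene clusters found either by
    homology to characterized families (MtrABC, MtoAB, PioAB,
    OmbB-OmaB-OmcB) or by their characteristic porin/periplasmic-MHC
    gene organization, outer-surface MHCs not associated with a PCC,
    and Cyc2-like monoheme iron-cycling cytochromes. Gene abundances
    are normalized by the average read coverage of single-copy
    conserved housekeeping genes and summarized per gene, per
    metagenome-assembled genome (MAG), and per metagenome. A
    synthetic-metagenome generator with planted ground truth supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
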