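Package: hetcal
Title: Spike-In Calibrated Genome-Wide Analysis of HDAC-Regulated Transcription
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for spike-in calibrated genome-wide analysis of
    transcriptional silencing by class I/II histone deacetylases in fission
    yeast: dual-genome read disambiguation against an S. cerevisiae spike,
    per-assay spike size factors (total-spike, ribosomal-protein-gene, ERCC,
    and input-corrected ChIP schemes), NET-seq Pol II occupancy at
    single-nucleotide resolution, calibrated negative-binomial differential
    expression with two-fold classification and cross-assay concordance,
    H3-normalized H3K14ac coverage with TSS metagene profiles, and
    segmentation-based annotation of cryptic unstable transcripts (CUTs).
    Includes a deterministic two-species synthetic-data generator with
    planted effects so that every pipeline stage can be validated against a
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    MASS
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Sequencing, Epigenetics, Normalization, DifferentialExpression,
    Transcription, Coverage
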