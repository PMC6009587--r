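## Shared fixture builders.  Everything is generated in code at test time;
## sizes are kept small so the whole suite runs in minutes.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(S4Vectors)
})

tinyConfig <- function(...) {
    defs <- list(targetSize = 40000L, targetChroms = 1L,
                 spikeSize = 20000L, spikeChroms = 1L,
                 nMrna = 20L, nNcrna = 4L, nCut = 4L,
                 nSpikeMrna = 6L, nRpSpike = 5L, nErcc = 4L)
    do.call(simConfig, utils::modifyList(defs, list(...)))
}

tinyRef <- function(seed = 1, cfg = tinyConfig()) buildToyReference(seed, cfg)

## a GRanges of fragments with read ids
fragGR <- function(chrom, start, end, strand = "+", ids = NULL,
                   seqlens = NULL) {
    gr <- if (length(start) == 0L) GRanges()
    else GRanges(chrom, IRanges(start, end), strand = strand)
    if (!is.null(seqlens)) {
        seqlevels(gr) <- names(seqlens)
        seqlengths(gr) <- seqlens
    }
    if (length(gr))
        names(gr) <- ids %||% paste0("r", seq_along(gr))
    gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## write a small FASTQ with given per-read qualities (single Phred char)
writeTestFastq <- function(path, seqs, qchars) {
    stopifnot(length(seqs) == length(qchars))
    lines <- as.vector(rbind(paste0("@read", seq_along(seqs)), seqs, "+",
                             vapply(seq_along(seqs), function(i)
                                 strrep(qchars[i], nchar(seqs[i])),
                                 character(1))))
    writeLines(lines, path)
    path
}

## independent brute-force BH step-up (the oracle): for each p_i take the
## minimum over all j with p_j >= p_i of m * p_j / rank_j
bruteBH <- function(p) {
    m <- length(p)
    r <- rank(p, ties.method = "first")
    vapply(seq_len(m), function(i) {
        cand <- which(p >= p[i] | seq_len(m) == i)
        min(1, min(m * p[cand] / r[cand]))
    }, numeric(1))
}
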