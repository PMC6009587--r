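## Read preparation: FASTQ quality filtering, SAM loading via
## Rsamtools/GenomicAlignments, competitive target/spike disambiguation,
## and reduction of NET-seq fragments to single Pol II nucleotides.

#' Read filter configuration
#'
#' Defaults follow the study's trimming thresholds: reads with mean Phred
#' quality below 20 or shorter than 20 nt are discarded.
#'
#' @param minMeanQuality Minimum mean Phred score over the read.
#' @param minLengthNt Minimum read length in nt.
#' @return A validated list of class `ReadFilterConfig`.
#' @export
readFilterConfig <- function(minMeanQuality = 20, minLengthNt = 20) {
    stopifnot(minMeanQuality >= 0, minLengthNt >= 0)
    structure(list(minMeanQuality = minMeanQuality,
                   minLengthNt = as.integer(minLengthNt)),
              class = "ReadFilterConfig")
}

## structural FASTQ sanity check so parse failures name the record
.check_fastq <- function(path) {
    n <- length(readLines(path, warn = FALSE))
    if (n %% 4L != 0L)
        stop("parse error: FASTQ record ", n %/% 4L + 1L,
             " is truncated in ", path)
    invisible(TRUE)
}

#' Filter reads on mean quality and length
#'
#' Keeps reads whose mean Phred score is at least `cfg$minMeanQuality` and
#' whose length is at least `cfg$minLengthNt`.  A read failing the length
#' check is counted as `dropped_length` regardless of its quality; only
#' length-passing reads can be `dropped_quality`.
#'
#' @param input Path to a FASTQ file.
#' @param output Optional path for the filtered FASTQ.
#' @param cfg A [readFilterConfig()].
#' @return List with `kept`, `dropped_quality`, `dropped_length`, `output`.
#' @export
qualityFilter <- function(input, output = NULL, cfg = readFilterConfig()) {
    stopifnot(inherits(cfg, "ReadFilterConfig"))
    .check_fastq(input)
    reads <- tryCatch(
        suppressWarnings(
            readQualityScaledDNAStringSet(input, quality.scoring = "phred")),
        error = function(e) stop("parse error reading FASTQ '", input,
                                 "': ", conditionMessage(e)))
    if (length(reads) == 0L)
        res <- list(kept = 0L, dropped_quality = 0L, dropped_length = 0L)
    else {
        lens <- width(reads)
        meanQ <- vapply(as(quality(reads), "IntegerList"), mean, numeric(1))
        shortr <- lens < cfg$minLengthNt
        lowq <- !shortr & meanQ < cfg$minMeanQuality
        keep <- !shortr & !lowq
        res <- list(kept = sum(keep), dropped_quality = sum(lowq),
                    dropped_length = sum(shortr))
        reads <- reads[keep]
    }
    if (!is.null(output))
        .atomic_write(output, function(tmp)
            suppressWarnings(writeQualityScaledXStringSet(reads, tmp)))
    res$output <- output
    res$reads <- reads
    res
}

#' Load per-genome alignments as fragments
#'
#' Reads a SAM (or BAM) file through Rsamtools and reduces alignments to
#' strand-aware fragment intervals keyed by read id.  In `paired` mode only
#' properly-paired primary alignments are kept and each mate pair is merged
#' into one fragment interval (strand of the first mate); in `single` mode
#' primary mapped records are kept.  Unmapped, secondary and supplementary
#' records are always dropped.
#'
#' @param path SAM/BAM path (SAM must carry a header with `@SQ` lines).
#' @param mode `"paired"` or `"single"`.
#' @return A GRanges named by read id with a `properly_paired` metadata
#'   column; `metadata()` holds record counts (`records`, `kept`).
#' @export
loadAlignments <- function(path, mode = c("paired", "single")) {
    mode <- match.arg(mode)
    bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) path
    else {
        hdr <- readLines(path, n = 200L, warn = FALSE)
        if (!any(startsWith(hdr, "@SQ")))
            stop("format error: SAM '", path,
                 "' has no @SQ header lines")
        dest <- tempfile(fileext = "")
        tryCatch(asBam(path, dest, overwrite = TRUE,
                       indexDestination = TRUE),
                 error = function(e)
                     stop("format error: cannot read SAM '", path, "': ",
                          conditionMessage(e)))
    }
    total <- Rsamtools::countBam(bam)$records
    if (mode == "paired") {
        flags <- scanBamFlag(isProperPair = TRUE,
                             isSecondaryAlignment = FALSE,
                             isSupplementaryAlignment = FALSE)
        ga <- readGAlignmentPairs(bam, use.names = TRUE,
                                  param = ScanBamParam(flag = flags))
        gr <- granges(ga, on.discordant.seqnames = "drop")
        gr$properly_paired <- rep(TRUE, length(gr))
    } else {
        flags <- scanBamFlag(isUnmappedQuery = FALSE,
                             isSecondaryAlignment = FALSE,
                             isSupplementaryAlignment = FALSE)
        ga <- readGAlignments(bam, use.names = TRUE,
                              param = ScanBamParam(flag = flags))
        gr <- granges(ga)
        gr$properly_paired <- rep(FALSE, length(gr))
    }
    metadata(gr) <- list(records = total, kept = length(gr))
    gr
}

#' Competitive target/spike disambiguation
#'
#' Reads aligned to both genomes are removed from both sides; only reads
#' unique to one genome are kept.  The decision is made at read-id level:
#' a read id present in both alignment sets is ambiguous regardless of
#' where or how well it aligned.
#'
#' @param targetFrags,spikeFrags GRanges named by read id (one record per
#'   read), e.g. from [loadAlignments()].
#' @return List with `unique_target`, `unique_spike` (GRanges) and
#'   `ambiguous_ids` (character).
#' @examples
#' t <- GenomicRanges::GRanges("c1", IRanges::IRanges(1:3 * 10, width = 5))
#' names(t) <- c("r1", "r2", "shared")
#' s <- GenomicRanges::GRanges("s1", IRanges::IRanges(c(5, 50), width = 5))
#' names(s) <- c("shared", "r9")
#' disambiguate(t, s)$ambiguous_ids
#' @export
disambiguate <- function(targetFrags, spikeFrags) {
    tn <- names(targetFrags); sn <- names(spikeFrags)
    if (is.null(tn) && length(targetFrags) ||
        is.null(sn) && length(spikeFrags))
        stop("input error: fragments must be named by read_id")
    if (anyDuplicated(tn))
        stop("input error: duplicate read_id in target alignments")
    if (anyDuplicated(sn))
        stop("input error: duplicate read_id in spike alignments")
    shared <- intersect(tn, sn)
    list(unique_target = targetFrags[!(tn %in% shared)],
         unique_spike = spikeFrags[!(sn %in% shared)],
         ambiguous_ids = shared)
}

#' Trim NET-seq fragments to the Pol II nucleotide
#'
#' Each NET-seq read's 3' end marks the nucleotide in the active centre of
#' Pol II, so every fragment is reduced to that single base: the last base
#' in transcription direction (the rightmost base for plus-strand
#' fragments, the leftmost for minus-strand fragments).  Identical
#' positions are aggregated with a `weight` count; total weight equals the
#' number of input fragments.
#'
#' @param frags Stranded GRanges of single-end NET-seq fragments.
#' @return Width-1 GRanges with a `weight` column.
#' @export
trimToPol2 <- function(frags) {
    if (any(strand(frags) == "*"))
        stop("NET-seq fragments must be stranded")
    sl <- seqlengths(frags)
    if (!all(is.na(sl))) {
        bad <- end(frags) > sl[as.character(seqnames(frags))] |
            start(frags) < 1L
        if (any(bad, na.rm = TRUE))
            stop("coordinate error: ", sum(bad, na.rm = TRUE),
                 " fragment(s) extend beyond chromosome ends")
    }
    pos <- resize(granges(frags), width = 1L, fix = "end")
    u <- unique(pos)
    u$weight <- countOverlaps(u, pos, type = "equal")
    names(u) <- NULL
    u
}
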