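## I/O layer.  All coordinate conversions to on-disk formats happen here and
## nowhere else: GFF3 and SAM are written 1-based closed (native), bedGraph
## 0-based half-open (handled by rtracklayer in tracks.R).  SAM is written
## by a plain-text writer below; SAM *reading* always goes through
## Rsamtools/GenomicAlignments (readprep.R).

.atomic_write <- function(path, writer) {
    tmp <- paste0(path, ".tmp", Sys.getpid())
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop("I/O error: cannot write ", path)
    invisible(path)
}

## vectorized sequence extraction, reverse-complemented on the minus strand
.extract_seq <- function(genome, chrom, start, end, strand) {
    chars <- as.character(genomeSeqs(genome))
    s <- substring(chars[chrom], start, end)
    neg <- strand == "-"
    if (any(neg))
        s[neg] <- as.character(reverseComplement(DNAStringSet(s[neg])))
    s
}

.sam_header <- function(sl) {
    c("@HD\tVN:1.6\tSO:unknown",
      sprintf("@SQ\tSN:%s\tLN:%d", names(sl), unname(sl)))
}

#' Write simulated ground-truth alignments as SAM
#'
#' Emits the simulated placements of one library against one genome as a
#' plain-text SAM file (header with chromosome lengths, coordinate-sortable
#' records).  Paired libraries are written as two properly-paired mates per
#' fragment; single-end libraries as one record per read.  Ambiguous reads
#' (drawn from the shared cassette) are included, so the same read ids
#' appear in both genomes' files.
#'
#' @param sim A `SimReads` object from [simulateAssay()].
#' @param ref The [ToyReference-class] the simulation was built on.
#' @param side `"target"` or `"spike"`.
#' @param path Output SAM path.
#' @return The path, invisibly.
#' @export
writeSAM <- function(sim, ref, side = c("target", "spike"), path) {
    side <- match.arg(side)
    genome <- refGenome(ref, side)
    sl <- seqlengths(genome)
    gr <- c(sim[[side]],
            sim[[if (side == "target") "ambiguousTarget"
                 else "ambiguousSpike"]])
    .atomic_write(path, function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines(.sam_header(sl), con)
        if (!length(gr)) return(invisible())
        chrom <- as.character(seqnames(gr))
        str <- as.character(strand(gr))
        if (sim$paired) {
            ## SAM SEQ is reference-forward for a perfect match, so both
            ## mates carry plain forward substrings; only flags differ.
            rl <- pmin(sim$readLength, width(gr))
            s1 <- ifelse(str == "-", end(gr) - rl + 1L, start(gr))
            s2 <- ifelse(str == "-", start(gr), end(gr) - rl + 1L)
            seq1 <- .extract_seq(genome, chrom, s1, s1 + rl - 1L, "+")
            seq2 <- .extract_seq(genome, chrom, s2, s2 + rl - 1L, "+")
            ## R1 carries the fragment strand, R2 the opposite
            f1 <- ifelse(str == "-", 83L, 99L)
            f2 <- ifelse(str == "-", 163L, 147L)
            tl <- width(gr)
            qual <- strrep("I", rl)
            lines <- c(
                paste(names(gr), f1, chrom, s1, 60L, paste0(rl, "M"), "=",
                      s2, ifelse(str == "-", -tl, tl), seq1, qual,
                      sep = "\t"),
                paste(names(gr), f2, chrom, s2, 60L, paste0(rl, "M"), "=",
                      s1, ifelse(str == "-", tl, -tl), seq2, qual,
                      sep = "\t"))
        } else {
            flag <- ifelse(str == "-", 16L, 0L)
            seqs <- .extract_seq(genome, chrom, start(gr), end(gr), "+")
            qual <- strrep("I", width(gr))
            lines <- paste(names(gr), flag, chrom, start(gr), 60L,
                           paste0(width(gr), "M"), "*", 0L, 0L, seqs, qual,
                           sep = "\t")
        }
        writeLines(lines, con)
    })
}

#' Write simulated reads as FASTQ
#'
#' Single-end libraries produce one file; paired libraries produce
#' `<prefix>_1.fastq` and `<prefix>_2.fastq`.  Base qualities are uniform
#' (Phred 40): the generator does not model base-call errors.
#'
#' @param sim A `SimReads` object.
#' @param ref The [ToyReference-class].
#' @param prefix Output path prefix (single-end: `<prefix>.fastq`).
#' @return Character vector of the written paths, invisibly.
#' @export
writeFASTQ <- function(sim, ref, prefix) {
    grs <- list(target = c(sim$target, sim$ambiguousTarget))
    genome <- refGenome(ref, "target")
    ## spike reads are sequenced from the spike genome
    sgr <- sim$spike
    sgenome <- refGenome(ref, "spike")
    fq_block <- function(ids, seqs)
        as.vector(rbind(paste0("@", ids), seqs, "+",
                        strrep("I", nchar(seqs))))
    get_seqs <- function(gr, genome, mate = 0L) {
        if (!length(gr)) return(character())
        chrom <- as.character(seqnames(gr))
        str <- as.character(strand(gr))
        if (mate == 0L)
            return(.extract_seq(genome, chrom, start(gr), end(gr), str))
        rl <- pmin(sim$readLength, width(gr))
        if (mate == 1L) {
            s <- ifelse(str == "-", end(gr) - rl + 1L, start(gr))
            .extract_seq(genome, chrom, s, s + rl - 1L, str)
        } else {
            s <- ifelse(str == "-", start(gr), end(gr) - rl + 1L)
            .extract_seq(genome, chrom, s, s + rl - 1L,
                         ifelse(str == "-", "+", "-"))
        }
    }
    if (sim$paired) {
        paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
        ids <- c(names(grs$target), names(sgr))
        for (m in 1:2) {
            seqs <- c(get_seqs(grs$target, genome, m),
                      get_seqs(sgr, sgenome, m))
            .atomic_write(paths[m], function(tmp)
                writeLines(fq_block(ids, seqs), tmp))
        }
    } else {
        paths <- paste0(prefix, ".fastq")
        ids <- c(names(grs$target), names(sgr))
        seqs <- c(get_seqs(grs$target, genome),
                  get_seqs(sgr, sgenome))
        .atomic_write(paths, function(tmp)
            writeLines(fq_block(ids, seqs), tmp))
    }
    invisible(paths)
}

#' Write a feature annotation as GFF3
#'
#' @param anno A GRanges with `feature_id` and `biotype` metadata columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeAnnotationGFF3 <- function(anno, path) {
    gr <- anno
    gr$type <- gr$biotype
    gr$ID <- gr$feature_id
    gr$source <- "hetcal"
    .atomic_write(path, function(tmp)
        export(gr, tmp, format = "gff3"))
}

#' Read a feature annotation from GFF3
#'
#' @param path GFF3 path.
#' @param seqlens Optional named chromosome lengths to attach.
#' @return A GRanges with `feature_id` and `biotype` columns.
#' @export
readAnnotationGFF3 <- function(path, seqlens = NULL) {
    gr <- import(path, format = "gff3")
    out <- GRanges(seqnames(gr), ranges(gr), strand = strand(gr))
    out$feature_id <- gr$feature_id
    out$biotype <- gr$biotype
    if (!is.null(seqlens)) {
        seqlevels(out) <- names(seqlens)
        seqlengths(out) <- seqlens
    }
    out
}

#' Write a complete simulated fixture to disk
#'
#' Emits the two genomes (FASTA), their annotations (GFF3), the planted
#' truth (TSV with `#` parameter comments), per-sample ground-truth SAM
#' pairs and FASTQ reads, and a manifest TSV listing every sample.  Writes
#' are atomic (tempfile + rename), so re-running overwrites cleanly.
#'
#' @param ref A [ToyReference-class].
#' @param truth A [SimTruth-class].
#' @param sims List of `SimReads` objects (may be empty).
#' @param outdir Output directory, created if needed.
#' @return `outdir`, invisibly.
#' @export
writeFixture <- function(ref, truth, sims = list(), outdir) {
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
        stop("I/O error: cannot create ", outdir)
    .atomic_write(file.path(outdir, "target.fa"), function(tmp)
        writeXStringSet(genomeSeqs(refGenome(ref, "target")), tmp,
                        width = 70L))
    .atomic_write(file.path(outdir, "spike.fa"), function(tmp)
        writeXStringSet(genomeSeqs(refGenome(ref, "spike")), tmp,
                        width = 70L))
    writeAnnotationGFF3(refFeatures(ref, "target"),
                        file.path(outdir, "target.gff3"))
    writeAnnotationGFF3(refFeatures(ref, "spike"),
                        file.path(outdir, "spike.gff3"))

    .atomic_write(file.path(outdir, "truth.tsv"), function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        p <- truth@params
        writeLines(c(sprintf("# mixingRatio=%g", truth@mixingRatio),
                     sprintf("# seed=%d", truth@seed),
                     sprintf("# %s=%g", names(p), unlist(p))), con)
        df <- as.data.frame(truth@table)
        writeLines(paste(colnames(df), collapse = "\t"), con)
        write.table(df, con, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
    })

    rows <- list()
    repl <- integer()
    for (sim in sims) {
        key <- paste(sim$assay, sim$condition)
        if (is.na(repl[key])) repl[key] <- 1L
        st <- file.path(outdir, paste0(sim$sampleId, ".target.sam"))
        ss <- file.path(outdir, paste0(sim$sampleId, ".spike.sam"))
        writeSAM(sim, ref, "target", st)
        writeSAM(sim, ref, "spike", ss)
        fq <- writeFASTQ(sim, ref, file.path(outdir, sim$sampleId))
        rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sim$sampleId, assay = sim$assay,
            condition = sim$condition, replicate = repl[key],
            file_target = basename(st), file_spike = basename(ss),
            file_fastq = paste(basename(fq), collapse = ","),
            checksum = unname(md5sum(st)),
            stringsAsFactors = FALSE)
        repl[key] <- repl[key] + 1L
    }
    .atomic_write(file.path(outdir, "manifest.tsv"), function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines("# hetcal simulated fixture manifest", con)
        df <- if (length(rows)) do.call(rbind, rows) else
            data.frame(sample_id = character(), assay = character(),
                       condition = character(), replicate = integer(),
                       file_target = character(), file_spike = character(),
                       file_fastq = character(), checksum = character())
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    })
    invisible(outdir)
}
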