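## Reference construction: random genomes, non-overlapping feature placement,
## and a shared sequence cassette copied into both genomes so that a known
## subset of reads is genuinely ambiguous between species.

.rand_dna <- function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

## Place n features of given lengths on chromosomes, non-overlapping, with
## multinomially distributed gaps.  Returns a GRanges (no metadata).
.place_features <- function(lens, chrom_lens, label) {
    n <- length(lens)
    if (n == 0L)
        return(GRanges(seqlengths = chrom_lens))
    ## assign features to chromosomes proportionally to length, then lay out
    chrom <- sample(names(chrom_lens), n, replace = TRUE,
                    prob = chrom_lens / sum(chrom_lens))
    out <- vector("list", length(chrom_lens))
    for (k in seq_along(chrom_lens)) {
        cid <- names(chrom_lens)[k]
        idx <- which(chrom == cid)
        if (!length(idx)) { out[[k]] <- GRanges(); next }
        idx <- idx[sample.int(length(idx))]
        L <- chrom_lens[[k]]
        need <- sum(lens[idx])
        if (need >= L)
            stop("sizing error: ", label, " features (", need,
                 " bp) do not fit on ", cid, " (", L, " bp)")
        gaps <- as.vector(rmultinom(1L, L - need, rep(1, length(idx) + 1L)))
        starts <- cumsum(gaps[-length(gaps)] + c(0L, lens[idx[-length(idx)]])) + 1L
        out[[k]] <- GRanges(cid, IRanges(starts, width = lens[idx]),
                            strand = sample(c("+", "-"), length(idx),
                                            replace = TRUE))
        out[[k]]$ord <- idx
    }
    gr <- suppressWarnings(do.call(c, out[lengths(out) > 0]))
    gr <- gr[order(gr$ord)]
    gr$ord <- NULL
    seqlevels(gr) <- names(chrom_lens)
    seqlengths(gr) <- chrom_lens
    gr
}

.draw_lens <- function(n, range) {
    if (n == 0L) return(integer())
    as.integer(round(runif(n, range[1], range[2])))
}

#' Build a two-species toy reference
#'
#' Generates random target and spike genomes, places non-overlapping features
#' on both (target: mRNA, ncRNA and planted-CUT intervals; spike: mRNA,
#' ribosomal-protein-coding genes, plus ERCC-like transcripts each on its own
#' contig), and copies one shared sequence cassette into an intergenic region
#' of each genome so that reads drawn from it align to both species.
#' Deterministic for a fixed `(seed, cfg)`.
#'
#' @param seed Integer seed.
#' @param cfg A [simConfig()] object.
#' @return A [ToyReference-class] object.
#' @examples
#' ref <- buildToyReference(1, simConfig(targetSize = 2e4, spikeSize = 1.5e4,
#'                                       nMrna = 8, nNcrna = 2, nCut = 2,
#'                                       nSpikeMrna = 4))
#' refFeatures(ref, "target")
#' @export
buildToyReference <- function(seed, cfg = simConfig()) {
    validateSimConfig(cfg)
    seed <- as.integer(seed)
    set.seed(seed)

    chr_split <- function(total, n, prefix) {
        base <- rep(total %/% n, n)
        base[1] <- base[1] + total %% n
        setNames(base, paste0(prefix, seq_len(n)))
    }
    tgt_lens <- chr_split(cfg$targetSize, cfg$targetChroms, "tchr")
    spk_lens <- chr_split(cfg$spikeSize, cfg$spikeChroms, "schr")
    ercc_lens <- setNames(.draw_lens(cfg$nErcc, cfg$erccLenRange),
                          sprintf("ERCC-%04d", seq_len(cfg$nErcc)))

    ## --- target side: cassette placed as an extra pseudo-feature ----------
    t_lens <- c(.draw_lens(cfg$nMrna, cfg$mrnaLenRange),
                .draw_lens(cfg$nNcrna, cfg$ncrnaLenRange),
                .draw_lens(cfg$nCut, cfg$cutLenRange),
                cfg$cassetteLength)
    t_bio <- c(rep("mRNA", cfg$nMrna), rep("ncRNA", cfg$nNcrna),
               rep("planted_CUT", cfg$nCut), "cassette")
    t_gr <- .place_features(t_lens, tgt_lens, "target")
    t_cass <- t_gr[t_bio == "cassette"]
    strand(t_cass) <- "+"
    t_feat <- t_gr[t_bio != "cassette"]
    t_feat$feature_id <- sprintf("%s_%03d",
        c(rep("gene", cfg$nMrna), rep("ncrna", cfg$nNcrna),
          rep("cut", cfg$nCut)),
        c(seq_len(cfg$nMrna), seq_len(cfg$nNcrna), seq_len(cfg$nCut)))
    t_feat$biotype <- t_bio[t_bio != "cassette"]

    ## --- spike side -------------------------------------------------------
    s_lens <- c(.draw_lens(cfg$nSpikeMrna, cfg$mrnaLenRange),
                .draw_lens(cfg$nRpSpike, cfg$rpLenRange),
                cfg$cassetteLength)
    s_bio <- c(rep("mRNA", cfg$nSpikeMrna), rep("spike_rp_gene", cfg$nRpSpike),
               "cassette")
    s_gr <- .place_features(s_lens, spk_lens, "spike")
    s_cass <- s_gr[s_bio == "cassette"]
    strand(s_cass) <- "+"
    s_feat <- s_gr[s_bio != "cassette"]
    s_feat$feature_id <- sprintf("%s_%03d",
        c(rep("sgene", cfg$nSpikeMrna), rep("rp", cfg$nRpSpike)),
        c(seq_len(cfg$nSpikeMrna), seq_len(cfg$nRpSpike)))
    s_feat$biotype <- s_bio[s_bio != "cassette"]

    ## ERCC transcripts: one per contig, full length, + strand
    e_feat <- GRanges(names(ercc_lens), IRanges(1L, width = ercc_lens),
                      strand = "+",
                      feature_id = paste0(names(ercc_lens), "_tx"),
                      biotype = "ercc")
    all_spk_lens <- c(spk_lens, ercc_lens)
    seqlevels(s_feat) <- names(all_spk_lens)
    seqlengths(s_feat) <- all_spk_lens
    seqlevels(e_feat) <- names(all_spk_lens)
    seqlengths(e_feat) <- all_spk_lens
    s_feat <- sort(c(s_feat, e_feat))
    t_feat <- sort(t_feat)

    ## --- sequences, with the cassette spliced into both genomes ----------
    cassette_seq <- .rand_dna(cfg$cassetteLength)
    t_seqs <- DNAStringSet(vapply(tgt_lens, .rand_dna, character(1)))
    s_seqs <- DNAStringSet(c(vapply(spk_lens, .rand_dna, character(1)),
                             vapply(ercc_lens, .rand_dna, character(1))))
    subseq(t_seqs[[as.character(seqnames(t_cass))]],
           start(t_cass), end(t_cass)) <- DNAStringSet(cassette_seq)[[1]]
    subseq(s_seqs[[as.character(seqnames(s_cass))]],
           start(s_cass), end(s_cass)) <- DNAStringSet(cassette_seq)[[1]]

    seqlevels(t_cass) <- names(tgt_lens)
    seqlengths(t_cass) <- tgt_lens
    seqlevels(s_cass) <- names(all_spk_lens)
    seqlengths(s_cass) <- all_spk_lens

    new("ToyReference",
        genomes = list(
            target = new("ToyGenome", species = "target", seqs = t_seqs),
            spike  = new("ToyGenome", species = "spike",  seqs = s_seqs)),
        annotations = list(target = t_feat, spike = s_feat),
        cassette = list(target = t_cass, spike = s_cass),
        config = unclass(cfg), seed = seed)
}
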