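test_that("reference building respects bounds, counts and determinism", {
    cfg <- simConfig(targetSize = 10000L, targetChroms = 1L,
                     spikeSize = 5000L, nMrna = 5L, nNcrna = 0L, nCut = 0L,
                     nSpikeMrna = 2L, nRpSpike = 2L, nErcc = 2L,
                     mrnaLenRange = c(300L, 600L))
    ref <- buildToyReference(1, cfg)
    tgt <- refFeatures(ref, "target")
    expect_length(tgt, 5L)
    expect_true(all(tgt$biotype == "mRNA"))
    sl <- seqlengths(refGenome(ref, "target"))
    expect_true(all(start(tgt) >= 1L &
                    end(tgt) <= sl[as.character(seqnames(tgt))]))

    ## byte-identical rerun
    ref2 <- buildToyReference(1, cfg)
    f1 <- tempfile(); f2 <- tempfile()
    Biostrings::writeXStringSet(genomeSeqs(refGenome(ref, "target")), f1)
    Biostrings::writeXStringSet(genomeSeqs(refGenome(ref2, "target")), f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))

    ## different seed: different sequence, same feature counts
    ref3 <- buildToyReference(2, cfg)
    expect_false(identical(as.character(genomeSeqs(refGenome(ref, "target"))),
                           as.character(genomeSeqs(refGenome(ref3,
                                                             "target")))))
    expect_identical(table(refFeatures(ref, "target")$biotype),
                     table(refFeatures(ref3, "target")$biotype))

    ## spike-only biotypes stay on the spike side; rp/ercc present
    spk <- refFeatures(ref, "spike")
    expect_true(sum(spk$biotype == "spike_rp_gene") >= 1L)
    expect_true(sum(spk$biotype == "ercc") >= 1L)

    ## features non-overlapping per strand
    for (s in c("+", "-")) {
        gr <- tgt[strand(tgt) == s]
        if (length(gr) > 1)
            expect_true(isDisjoint(gr))
    }

    ## sizing error when features cannot fit
    expect_error(simConfig(targetSize = 3000L, nMrna = 50L,
                           spikeSize = 5000L), "sizing")
})

test_that("effect planting matches requested fractions and null case", {
    ref <- tinyRef(1)
    ## 0% affected: all effects exactly 1
    t0 <- plantEffects(ref, 5, tsaDownFrac = 0, tsaUpFrac = 0,
                       rrp6Fold = 3)
    tab <- truthTable(t0)
    expect_true(all(tab$tsa_effect == 1))
    expect_true(all(tab$acetyl_effect == 1))

    ## 10% up at 4-fold: the count is round(0.10 * N) among target mRNAs
    t1 <- plantEffects(ref, 5, tsaDownFrac = 0, tsaUpFrac = 0.10,
                       tsaUpFold = 4)
    tab1 <- truthTable(t1)
    nm <- sum(tab1$species == "target" & tab1$biotype == "mRNA")
    expect_identical(sum(tab1$tsa_effect == 4), as.integer(round(0.10 * nm)))

    ## planted CUTs always get a rrp6 effect above the 2-fold threshold
    expect_true(all(tab1$rrp6_effect[tab1$biotype == "planted_CUT"] > 2))

    ## impossible fractions refuse
    expect_error(plantEffects(ref, 5, tsaDownFrac = 0.8, tsaUpFrac = 0.5),
                 "config error")
})

test_that("simulated libraries conserve reads and obey assay semantics", {
    ref <- tinyRef(1)
    truth <- plantEffects(ref, 2)

    ## depth 0: empty everything
    s0 <- simulateAssay(ref, truth, "rnaseq", "untreated", depth = 0,
                        seed = 3)
    expect_length(s0$target, 0L)
    expect_length(s0$spike, 0L)
    p <- tempfile(fileext = ".sam")
    writeSAM(s0, ref, "target", p)
    expect_true(all(startsWith(readLines(p), "@")))

    ## conservation: emitted = target + spike + ambiguous exactly
    s1 <- simulateAssay(ref, truth, "netseq", "untreated", depth = 5000,
                        seed = 4)
    expect_identical(length(s1$target) + length(s1$spike) +
                     length(s1$ambiguousTarget), 5000L)
    expect_identical(names(s1$ambiguousTarget), names(s1$ambiguousSpike))

    ## NET-seq 3' ends lie inside the source feature, including on -
    anno <- refFeatures(ref, "target")
    pol2 <- s1$target$pol2
    hit <- anno[match(s1$target$feature_id, anno$feature_id)]
    expect_true(all(pol2 >= start(hit) & pol2 <= end(hit)))
    neg <- as.character(strand(hit)) == "-"
    expect_true(any(neg))
    expect_identical(start(s1$target)[neg], pol2[neg])
    expect_identical(end(s1$target)[!neg], pol2[!neg])

    ## unknown assay/condition refuse
    expect_error(simulateAssay(ref, truth, "hic", "untreated", seed = 1),
                 "usage error")
    expect_error(simulateAssay(ref, truth, "rnaseq", "frozen", seed = 1),
                 "usage error")
})

test_that("observed target:spike ratio stays within binomial error", {
    ref <- tinyRef(1)
    truth <- plantEffects(ref, 2, tsaDownFrac = 0, tsaUpFrac = 0)
    depth <- 50000L
    s <- simulateAssay(ref, truth, "netseq", "untreated", depth = depth,
                       seed = 9)
    r0 <- mixingRatio(truth)
    q0 <- 1 / (1 + r0)          # expected spike fraction of unambiguous
    n <- length(s$target) + length(s$spike)
    qhat <- length(s$spike) / n
    expect_lt(abs(qhat - q0), 3 * sqrt(q0 * (1 - q0) / n))
})

test_that("fixtures round-trip through disk and differ only by checksum", {
    cfg <- tinyConfig()
    ref <- buildToyReference(3, cfg)
    truth <- plantEffects(ref, 4)
    sims <- list(
        simulateAssay(ref, truth, "netseq", "untreated", depth = 500,
                      seed = 5, sampleId = "net_unt_1"),
        simulateAssay(ref, truth, "rnaseq", "tsa", depth = 500,
                      seed = 6, sampleId = "rna_tsa_1"))
    d1 <- file.path(tempdir(), "fix1")
    writeFixture(ref, truth, sims, d1)
    man <- read.table(file.path(d1, "manifest.tsv"), header = TRUE,
                      sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    expect_setequal(man$sample_id, c("net_unt_1", "rna_tsa_1"))
    expect_setequal(man$assay, c("netseq", "rnaseq"))
    expect_true(all(c("condition", "replicate", "checksum") %in%
                    colnames(man)))

    ## reloaded annotation identical to the in-memory one
    sl <- seqlengths(refGenome(ref, "target"))
    back <- readAnnotationGFF3(file.path(d1, "target.gff3"), sl)
    orig <- refFeatures(ref, "target")
    expect_identical(start(back), start(orig))
    expect_identical(end(back), end(orig))
    expect_identical(as.character(strand(back)), as.character(strand(orig)))
    expect_identical(back$feature_id, orig$feature_id)
    expect_identical(back$biotype, orig$biotype)

    ## same reference, different library seeds: manifests differ only in
    ## the checksum column
    sims2 <- list(
        simulateAssay(ref, truth, "netseq", "untreated", depth = 500,
                      seed = 50, sampleId = "net_unt_1"),
        simulateAssay(ref, truth, "rnaseq", "tsa", depth = 500,
                      seed = 60, sampleId = "rna_tsa_1"))
    d2 <- file.path(tempdir(), "fix2")
    writeFixture(ref, truth, sims2, d2)
    man2 <- read.table(file.path(d2, "manifest.tsv"), header = TRUE,
                       sep = "\t", comment.char = "#",
                       stringsAsFactors = FALSE)
    same <- setdiff(colnames(man), "checksum")
    expect_identical(man[same], man2[same])
    expect_false(any(man$checksum == man2$checksum))
})

test_that("count model hits requested means and dispersion", {
    ref <- tinyRef(1)
    truth <- plantEffects(ref, 2, tsaDownFrac = 0, tsaUpFrac = 0)
    tab <- truthTable(truth)
    depth <- 20000L
    reps <- vapply(1:40, function(i)
        drawFeatureCounts(truth, "rnaseq", "untreated", depth,
                          seed = 100 + i)$counts,
        numeric(nrow(tab)))
    m <- rowMeans(reps)
    ## relative expected mass
    p <- truth@params
    mass <- tab$base_rate * tab$length
    sg <- tab$species == "spike" & tab$biotype != "ercc"
    mass[sg] <- mass[sg] * p$spikeScale
    mass[tab$biotype == "ercc"] <- mass[tab$biotype == "ercc"] * p$erccScale
    expe <- depth * (1 - p$ambiguousFraction) * mass / sum(mass)
    big <- expe > 50
    expect_gt(cor(m[big], expe[big]), 0.99)
    ## per-feature variance implies dispersion near the configured value
    v <- apply(reps, 1, var)
    alpha <- (v - m) / m^2
    expect_lt(abs(median(alpha[big]) - p$dispersion), 0.04)
})
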