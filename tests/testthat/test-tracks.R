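test_that("coverage tracks conserve mass and scale with the factor", {
    sl <- c(c1 = 100L)
    ## no fragments: an all-zero track
    t0 <- makeCoverage(fragGR("c1", integer(), integer(), seqlens = sl),
                       seqlens = sl)
    expect_identical(trackMass(t0), 0)

    ## one fragment of ten bases at factor 1: ten bases of value 1
    fr <- fragGR("c1", 10, 19, "+", seqlens = sl)
    t1 <- makeCoverage(fr)
    v <- as.numeric(trackCov(t1)[["c1"]])
    expect_identical(v[10:19], rep(1, 10))
    expect_identical(sum(v), 10)

    ## factor 2 halves every value
    t2 <- makeCoverage(fr, sizeFactor = 2)
    expect_equal(as.numeric(trackCov(t2)[["c1"]]), v / 2)

    ## mass conservation: sum(coverage) * factor = total fragment-bp
    set.seed(1)
    st <- sample(1:60, 20, TRUE)
    frs <- fragGR("c1", st, st + sample(5:30, 20, TRUE), "+", seqlens = sl)
    tr <- makeCoverage(frs, sizeFactor = 1)
    expect_equal(trackMass(tr), sum(width(frs)))

    ## position mode: mass equals total weight / factor
    p2 <- trimToPol2(frs)
    tp <- makeCoverage(p2, sizeFactor = 2, mode = "position")
    expect_equal(trackMass(tp) * 2, sum(p2$weight))

    ## out-of-range fragments refuse
    expect_error(
        makeCoverage(suppressWarnings(GRanges("c1", IRanges(95, 120),
                                              seqlengths = sl))),
        "coordinate error")
})

test_that("metagene anchors at the TSS and is orientation-invariant", {
    sl <- c(c1 = 3000L)
    ## delta signal exactly at the TSS of a + gene
    tss <- 1000L
    sig <- fragGR("c1", tss, tss, "+", seqlens = sl)
    track <- makeCoverage(sig)
    gene <- GRanges("c1", IRanges(tss, tss + 499L), strand = "+")
    mg <- metagene(track, gene)
    expect_identical(profileOffsets(mg)[which.max(profileMean(mg))], 0L)

    ## the same gene mirrored onto the minus strand: identical profile
    L <- 3000L
    sigm <- fragGR("c1", L - tss + 1L, L - tss + 1L, "-", seqlens = sl)
    genem <- GRanges("c1", IRanges(L - tss - 499L, L - tss + 1L),
                     strand = "-")
    mgm <- metagene(makeCoverage(sigm), genem)
    expect_equal(profileMean(mgm), profileMean(mg))

    ## strand-randomized feature set gives the same profile as the
    ## original when the signal is mirrored with it
    set.seed(3)
    starts <- seq(300L, 2400L, by = 300L)
    genes <- GRanges("c1", IRanges(starts, width = 200L), strand = "+")
    sigs <- fragGR("c1", starts + 10L, starts + 29L, "+", seqlens = sl)
    base <- metagene(makeCoverage(sigs), genes)
    flip <- sample(c(TRUE, FALSE), length(genes), TRUE)
    genes2 <- genes
    strand(genes2)[flip] <- "-"
    ## mirror the signal for flipped genes: 3' anchored 20-mer
    s2 <- ifelse(flip, end(genes) - 29L, starts + 10L)
    sigs2 <- fragGR("c1", s2, s2 + 19L,
                    ifelse(flip, "-", "+"), seqlens = sl)
    both <- metagene(makeCoverage(sigs2), genes2)
    expect_equal(profileMean(both), profileMean(base))

    ## windows overrunning the chromosome are dropped and counted
    edge <- GRanges("c1", IRanges(c(10L, 1000L), width = 100L),
                    strand = "+")
    mge <- metagene(makeCoverage(sigs), edge)
    expect_identical(mge@nDropped, 1L)
    expect_identical(mge@n, 1L)

    expect_error(metagene(track, GRanges()), "usage error")
})

test_that("replicate correlation is a proper Spearman matrix", {
    sl <- c(c1 = 5000L)
    set.seed(7)
    mk <- function(seed) {
        set.seed(seed)
        st <- sample(1:4900, 200, TRUE)
        makeCoverage(fragGR("c1", st, st + 49L, "+", seqlens = sl))
    }
    a <- mk(1); b <- mk(2)
    cm <- replicateCorrelation(list(a = a, b = b), binSize = 50)
    expect_identical(dim(cm), c(2L, 2L))
    expect_identical(diag(cm), c(a = 1, b = 1))
    expect_true(all(cm >= -1 & cm <= 1))
    expect_equal(cm[1, 2], cm[2, 1])

    ## a sample against its elementwise square (positive values): rank
    ## invariance gives rho = 1 on the per-base grid
    sq <- a
    sq@cov <- a@cov * a@cov
    cm2 <- replicateCorrelation(list(a = a, sq = sq), binSize = 1)
    expect_equal(cm2[1, 2], 1)

    ## two independent noise tracks over many bins: |rho| small
    big <- c(c1 = 50000L)
    mkbig <- function(seed) {
        set.seed(seed)
        st <- sample(1:49000, 3000, TRUE)
        makeCoverage(fragGR("c1", st, st + 30L, "+", seqlens = big))
    }
    cm3 <- replicateCorrelation(list(x = mkbig(11), y = mkbig(22)),
                                binSize = 50)
    expect_lt(abs(cm3[1, 2]), 0.1)

    ## constant sample flagged, not NaN-propagated
    z <- makeCoverage(fragGR("c1", integer(), integer(), seqlens = sl),
                      seqlens = sl)
    expect_warning(cm4 <- replicateCorrelation(list(a = a, z = z),
                                               binSize = 50),
                   "constant")
    expect_true(is.na(cm4[1, 2]))
    expect_identical(diag(cm4), c(a = 1, z = 1))
})

test_that("bedGraph round-trips step tracks and merges equal runs", {
    sl <- c(c1 = 400L, c2 = 150L)
    set.seed(9)
    st <- sample(1:350, 25, TRUE)
    gr <- fragGR(sample(c("c1", "c2"), 25, TRUE), pmin(st, 120),
                 pmin(st, 120) + sample(3:20, 25, TRUE), "+", seqlens = sl)
    tr <- makeCoverage(gr)
    p <- tempfile(fileext = ".bedGraph")
    writeBedGraph(tr, p)
    back <- readBedGraph(p, sl)
    expect_equal(lapply(trackCov(tr), as.numeric),
                 lapply(trackCov(back), as.numeric))

    ## run-length oracle: one bedGraph line per nonzero run
    nruns <- sum(vapply(trackCov(tr), function(r)
        sum(runValue(r) != 0), integer(1)))
    lines <- readLines(p)
    lines <- lines[!grepl("^track|^#", lines)]
    expect_identical(length(lines), nruns)
    ## intervals are 0-based half-open with the right span
    f <- read.table(text = lines, sep = "\t")
    expect_identical(sum(f$V3 - f$V2), sum(vapply(trackCov(tr), function(r)
        sum(runLength(r)[runValue(r) != 0]), integer(1))))

    ## empty track: header-only file
    t0 <- makeCoverage(fragGR("c1", integer(), integer(), seqlens = sl),
                       seqlens = sl)
    p0 <- tempfile(fileext = ".bedGraph")
    writeBedGraph(t0, p0)
    expect_true(all(grepl("^track", readLines(p0))))

    ## overlapping intervals on read: format error
    pbad <- tempfile(fileext = ".bedGraph")
    writeLines(c("c1\t0\t10\t1", "c1\t5\t15\t2"), pbad)
    expect_error(readBedGraph(pbad, sl), "format error")
})
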