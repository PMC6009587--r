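test_that("quality filter drops short and low-quality reads as configured", {
    ## a 19-nt read at Q40 is a length drop, never a quality drop
    fq <- tempfile(fileext = ".fastq")
    writeTestFastq(fq, c(strrep("A", 19), strrep("C", 30)), c("I", "I"))
    r <- qualityFilter(fq)
    expect_identical(r$dropped_length, 1L)
    expect_identical(r$dropped_quality, 0L)
    expect_identical(r$kept, 1L)

    ## empty input: all counters zero
    fq0 <- tempfile(fileext = ".fastq")
    writeLines(character(), fq0)
    r0 <- qualityFilter(fq0)
    expect_identical(unlist(r0[c("kept", "dropped_quality",
                                 "dropped_length")]),
                     c(kept = 0L, dropped_quality = 0L,
                       dropped_length = 0L))

    ## 100 reads, 10 planted below Q20 ('#' is Phred 2): kept = 90
    fq1 <- tempfile(fileext = ".fastq")
    qc <- c(rep("#", 10), rep("I", 90))
    writeTestFastq(fq1, rep(strrep("G", 30), 100), qc)
    r1 <- qualityFilter(fq1)
    expect_identical(r1$kept, 90L)
    expect_identical(r1$dropped_quality, 10L)
    expect_identical(r1$kept + r1$dropped_quality + r1$dropped_length, 100L)

    ## idempotence: filtering the filtered output changes nothing
    out1 <- tempfile(fileext = ".fastq")
    qualityFilter(fq1, out1)
    r2 <- qualityFilter(out1)
    expect_identical(r2$kept, 90L)
    expect_identical(r2$dropped_quality + r2$dropped_length, 0L)

    ## malformed record reports a parse error with the record index
    bad <- tempfile(fileext = ".fastq")
    writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), bad)
    expect_error(qualityFilter(bad), "parse error.*record 2")
})

test_that("alignment loading keeps proper pairs / primary mapped records", {
    sl <- "@SQ\tSN:c1\tLN:1000"
    hd <- c("@HD\tVN:1.6\tSO:unknown", sl)
    rec <- function(id, flag, pos, mpos = 0, tlen = 0, rnext = "*")
        paste(id, flag, "c1", pos, 60, "10M", rnext, mpos, tlen,
              strrep("A", 10), strrep("I", 10), sep = "\t")

    ## header-only SAM: empty result
    p0 <- tempfile(fileext = ".sam")
    writeLines(hd, p0)
    expect_length(loadAlignments(p0, "paired"), 0L)
    expect_length(loadAlignments(p0, "single"), 0L)

    ## 10 proper pairs + 3 singletons: paired mode yields 10 fragments
    lines <- hd
    for (i in 1:10)
        lines <- c(lines,
                   rec(paste0("p", i), 99, i * 50, i * 50 + 40, 50, "="),
                   rec(paste0("p", i), 147, i * 50 + 40, i * 50, -50, "="))
    for (i in 1:3)
        lines <- c(lines, rec(paste0("s", i), 0, 600 + i * 20))
    p1 <- tempfile(fileext = ".sam")
    writeLines(lines, p1)
    frags <- loadAlignments(p1, "paired")
    expect_length(frags, 10L)
    expect_true(all(width(frags) == 50L))

    ## a pair with one unmapped mate is not properly paired: excluded
    lines2 <- c(hd,
                rec("q1", 73, 100),   # paired, mate unmapped, not proper
                rec("q1", 133, 100))  # the unmapped mate
    p2 <- tempfile(fileext = ".sam")
    writeLines(lines2, p2)
    expect_length(loadAlignments(p2, "paired"), 0L)

    ## headerless SAM is a format error
    p3 <- tempfile(fileext = ".sam")
    writeLines(rec("x", 0, 10), p3)
    expect_error(loadAlignments(p3, "single"), "format error")
})

test_that("disambiguation partitions reads exactly and symmetrically", {
    t <- fragGR("c1", c(10, 20, 30, 40, 50, 60, 70), c(15, 25, 35, 45, 55, 65, 75),
                ids = c(paste0("t", 1:5), "x1", "x2"))
    s <- fragGR("s1", c(10, 20, 30, 40, 50), c(15, 25, 35, 45, 55),
                ids = c(paste0("s", 1:3), "x1", "x2"))
    d <- disambiguate(t, s)
    expect_length(d$unique_target, 5L)
    expect_length(d$unique_spike, 3L)
    expect_setequal(d$ambiguous_ids, c("x1", "x2"))
    ## every input id in exactly one output
    expect_setequal(c(names(d$unique_target), names(d$unique_spike),
                      d$ambiguous_ids), union(names(t), names(s)))
    expect_length(intersect(names(d$unique_target),
                            names(d$unique_spike)), 0L)
    ## shared ids absent from both unique outputs
    expect_false(any(c("x1", "x2") %in%
                     c(names(d$unique_target), names(d$unique_spike))))

    ## symmetry: swapping inputs swaps outputs
    d2 <- disambiguate(s, t)
    expect_identical(names(d2$unique_target), names(d$unique_spike))
    expect_identical(names(d2$unique_spike), names(d$unique_target))
    expect_setequal(d2$ambiguous_ids, d$ambiguous_ids)

    ## disjoint id sets: identity
    d3 <- disambiguate(t[1:3], s[1:2])
    expect_length(d3$ambiguous_ids, 0L)
    expect_identical(names(d3$unique_target), names(t)[1:3])

    ## duplicate read ids are an input error
    tdup <- t
    names(tdup)[2] <- "t1"
    expect_error(disambiguate(tdup, s), "input error")
})

test_that("species assignment on the fixture has zero misassignments", {
    ref <- tinyRef(1)
    truth <- plantEffects(ref, 2)
    sim <- simulateAssay(ref, truth, "netseq", "untreated", depth = 4000,
                         seed = 7, sampleId = "n1")
    d <- tempdir()
    writeSAM(sim, ref, "target", file.path(d, "zt.sam"))
    writeSAM(sim, ref, "spike", file.path(d, "zs.sam"))
    dd <- disambiguate(loadAlignments(file.path(d, "zt.sam"), "single"),
                       loadAlignments(file.path(d, "zs.sam"), "single"))
    expect_setequal(names(dd$unique_target), names(sim$target))
    expect_setequal(names(dd$unique_spike), names(sim$spike))
    expect_setequal(dd$ambiguous_ids, names(sim$ambiguousTarget))
})

test_that("Pol II trimming takes the strand-correct 3' base and conserves mass", {
    sl <- c(chrA = 500L)
    ## plus-strand fragment 101..150 -> Pol II at 150; minus -> 101
    fp <- fragGR("chrA", 101, 150, "+", seqlens = sl)
    fm <- fragGR("chrA", 101, 150, "-", seqlens = sl)
    expect_identical(start(trimToPol2(fp)), 150L)
    expect_identical(start(trimToPol2(fm)), 101L)

    ## conservation on a simulated batch
    ref <- tinyRef(1)
    truth <- plantEffects(ref, 2)
    sim <- simulateAssay(ref, truth, "netseq", "untreated", depth = 1000,
                         seed = 8)
    p2 <- trimToPol2(sim$target)
    expect_identical(sum(p2$weight), length(sim$target))
    ## positions equal the recorded Pol II truth
    truthPos <- GRanges(seqnames(sim$target),
                        IRanges(sim$target$pol2, width = 1L),
                        strand = strand(sim$target))
    agg <- unique(truthPos)
    agg$weight <- countOverlaps(agg, truthPos, type = "equal")
    asdf <- function(gr)
        data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   strand = as.character(strand(gr)),
                   weight = unname(gr$weight))
    o <- order(asdf(p2)$chrom, asdf(p2)$strand, start(p2))
    o2 <- order(asdf(agg)$chrom, asdf(agg)$strand, start(agg))
    expect_identical(asdf(p2)[o, ], asdf(agg)[o2, ],
                     ignore_attr = TRUE)

    ## off-chromosome fragments are a coordinate error
    bad <- suppressWarnings(GRanges("chrA", IRanges(490, 520),
                                    strand = "+", seqlengths = sl))
    expect_error(trimToPol2(bad), "coordinate error")

    ## mirror property: strand-flip commutes with trimming
    L <- 500L
    flip <- function(gr) {
        out <- fragGR("chrA", L - end(gr) + 1L, L - start(gr) + 1L,
                      ifelse(as.character(strand(gr)) == "+", "-", "+"),
                      ids = names(gr), seqlens = sl)
        out
    }
    set.seed(42)
    st <- sample(50:400, 30)
    gr <- fragGR("chrA", st, st + sample(20:40, 30, TRUE),
                 sample(c("+", "-"), 30, TRUE), seqlens = sl)
    a <- trimToPol2(flip(gr))
    b <- flip(trimToPol2(gr))
    expect_identical(sort(unname(granges(a))), sort(unname(granges(b))))
})
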