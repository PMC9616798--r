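test_that("binned correlation: self r=1, scale invariance, anti-correlation", {
    map <- toy_map(integer(0), 1000L)
    gr1 <- GRanges("chr1", IRanges(c(1, 5, 600), width = 10))
    r <- binnedCorrelation(list(a = gr1, b = gr1), map, binSize = 500L, ext = 150L)
    expect_equal(r["a", "b"], 1.0)
    expect_equal(diag(r), c(a = 1, b = 1))

    # doubling all reads leaves r at 1
    gr2 <- c(gr1, gr1)
    r <- binnedCorrelation(list(a = gr1, b = gr2), map, binSize = 500L)
    expect_equal(r["a", "b"], 1.0)

    # coverages (1,3) vs (3,1) over two bins -> r = -1 (ext kept inside bins)
    a <- GRanges("chr1", IRanges(c(1, 501, 521, 541), width = 10))
    b <- GRanges("chr1", IRanges(c(1, 21, 41, 501), width = 10))
    r <- binnedCorrelation(list(a = a, b = b), map, binSize = 500L, ext = 10L)
    expect_equal(r["a", "b"], -1.0)
    expect_true(all(abs(r) <= 1 + 1e-12))
    expect_equal(r, t(r))
    expect_error(binnedCorrelation(list(a = gr1), map), "two samples")
})

test_that("read extension is strand-aware from the 5' end", {
    map <- toy_map(integer(0), 1000L)
    # - strand read with 5' end at 509 extends left across the bin boundary
    plus <- GRanges("chr1", IRanges(496, 505), strand = "+")
    minus <- GRanges("chr1", IRanges(500, 509), strand = "-")
    r <- binnedCorrelation(list(p = plus, m = minus, p2 = plus), map,
                           binSize = 500L, ext = 20L)
    # + read covers [495,515): 5 bp in bin1, 15 in bin2; - read covers
    # [489,509): 11 bp in bin1, 9 in bin2 -> different bin profiles
    expect_equal(r["p", "p2"], 1.0)
    expect_false(isTRUE(all.equal(r["p", "m"], 1.0)))
})

test_that("ROC-like recovery handles identity, disjoint and partial overlap", {
    ref <- toy_peakset("chr1", c(0L, 200L), c(100L, 300L), fdr = c(1e-40, 1e-30))
    # identical query recovers everything
    rc <- rocLikeRecovery(ref, ref)
    expect_equal(rc$y[length(rc$y)], 1.0)
    # disjoint query recovers nothing
    far <- toy_peakset("chr1", c(1000L, 2000L), c(1100L, 2100L),
                       fdr = c(1e-40, 1e-30))
    rc <- rocLikeRecovery(ref, far)
    expect_equal(rc$y, c(0, 0)); expect_equal(rc$area, 0)
    # two query peaks, the better-scored one hits 1 of 2 references
    q <- toy_peakset("chr1", c(0L, 5000L), c(50L, 5100L), fdr = c(1e-50, 1e-10))
    rc <- rocLikeRecovery(ref, q)
    expect_equal(rc$y, c(0.5, 0.5)); expect_equal(rc$area, 0.5)
    # curves are monotone; reference subset of query ends at 1
    rc <- rocLikeRecovery(ref, toy_peakset("chr1", c(0L, 200L, 900L),
                                           c(100L, 300L, 950L),
                                           fdr = c(1e-20, 1e-45, 1e-33)))
    expect_true(all(diff(rc$y) >= 0))
    expect_equal(rc$y[3], 1.0)
    expect_gte(rc$area, 0); expect_lte(rc$area, 1)
    expect_error(rocLikeRecovery(ref, new("PeakSet", peaks = nanodam:::.emptyPeaks(),
                                          provenance = list())), "non-empty")
})

test_that("signal enrichment meta-profile reproduces planted plateaus", {
    map <- toy_map(seq(100L, 900L, by = 100L), 1000L)  # ten 100 bp fragments
    # constant profile -> flat meta-profile
    flat <- toy_profile(rep(3, 10))
    peaks <- toy_peakset("chr1", 300L, 500L)
    se <- signalEnrichment(flat, map, peaks, nPoints = 40L, flankFrac = 0.5)
    expect_equal(se$mean_signal, rep(3, 40L))
    # value 2 inside the peak, 0 outside, flank 0.5 -> 0 / 2 / 0 blocks
    prof <- toy_profile(c(0, 0, 0, 2, 2, 0, 0, 0, 0, 0))
    se <- signalEnrichment(prof, map, peaks, nPoints = 40L, flankFrac = 0.5)
    expect_equal(se$mean_signal[1:10], rep(0, 10))
    expect_equal(se$mean_signal[11:30], rep(2, 20))
    expect_equal(se$mean_signal[31:40], rep(0, 10))
    # single peak: meta-profile equals that peak's rescaled profile
    se2 <- signalEnrichment(prof, map, toy_peakset("chr1", 300L, 500L),
                            nPoints = 8L, flankFrac = 0.5)
    expect_equal(se2$mean_signal, c(0, 0, 2, 2, 2, 2, 0, 0))
    expect_error(signalEnrichment(prof, map,
        new("PeakSet", peaks = nanodam:::.emptyPeaks(), provenance = list())),
        "empty")
})

test_that("fingerprint curve: diagonal for uniform, step for concentrated", {
    uni <- toy_counts(rep(7L, 40L))
    fp <- fingerprintAndComplexity(uni)
    expect_lt(max(abs(fp$y - fp$q)), 1e-12)
    expect_equal(fp$y[length(fp$y)], 1.0)

    # all reads in one of B bins
    conc <- toy_counts(c(rep(0L, 9L), 100L))
    fp <- fingerprintAndComplexity(conc)
    expect_equal(fp$y, c(rep(0, 9), 1))
    # convexity for ascending-sorted bins
    set.seed(3)
    fp <- fingerprintAndComplexity(toy_counts(rpois(100, 5)))
    expect_true(all(diff(diff(fp$y)) >= -1e-12))
    expect_error(fingerprintAndComplexity(toy_counts(c(0L, 0L))), "zero")
})

test_that("unique-read fraction counts distinct 5' triples", {
    map <- toy_map(integer(0), 1000L)
    gr <- GRanges("chr1", IRanges(c(1, 1, 50, 50), width = 10),
                  strand = c("+", "+", "+", "-"))
    fp <- fingerprintAndComplexity(assignReadsToFragments(gr, map), alignments = gr)
    expect_equal(fp$unique_read_fraction, 3 / 4)
    # all distinct -> 1.0
    gr2 <- GRanges("chr1", IRanges(c(1, 20, 40), width = 10))
    fp <- fingerprintAndComplexity(assignReadsToFragments(gr2, map), alignments = gr2)
    expect_equal(fp$unique_read_fraction, 1.0)
})

test_that("within-condition correlation exceeds condition-vs-control", {
    ok <- 0L
    for (seed in 1:5) {
        spec <- simulationSpec(nChroms = 1L, chromLength = 3e4,
                               sitesPerArchetype = 3L,
                               fusionReplicates = c(D = 2L, Grh = 1L, Ey = 1L),
                               controlReplicates = 1L, depth = 30,
                               seed = 500L + seed)
        ex <- simulateExperiment(spec)
        v <- function(bc) fragmentCounts(bc)
        rWithin <- cor(v(ex$fusions$D[[1]]), v(ex$fusions$D[[2]]))
        rCross <- cor(v(ex$fusions$D[[1]]), v(ex$controls[[1]]))
        if (rWithin > rCross) ok <- ok + 1L
    }
    expect_gte(ok, 4L)
})
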