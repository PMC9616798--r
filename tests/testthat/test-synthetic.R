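test_that("fixed-spacing genomes give constant fragment lengths", {
    spec <- simulationSpec(nChroms = 1L, chromLength = 1000L,
                           gatcMode = "fixed", gatcSpacing = 200L,
                           sitesPerArchetype = 0L, seed = 1L)
    g <- simulateGenome(spec)
    expect_true(all(width(fragments(g$map)) == 200L))
    expect_equal(nFragments(g$map), 5L)
})

test_that("random genomes have ~256 bp mean fragments and are seed-stable", {
    spec <- simulationSpec(nChroms = 1L, chromLength = 1e6, # 4^-4 motif rate
                           sitesPerArchetype = 0L, seed = 42L)
    g <- simulateGenome(spec)
    mfl <- mean(width(fragments(g$map)))
    expect_gt(mfl, 256 * 0.9); expect_lt(mfl, 256 * 1.1)
    g2 <- simulateGenome(spec)
    expect_identical(as.character(g$genome), as.character(g2$genome))
})

test_that("planted sites are disjoint fragment runs with archetype labels", {
    spec <- simulationSpec(nChroms = 2L, chromLength = 5e4,
                           sitesPerArchetype = 4L, siteWidthFragments = 2L,
                           seed = 9L)
    g <- simulateGenome(spec)
    truth <- plantSites(spec, g$map)
    expect_equal(nrow(truth), 6L * 4L)
    expect_equal(truth$frag_last - truth$frag_first, rep(1L, 24L))
    # non-overlapping fragment runs
    occupied <- unlist(Map(seq, truth$frag_first, truth$frag_last))
    expect_false(any(duplicated(occupied)))
    # runs never straddle a chromosome boundary
    frag <- fragments(g$map)
    expect_equal(as.character(seqnames(frag))[truth$frag_first],
                 as.character(seqnames(frag))[truth$frag_last])
    expect_equal(sort(unique(truth$archetype)), sort(rownames(defaultArchetypes())))
    # zero sites -> empty truth
    spec0 <- simulationSpec(sitesPerArchetype = 0L, seed = 1L)
    g0 <- simulateGenome(spec0)
    expect_equal(nrow(plantSites(spec0, g0$map)), 0L)
    # infeasible placement errors out
    specBig <- simulationSpec(nChroms = 1L, chromLength = 2000L,
                              sitesPerArchetype = 50L, siteWidthFragments = 3L,
                              seed = 1L)
    gBig <- simulateGenome(specBig)
    expect_error(plantSites(specBig, gBig$map), "not enough|failed")
})

test_that("replicate structure and determinism of simulated counts", {
    spec <- simulationSpec(nChroms = 1L, chromLength = 2e4,
                           sitesPerArchetype = 1L, seed = 77L)
    ex <- simulateExperiment(spec)
    expect_length(ex$controls, 8L)
    expect_equal(vapply(ex$fusions, length, integer(1)), c(D = 4L, Grh = 5L, Ey = 4L))
    ex2 <- simulateExperiment(spec)
    expect_identical(fragmentCounts(ex$fusions$Grh[[3]]),
                     fragmentCounts(ex2$fusions$Grh[[3]]))
})

test_that("without enrichment, fusion and control counts share a distribution", {
    pvals <- vapply(1:10, function(seed) {
        spec <- simulationSpec(nChroms = 1L, chromLength = 5e4,
                               sitesPerArchetype = 0L,
                               fusionReplicates = c(D = 1L, Grh = 1L, Ey = 1L),
                               controlReplicates = 1L, seed = 900L + seed)
        ex <- simulateExperiment(spec)
        suppressWarnings(ks.test(fragmentCounts(ex$fusions$D[[1]]),
                                 fragmentCounts(ex$controls[[1]]))$p.value)
    }, numeric(1))
    expect_gt(min(pvals), 0.01)
})

test_that("large dispersion approaches the Poisson variance-mean identity", {
    # ~2000 fragments keep the var/mean estimator's sampling error ~0.03
    spec <- simulationSpec(nChroms = 1L, chromLength = 5e5,
                           sitesPerArchetype = 0L, accessibilitySd = 0,
                           dispersion = 1e6, depth = 50,
                           fusionReplicates = c(D = 1L, Grh = 1L, Ey = 1L),
                           controlReplicates = 1L, seed = 12L)
    ex <- simulateExperiment(spec)
    cnt <- fragmentCounts(ex$controls[[1]])
    expect_lt(abs(var(cnt) / mean(cnt) - 1), 0.05)
})

test_that("default archetypes encode the six qualitative binding patterns", {
    a <- defaultArchetypes()
    expect_equal(dim(a), c(6L, 3L))
    expect_equal(rownames(a), paste0("ND", 1:6))
    # strong-vs-baseline structure: D strong in ND1/2/4, Grh in ND2/3/4, Ey in ND4/5
    expect_equal(unname(a[, "D"] == 3), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
    expect_equal(unname(a[, "Grh"] == 3), c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE))
    expect_equal(unname(a[, "Ey"] == 3), c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("synthetic SAM output reproduces the original counts when re-read", {
    spec <- simulationSpec(nChroms = 1L, chromLength = 2e4,
                           sitesPerArchetype = 1L,
                           fusionReplicates = c(D = 1L, Grh = 1L, Ey = 1L),
                           controlReplicates = 1L, depth = 5, seed = 31L)
    ex <- simulateExperiment(spec)
    sam <- withr::local_tempfile(fileext = ".sam")
    writeSyntheticSAM(ex$fusions$D[[1]], ex$map, sam)
    bc <- assignReadsToFragments(sam, ex$map, minMapq = 0L)
    expect_equal(fragmentCounts(bc), fragmentCounts(ex$fusions$D[[1]]))
})

test_that("full pipeline on defaults recovers the planted archetypes", {
    aris <- vapply(1:3, function(seed) {
        spec <- simulationSpec(seed = 1000L + seed)   # study-design defaults
        ex <- simulateExperiment(spec)
        conds <- colnames(spec$archetypes)
        profiles <- list(); consensus <- list()
        for (cn in conds) {
            tracks <- quantileNormalizeTracks(
                allPairwiseRatios(ex$fusions[[cn]], ex$controls))
            profiles[[cn]] <- averageProfiles(tracks, cn)
            sets <- list()
            for (f in ex$fusions[[cn]]) for (g in ex$controls)
                sets[[length(sets) + 1L]] <- callPeaks(f, g, ex$map)
            consensus[[cn]] <- mergeConsensus(sets)
        }
        universe <- combinePeakSets(consensus)
        mat <- buildPeakIntensityMatrix(profiles, ex$map, universe)
        res <- selectKAndCluster(mat, kRange = 2:10, nInit = 25L, seed = 1L)
        # label each peak by the planted archetype it overlaps; a peak
        # spanning two adjacent sites of different archetypes has no
        # single true label and is excluded from the comparison
        gr <- peakRanges(universe)
        tr <- GRanges(ex$truth$chrom, IRanges(ex$truth$start + 1L, ex$truth$end))
        hits <- findOverlaps(gr, tr)
        lab <- rep(NA_character_, length(gr))
        lab[queryHits(hits)] <- ex$truth$archetype[subjectHits(hits)]
        nSites <- table(factor(queryHits(hits), levels = seq_along(gr)))
        keep <- !is.na(lab) & nSites == 1L
        mclust::adjustedRandIndex(clusterLabels(res)[keep], lab[keep])
    }, numeric(1))
    expect_gte(min(aris), 0.9)
})
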