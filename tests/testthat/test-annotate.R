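write_gtf <- function(path, rows) {
    # rows: data.frame(chrom, feature, start1, end1, strand, gene_id, biotype, extra)
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                     rows$gene_id, rows$gene_id, rows$biotype)
    writeLines(sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       rows$chrom, rows$feature, rows$start1, rows$end1,
                       rows$strand, attrs), path)
    path
}

test_that("gene models get strand-aware, 5'-most canonical TSSs", {
    gtf <- withr::local_tempfile(fileext = ".gtf")
    write_gtf(gtf, data.frame(
        chrom = "chr1",
        feature = c("gene", "gene", "gene", "transcript", "transcript"),
        start1 = c(101L, 101L, 301L, 101L, 151L),
        end1 = c(500L, 500L, 600L, 480L, 500L),
        strand = c("+", "-", "+", "+", "+"),
        gene_id = c("gPlus", "gMinus", "gTwoTx", "gTwoTx", "gTwoTx"),
        biotype = "protein_coding"))
    gm <- parseGeneModels(gtf)
    expect_equal(gm$tss[gm$gene_id == "gPlus"], 100L)
    expect_equal(gm$tss[gm$gene_id == "gMinus"], 499L)
    # canonical TSS = 5'-most across transcripts
    expect_equal(gm$tss[gm$gene_id == "gTwoTx"], 100L)
    expect_error(parseGeneModels(withr::local_tempfile(fileext = ".gtf",
        lines = "chr1\tt\texon\t1\t10\t.\t+\t.\tgene_id \"x\";")), "no gene")
})

test_that("nearest TSS uses boundary distance, zero inside, lexicographic ties", {
    genes <- data.frame(
        gene_id = c("gA", "gB", "gIn", "aTie", "bTie"),
        symbol = c("gA", "gB", "gIn", "aTie", "bTie"),
        chrom = "chr1", strand = "+",
        tss = c(90L, 250L, 150L, 80L, 219L),
        biotype = "protein_coding")
    # tss inside the peak
    hit <- nearestTSS(c("chr1", 100L, 200L), genes)
    expect_equal(hit$gene_id, "gIn"); expect_equal(hit$distance, 0L)
    # without the inside gene: 90 is 10 bp from start, 250 is 51 bp from end-1
    hit <- nearestTSS(c("chr1", 100L, 200L), genes[genes$gene_id %in% c("gA", "gB"), ])
    expect_equal(hit$gene_id, "gA"); expect_equal(hit$distance, 10L)
    # equidistant TSSs (80 vs start 100; 219 vs end-1 199) break to the
    # lexicographically smaller id
    hit <- nearestTSS(c("chr1", 100L, 200L),
                      genes[genes$gene_id %in% c("aTie", "bTie"), ])
    expect_equal(hit$gene_id, "aTie")
    expect_equal(hit$distance, 20L)
})

test_that("nearest TSS agrees with a brute-force all-genes scan", {
    set.seed(17)
    for (rep in 1:10) {
        nGenes <- 30L
        genes <- data.frame(
            gene_id = sprintf("g%02d", seq_len(nGenes)),
            symbol = sprintf("g%02d", seq_len(nGenes)),
            chrom = sample(c("chr1", "chr2"), nGenes, replace = TRUE),
            strand = "+",
            tss = sample.int(10000, nGenes),
            biotype = sample(c("protein_coding", "ncRNA"), nGenes,
                             replace = TRUE, prob = c(0.8, 0.2)))
        for (i in 1:10) {
            chrom <- sample(c("chr1", "chr2"), 1)
            s <- sample.int(9000, 1); e <- s + sample(50:500, 1)
            hit <- nearestTSS(c(chrom, s, e), genes)
            g <- genes[genes$biotype == "protein_coding" & genes$chrom == chrom, ]
            if (nrow(g) == 0L) {
                expect_true(is.na(hit$gene_id))
            } else {
                d <- ifelse(g$tss >= s & g$tss < e, 0L,
                            pmin(abs(g$tss - s), abs(g$tss - (e - 1L))))
                best <- g$gene_id[order(d, g$gene_id)][1]
                expect_equal(hit$gene_id, best)
                expect_equal(hit$distance, min(d))
            }
        }
    }
})

test_that("peak annotation carries clusters and handles empty chromosomes", {
    genes <- data.frame(gene_id = "g1", symbol = "s1", chrom = "chr1",
                        strand = "+", tss = 50L, biotype = "protein_coding")
    peaks <- toy_peakset(c("chr1", "chr2"), c(0L, 0L), c(100L, 100L))
    ann <- annotatePeaks(peaks, genes, clusters = c(2L, 1L))
    expect_equal(ann$gene_id, c("g1", NA))
    expect_equal(ann$tss_distance, c(0L, NA))
    expect_equal(ann$nd_cluster, c("ND2", "ND1"))
    expect_error(annotatePeaks(peaks, genes, clusters = 1L), "one label")
})

test_that("candidate selection is the strict three-way intersection", {
    clusterGenes <- list(ND4 = c("hbn", "zld", "noTF"), ND5 = c("scro", "hbn"))
    tf <- c("hbn", "scro", "zld", "absentMarker")
    markers <- data.frame(
        gene_id = c("hbn", "scro", "zld", "noTF", "hbn"),
        cluster_id = c("INP", "INP", "INP", "INP", "glia"),
        log_fold_change = c(1.2, 0.8, -0.5, 2.0, 3.0),
        adjusted_p = c(1e-6, 1e-4, 1e-8, 1e-9, 1e-2))
    cand <- selectCandidates(clusterGenes, tf, markers, "INP",
                             pMax = 0.05, lfcMin = 0)
    # zld: negative lfc excluded; noTF: not in catalogue; hbn in two ND clusters
    expect_setequal(cand$gene_id, c("hbn", "scro"))
    expect_setequal(cand$nd_cluster[cand$gene_id == "hbn"], c("ND4", "ND5"))
    # output is contained in catalogue and markers
    expect_true(all(cand$gene_id %in% tf))
    expect_true(all(cand$gene_id %in% markers$gene_id))
    # relaxing pMax never shrinks the output
    candStrict <- selectCandidates(clusterGenes, tf, markers, "INP", pMax = 1e-5)
    expect_true(all(candStrict$gene_id %in% cand$gene_id))
    expect_lte(nrow(candStrict), nrow(cand))
    expect_error(selectCandidates(clusterGenes, tf, markers, "notACluster"),
                 "unknown")
})

test_that("TF catalogue and marker tables parse and validate", {
    tfPath <- withr::local_tempfile(lines = c("# FlyTF-style list", "hbn",
                                              "scro\textra column", "", "hbn"))
    expect_equal(readTFCatalog(tfPath), c("hbn", "scro"))

    mkPath <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("gene_id\tcluster_id\tlog_fold_change\tadjusted_p",
                 "hbn\tINP\t1.5\t0.001"), mkPath)
    mk <- readMarkerTable(mkPath)
    expect_equal(mk$gene_id, "hbn")
    writeLines(c("gene_id\tcluster_id\tlog_fold_change\tadjusted_p",
                 "hbn\tINP\t1.5\t1.2"), mkPath)
    expect_error(readMarkerTable(mkPath), "adjusted_p")
})
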