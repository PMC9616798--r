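# Brute-force oracles and tiny fixture builders shared across tests.
# Oracles are deliberately naive (window scans, linear interval search,
# O(n^2) silhouettes) and independent of the package implementation.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(Biostrings)
})

# exhaustive 4-mer window scan; returns 0-based starts
oracle_gatc <- function(seq) {
    n <- nchar(seq)
    if (n < 4L) return(integer(0))
    hits <- integer(0)
    for (p in seq_len(n - 3L))
        if (substr(seq, p, p + 3L) == "GATC") hits <- c(hits, p - 1L)
    hits
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# linear per-read scan: fragment index containing 0-based position
oracle_assign <- function(pos0, starts0, ends0) {
    for (i in seq_along(starts0))
        if (pos0 >= starts0[i] && pos0 < ends0[i]) return(i)
    NA_integer_
}

# rank-mean quantile normalization; tied values share the mean of the
# rank means they span
oracle_quantile_normalize <- function(mat) {
    rankMeans <- rowMeans(apply(mat, 2, sort))
    out <- mat
    for (j in seq_len(ncol(mat))) {
        r1 <- rank(mat[, j], ties.method = "first")
        vals <- rankMeans[r1]
        for (v in unique(mat[duplicated(mat[, j]), j])) {
            idx <- mat[, j] == v
            vals[idx] <- mean(rankMeans[r1[idx]])
        }
        out[, j] <- vals
    }
    out
}

# O(n^2) mean silhouette width
oracle_mean_silhouette <- function(x, labels) {
    d <- as.matrix(dist(x))
    n <- nrow(x)
    s <- numeric(n)
    for (i in seq_len(n)) {
        own <- labels == labels[i]
        a <- if (sum(own) > 1L) mean(d[i, own & seq_len(n) != i]) else NA
        b <- min(vapply(setdiff(unique(labels), labels[i]),
                        function(l) mean(d[i, labels == l]), numeric(1)))
        s[i] <- if (sum(own) == 1L) 0 else (b - a) / max(a, b)
    }
    mean(s)
}

# fragment map over explicit interior boundaries
toy_map <- function(sites, len, chrom = "chr1") buildFragmentMap(sites, len, chrom)

toy_counts <- function(counts, id = "s") {
    new("BinnedCounts", sampleId = id, counts = as.integer(counts))
}

toy_track <- function(scores, fusion = "f", control = "g") {
    new("RatioTrack", fusionId = fusion, controlId = control,
        scores = as.numeric(scores), pseudocount = 0.5)
}

toy_profile <- function(values, id = "cond") {
    new("AveragedProfile", conditionId = id, meanLog2 = as.numeric(values),
        nComparisons = 1L)
}

toy_peakset <- function(chrom, starts0, ends0, fdr = NULL, support = NULL,
                        src = "a|b") {
    n <- length(starts0)
    gr <- GRanges(chrom, IRanges(starts0 + 1L, ends0))
    mcols(gr)$fdr <- if (is.null(fdr)) rep(1e-30, n) else fdr
    mcols(gr)$support <- if (is.null(support)) rep(1L, n) else as.integer(support)
    mcols(gr)$source_ids <- rep(src, length.out = n)
    new("PeakSet", peaks = gr, provenance = list())
}

# overlap-based recall/precision of consensus peaks vs planted truth
match_truth <- function(consensus, truth) {
    gr <- peakRanges(consensus)
    tr <- GRanges(truth$chrom, IRanges(truth$start + 1L, truth$end))
    recall <- mean(countOverlaps(tr, gr, ignore.strand = TRUE) > 0L)
    precision <- if (length(gr)) mean(countOverlaps(gr, tr, ignore.strand = TRUE) > 0L) else NA
    list(recall = recall, precision = precision)
}

write_sam <- function(path, seqlens, reads) {
    # reads: data.frame(qname, flag, chrom, pos1, mapq, cigar)
    con <- file(path, "w")
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens)), con)
    # sequence length = sum of M/I/S/=/X ops
    seqlen <- vapply(reads$cigar, function(cg) {
        if (cg == "*") return(0L)
        ops <- regmatches(cg, gregexpr("[0-9]+[MIDNSHP=X]", cg))[[1]]
        sum(as.integer(sub("[A-Z=]", "", ops))[grepl("[MIS=X]", ops)])
    }, integer(1))
    seqs <- ifelse(seqlen > 0L, strrep("A", seqlen), "*")
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                       reads$qname, reads$flag, reads$chrom, reads$pos1,
                       reads$mapq, reads$cigar, seqs), con)
    close(con)
    path
}
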