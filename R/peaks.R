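#' Call broad enriched regions for one pairwise comparison
#'
#' Per fragment, a one-sided Poisson test of the fusion count against
#' the library-size-scaled control expectation
#' `lambda_i = (g_i + p) * (F / G)` (pseudocount `p = 0.5`), i.e.
#' `P[X >= f_i]` for `X ~ Poisson(lambda_i)`. P-values are converted to
#' FDR by Benjamini-Hochberg across all fragments of the genome.
#' Fragments with `FDR <= qMax` are merged into peaks when separated by
#' at most `gapBp` base pairs, peaks with fewer than `minFrags`
#' significant fragments are discarded, and a peak's FDR is the minimum
#' fragment FDR inside it.
#'
#' @param fusion,control [BinnedCounts-class] objects on `map`.
#' @param map The shared [FragmentMap-class].
#' @param qMax FDR threshold in (0, 1) (default 1e-25, the published
#'   consensus filter; caller-dependent, so exposed as a parameter).
#' @param gapBp Maximum gap between significant fragments that still
#'   merges them (default 0: only adjacent fragments merge).
#' @param minFrags Minimum number of significant fragments per retained
#'   peak (default 1).
#' @param pseudocount Pseudocount used in the control expectation.
#' @return A [PeakSet-class] with `support = 1` for every peak and
#'   `source_ids = "<fusion>|<control>"`.
#' @importFrom GenomicRanges reduce countOverlaps
#' @export
callPeaks <- function(fusion, control, map, qMax = 1e-25, gapBp = 0L,
                      minFrags = 1L, pseudocount = 0.5) {
    frag <- fragments(map)
    f <- fragmentCounts(fusion); g <- fragmentCounts(control)
    if (length(f) != length(frag) || length(g) != length(frag))
        stop("samples are not on the supplied fragment map")
    if (qMax <= 0 || qMax >= 1) stop("'qMax' must lie in (0, 1)")
    FF <- sum(f); G <- sum(g)
    if (FF == 0 || G == 0) stop("library total is zero")
    lambda <- (g + pseudocount) * (FF / G)
    pval <- stats::ppois(f - 1L, lambda, lower.tail = FALSE)
    fdr <- stats::p.adjust(pval, method = "BH")
    srcId <- paste0(sampleId(fusion), "|", sampleId(control))
    prov <- list(fusion = sampleId(fusion), control = sampleId(control),
                 q_max = qMax, gap_bp = gapBp, min_frags = minFrags,
                 pseudocount = pseudocount)
    sig <- which(fdr <= qMax)
    if (!length(sig)) {
        return(new("PeakSet", peaks = .emptyPeaks(), provenance = prov))
    }
    sigGr <- frag[sig]
    mcols(sigGr)$fdr <- fdr[sig]
    merged <- reduce(sigGr, min.gapwidth = gapBp + 1L, ignore.strand = TRUE)
    hits <- findOverlaps(sigGr, merged, ignore.strand = TRUE)
    nsig <- tabulate(S4Vectors::subjectHits(hits), nbins = length(merged))
    minFdr <- vapply(split(fdr[sig][S4Vectors::queryHits(hits)],
                           S4Vectors::subjectHits(hits)), min, numeric(1))
    mcols(merged)$fdr <- as.numeric(minFdr)
    mcols(merged)$support <- 1L
    mcols(merged)$source_ids <- srcId
    merged <- merged[nsig >= minFrags]
    merged <- BiocGenerics::sort(merged, ignore.strand = TRUE)
    new("PeakSet", peaks = merged, provenance = prov)
}

.emptyPeaks <- function() {
    gr <- GRanges()
    mcols(gr)$fdr <- numeric(0)
    mcols(gr)$support <- integer(0)
    mcols(gr)$source_ids <- character(0)
    gr
}

#' Merge per-comparison peak sets into filtered consensus peaks
#'
#' The union of all input peaks is merged into maximal overlapping
#' intervals. Each consensus peak records `support`, the number of input
#' sets with at least 1 bp of overlap, and `fdr`, the minimum FDR of the
#' contributing peaks. A consensus peak is retained iff
#' `fdr < fdrMax` and `support / n_sets > minOccurrence` — the
#' occurrence filter is a strict inequality, so a peak present in
#' exactly half of the combinations is dropped at `minOccurrence = 0.5`.
#'
#' @param peaksets List of [PeakSet-class] objects on one genome.
#' @param fdrMax FDR filter (default 1e-25, strict `<`).
#' @param minOccurrence Occurrence filter as a fraction of input sets
#'   (default 0.5, strict `>`).
#' @return A consensus [PeakSet-class] with disjoint, sorted intervals.
#' @export
mergeConsensus <- function(peaksets, fdrMax = 1e-25, minOccurrence = 0.5) {
    if (!length(peaksets)) stop("need at least one peak set")
    n <- length(peaksets)
    grl <- lapply(peaksets, peakRanges)
    all <- suppressWarnings(do.call(c, unname(grl)))
    prov <- list(n_sets = n, fdr_max = fdrMax, min_occurrence = minOccurrence)
    if (length(all) == 0L)
        return(new("PeakSet", peaks = .emptyPeaks(), provenance = prov))
    merged <- reduce(all, ignore.strand = TRUE)
    support <- integer(length(merged))
    for (gr in grl)
        support <- support + as.integer(countOverlaps(merged, gr,
            minoverlap = 1L, ignore.strand = TRUE) > 0L)
    hits <- findOverlaps(all, merged, ignore.strand = TRUE)
    minFdr <- rep(NA_real_, length(merged))
    agg <- tapply(mcols(all)$fdr[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), min)
    minFdr[as.integer(names(agg))] <- as.numeric(agg)
    srcs <- tapply(mcols(all)$source_ids[S4Vectors::queryHits(hits)],
                   S4Vectors::subjectHits(hits),
                   function(s) paste(unique(s), collapse = ","))
    src <- rep(NA_character_, length(merged))
    src[as.integer(names(srcs))] <- as.character(srcs)
    mcols(merged)$fdr <- minFdr
    mcols(merged)$support <- support
    mcols(merged)$source_ids <- src
    keep <- (minFdr < fdrMax) & (support / n > minOccurrence)
    merged <- BiocGenerics::sort(merged[keep], ignore.strand = TRUE)
    new("PeakSet", peaks = merged, provenance = prov)
}

#' Export / import a peak set as BED6+
#'
#' Columns: chrom, start, end, name, score (`-log10(fdr)` capped at
#' 999), strand (`.`), support, fdr, source_ids. Consensus parameters
#' are written to a JSON sidecar `<path>.json`.
#'
#' @param peaks A [PeakSet-class].
#' @param path Output/input BED path.
#' @return `writePeakBed()` returns `path` invisibly; `readPeakBed()`
#'   returns a [PeakSet-class].
#' @export
writePeakBed <- function(peaks, path) {
    gr <- peakRanges(peaks)
    score <- pmin(-log10(pmax(mcols(gr)$fdr, 1e-999)), 999)
    score[!is.finite(score)] <- 999
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     name = sprintf("peak_%d", seq_along(gr)),
                     score = sprintf("%.4g", score),
                     strand = rep(".", length(gr)),
                     support = mcols(gr)$support,
                     fdr = sprintf("%.6g", mcols(gr)$fdr),
                     source_ids = mcols(gr)$source_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(peaks@provenance, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePeakBed
#' @export
readPeakBed <- function(path) {
    prov <- list()
    side <- paste0(path, ".json")
    if (file.exists(side)) prov <- jsonlite::read_json(side)
    if (file.size(path) == 0L)
        return(new("PeakSet", peaks = .emptyPeaks(), provenance = prov))
    df <- utils::read.table(path, sep = "\t", header = FALSE,
        col.names = c("chrom", "start", "end", "name", "score", "strand",
                      "support", "fdr", "source_ids"),
        colClasses = c("character", "integer", "integer", "character",
                       "numeric", "character", "integer", "numeric", "character"))
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
    mcols(gr)$fdr <- df$fdr
    mcols(gr)$support <- df$support
    mcols(gr)$source_ids <- df$source_ids
    new("PeakSet", peaks = gr, provenance = prov)
}
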