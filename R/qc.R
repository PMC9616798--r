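#' Fixed-bin genome-wide correlation of libraries
#'
#' Each read is extended from its 5' end to `ext` bp in its strand
#' direction and contributes to consecutive fixed-width genomic bins in
#' proportion to its bp overlap with each bin. Pairwise Pearson
#' correlation coefficients over all bins are returned as a symmetric
#' matrix with unit diagonal. This is the replicate/method comparison
#' used to judge whether libraries of the same condition agree more than
#' they agree with controls.
#'
#' @param samples Named list of alignment inputs (SAM/BAM path,
#'   `GAlignments` or `GRanges`, as in [assignReadsToFragments()]).
#' @param map A [FragmentMap-class]; only its chromosome lengths are
#'   used to tile the genome.
#' @param binSize Bin width in bp (default 500).
#' @param ext Read extension length in bp (default 150).
#' @param minMapq MAPQ filter applied when reading SAM/BAM.
#' @return Pearson correlation matrix (samples x samples).
#' @importFrom GenomicRanges tileGenome trim
#' @export
binnedCorrelation <- function(samples, map, binSize = 500L, ext = 150L,
                              minMapq = 30L) {
    if (length(samples) < 2L) stop("need at least two samples")
    sl <- seqlengths(fragments(map))
    bins <- tileGenome(sl, tilewidth = binSize, cut.last.tile.in.chrom = TRUE)
    cov <- vapply(samples, function(s) {
        gr <- .loadAlignments(s, minMapq = minMapq)
        keep <- as.character(seqnames(gr)) %in% names(sl)
        if (!all(keep)) gr <- gr[keep]
        if (length(gr) == 0L) stop("sample has no alignments on the map's genome")
        GenomeInfoDb::seqlevels(gr) <- names(sl)
        seqlengths(gr) <- sl
        egr <- suppressWarnings(trim(GenomicRanges::resize(
            .fivePrime(gr), width = ext, fix = "start")))
        hits <- findOverlaps(egr, bins, ignore.strand = TRUE)
        ov <- BiocGenerics::width(pintersect(
            granges(egr)[S4Vectors::queryHits(hits)],
            granges(bins)[S4Vectors::subjectHits(hits)]))
        out <- numeric(length(bins))
        agg <- tapply(ov, S4Vectors::subjectHits(hits), sum)
        out[as.integer(names(agg))] <- as.numeric(agg)
        out
    }, numeric(length(bins)))
    r <- stats::cor(cov, method = "pearson")
    diag(r) <- 1
    nm <- names(samples)
    if (!is.null(nm)) dimnames(r) <- list(nm, nm)
    r
}

#' ROC-like peak recovery curve
#'
#' Query peaks are ranked by decreasing score (`-log10` FDR by default);
#' after including each query peak in turn, the y value is the fraction
#' of reference peaks overlapped by at least 1 bp by any included query
#' peak. The area is the mean of y over all ranks (in `[0, 1]`). Used to
#' compare peak sets between replicates or profiling methods: a query
#' that recovers the reference with few top peaks has area near 1.
#'
#' @param reference,query Non-empty [PeakSet-class] objects; query peaks
#'   must carry finite FDRs to be ranked (or supply `scores`).
#' @param scores Optional explicit ranking scores (higher = better),
#'   e.g. aggregated signal instead of the FDR-based default.
#' @return List with `x` (ranks), `y` (recovered fraction) and `area`.
#' @export
rocLikeRecovery <- function(reference, query, scores = NULL) {
    refGr <- peakRanges(reference); qGr <- peakRanges(query)
    if (!length(refGr) || !length(qGr)) stop("reference and query must be non-empty")
    if (is.null(scores)) {
        fdr <- mcols(qGr)$fdr
        if (is.null(fdr) || any(is.na(fdr))) stop("query peaks are unscored")
        scores <- -log10(pmax(fdr, .Machine$double.xmin))
    }
    if (length(scores) != length(qGr)) stop("one score per query peak required")
    ord <- order(scores, decreasing = TRUE)
    qGr <- qGr[ord]
    hits <- findOverlaps(qGr, refGr, minoverlap = 1L, ignore.strand = TRUE)
    firstHit <- rep(Inf, length(refGr))
    if (length(hits)) {
        agg <- tapply(S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits), min)
        firstHit[as.integer(names(agg))] <- as.numeric(agg)
    }
    y <- vapply(seq_along(qGr), function(k) mean(firstHit <= k), numeric(1))
    list(x = seq_along(qGr), y = y, area = mean(y))
}

#' Signal-enrichment meta-profile over a peak set
#'
#' Each peak, extended by `flankFrac` of its length on both sides, is
#' rescaled to `nPoints` equal segments; the profile value of each
#' segment is the overlap-weighted mean of the fragment values it
#' covers, and the meta-profile is the mean across peaks per segment.
#' Segments falling outside a chromosome are clamped to it.
#'
#' @param profile An [AveragedProfile-class].
#' @param map The matching [FragmentMap-class].
#' @param peaks A non-empty [PeakSet-class].
#' @param nPoints Number of positions the rescaled region is sampled at
#'   (default 60).
#' @param flankFrac Flank size as a fraction of peak length (default
#'   0.5).
#' @return List with `position` (relative coordinate in `[0, 1]`, peak
#'   body in the central band) and `mean_signal` per position.
#' @export
signalEnrichment <- function(profile, map, peaks, nPoints = 60L,
                             flankFrac = 0.5) {
    gr <- peakRanges(peaks)
    if (!length(gr)) stop("empty peak set")
    frag <- fragments(map)
    v <- meanLog2(profile)
    if (length(v) != length(frag))
        stop("profile length does not match the fragment map")
    sl <- seqlengths(frag)
    ## per-chromosome fragment boundaries for fast positional lookup
    chrIdx <- split(seq_along(frag), as.character(seqnames(frag)))
    acc <- matrix(0, nrow = length(gr), ncol = nPoints)
    for (i in seq_along(gr)) {
        chr <- as.character(seqnames(gr[i]))
        idx <- chrIdx[[chr]]
        st0 <- BiocGenerics::start(frag[idx]) - 1L
        en0 <- BiocGenerics::end(frag[idx])
        p0 <- BiocGenerics::start(gr[i]) - 1L
        p1 <- BiocGenerics::end(gr[i])
        len <- p1 - p0
        lo <- p0 - flankFrac * len
        hi <- p1 + flankFrac * len
        edges <- seq(lo, hi, length.out = nPoints + 1L)
        for (j in seq_len(nPoints)) {
            a <- max(edges[j], 0); b <- min(edges[j + 1L], sl[[chr]])
            if (b <= a) { # whole segment off-chromosome: clamp to edge fragment
                k <- if (edges[j] < 0) 1L else length(idx)
                acc[i, j] <- v[idx[k]]
                next
            }
            ov <- pmax(0, pmin(en0, b) - pmax(st0, a))
            acc[i, j] <- sum(v[idx] * ov) / sum(ov)
        }
    }
    list(position = (seq_len(nPoints) - 0.5) / nPoints,
         mean_signal = colMeans(acc))
}

#' Fingerprint curve and library-complexity summary
#'
#' The fingerprint curve answers "how concentrated is the signal": bins
#' are sorted by ascending count and `y(q)` is the cumulative fraction
#' of all reads contained in the lowest-count fraction `q` of bins. A
#' uniform library lies on the diagonal; a focused library hugs the
#' x-axis until the top bins. The unique-read fraction (distinct
#' (chrom, 5' position, strand) triples over accepted reads) is the
#' empirical complexity summary.
#'
#' @param counts A [BinnedCounts-class] with positive library total.
#' @param alignments Optional alignment input (SAM/BAM path,
#'   `GAlignments` or `GRanges`) used for the unique-read fraction.
#' @param minMapq MAPQ filter applied when reading SAM/BAM.
#' @return List with `q` (bin fraction), `y` (cumulative read
#'   fraction) and `unique_read_fraction` (`NA` when no alignments are
#'   supplied).
#' @export
fingerprintAndComplexity <- function(counts, alignments = NULL, minMapq = 30L) {
    cnt <- fragmentCounts(counts)
    total <- sum(cnt)
    if (total == 0L) stop("library total is zero")
    srt <- sort(cnt)
    B <- length(srt)
    y <- cumsum(as.numeric(srt)) / total
    uniqueFrac <- NA_real_
    if (!is.null(alignments)) {
        gr <- .loadAlignments(alignments, minMapq = minMapq)
        p5 <- .fivePrime(gr)
        key <- paste(as.character(seqnames(p5)), BiocGenerics::start(p5),
                     as.character(BiocGenerics::strand(p5)))
        uniqueFrac <- length(unique(key)) / length(key)
    }
    list(q = seq_len(B) / B, y = y, unique_read_fraction = uniqueFrac)
}
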