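#' Pairwise log2 fusion/control ratio
#'
#' One Dam-fusion replicate normalised against one Dam-only control
#' replicate. Per fragment,
#' `r_i = log2((f_i + p) / (g_i + p)) - log2(F / G)`
#' where `f_i`, `g_i` are fragment counts, `F`, `G` the library totals
#' and `p` a symmetric pseudocount that keeps the ratio finite and maps
#' 0/0 fragments to exactly zero.
#'
#' @param fusion,control [BinnedCounts-class] objects on the same
#'   fragment map.
#' @param pseudocount Pseudocount in reads (default 0.5).
#' @return A [RatioTrack-class].
#' @export
pairwiseLogRatio <- function(fusion, control, pseudocount = 0.5) {
    f <- fragmentCounts(fusion); g <- fragmentCounts(control)
    if (length(f) != length(g))
        stop("fusion and control are not on the same fragment map")
    if (pseudocount <= 0) stop("pseudocount must be positive")
    FF <- sum(f); G <- sum(g)
    if (FF == 0 || G == 0) stop("library total is zero")
    r <- log2((f + pseudocount) / (g + pseudocount)) - log2(FF / G)
    new("RatioTrack", fusionId = sampleId(fusion), controlId = sampleId(control),
        scores = r, pseudocount = pseudocount)
}

#' All pairwise fusion-vs-control ratio tracks
#'
#' Computes [pairwiseLogRatio()] for every (fusion replicate, control
#' replicate) combination, matching the all-combinations normalisation
#' design in which each of the fusion replicates is normalised
#' individually to all Dam-only control replicates.
#'
#' @param fusions,controls Lists of [BinnedCounts-class] replicates.
#' @param pseudocount Pseudocount in reads.
#' @return List of `length(fusions) * length(controls)`
#'   [RatioTrack-class] objects, fusion-major order.
#' @export
allPairwiseRatios <- function(fusions, controls, pseudocount = 0.5) {
    if (!length(fusions) || !length(controls))
        stop("need at least one fusion and one control replicate")
    out <- vector("list", length(fusions) * length(controls))
    k <- 1L
    for (f in fusions) for (g in controls) {
        out[[k]] <- pairwiseLogRatio(f, g, pseudocount)
        k <- k + 1L
    }
    out
}

#' Quantile-normalise a set of ratio tracks
#'
#' Classical quantile normalisation: at each rank position every track's
#' value is replaced by the mean across tracks of the values at that
#' rank, so afterwards all tracks share exactly the same sorted values.
#' Tied input values receive the mean of the rank means they span, which
#' keeps the operation deterministic and permutation-equivariant. By
#' default normalisation is applied jointly over all pairwise
#' comparisons of one condition; passing tracks from several conditions
#' normalises them jointly across conditions instead.
#'
#' @param tracks List of [RatioTrack-class] objects of equal length.
#' @return List of normalised [RatioTrack-class] objects, same order.
#' @export
quantileNormalizeTracks <- function(tracks) {
    if (!length(tracks)) stop("need at least one track")
    lens <- vapply(tracks, function(t) length(trackScores(t)), integer(1))
    if (length(unique(lens)) != 1L) stop("tracks differ in length")
    if (length(tracks) == 1L) return(tracks)
    mat <- vapply(tracks, trackScores, numeric(lens[1]))
    rankMeans <- rowMeans(apply(mat, 2, sort))
    qn <- apply(mat, 2, function(x) {
        # ties.method = "first" makes each tie group occupy the contiguous
        # block of rank positions it spans; the group then shares the mean
        # of the rank means over that block
        stats::ave(rankMeans[rank(x, ties.method = "first")], x)
    })
    lapply(seq_along(tracks), function(i)
        methods::initialize(tracks[[i]], scores = qn[, i]))
}

#' Average normalised tracks into one condition profile
#'
#' Arithmetic mean of the log2 binding intensities per fragment across
#' all quantile-normalised pairwise comparisons; the backtransformed
#' linear profile `2^mean` is available through [linearIntensity()] and
#' is only used for export.
#'
#' @param tracks List of (quantile-normalised) [RatioTrack-class]
#'   objects.
#' @param conditionId Condition label for the profile.
#' @return An [AveragedProfile-class].
#' @export
averageProfiles <- function(tracks, conditionId = "condition") {
    if (!length(tracks)) stop("need at least one track")
    lens <- vapply(tracks, function(t) length(trackScores(t)), integer(1))
    if (length(unique(lens)) != 1L) stop("tracks differ in length")
    mat <- vapply(tracks, trackScores, numeric(lens[1]))
    m <- if (is.matrix(mat)) rowMeans(mat) else mat
    new("AveragedProfile", conditionId = conditionId, meanLog2 = as.numeric(m),
        nComparisons = length(tracks))
}

#' Export a profile as bedGraph
#'
#' Writes the per-fragment profile as a 4-column bedGraph (0-based
#' half-open); `scale = "log2"` exports the mean log2 intensities,
#' `scale = "linear"` the backtransformed `2^mean` values.
#'
#' @param profile An [AveragedProfile-class].
#' @param map The matching [FragmentMap-class].
#' @param path Output path.
#' @param scale `"log2"` or `"linear"`.
#' @return `path`, invisibly.
#' @export
writeProfileBedGraph <- function(profile, map, path, scale = c("log2", "linear")) {
    scale <- match.arg(scale)
    frag <- fragments(map)
    v <- meanLog2(profile)
    if (length(v) != length(frag))
        stop("profile length does not match the fragment map")
    if (scale == "linear") v <- 2^v
    df <- data.frame(chrom = as.character(seqnames(frag)),
                     start = BiocGenerics::start(frag) - 1L,
                     end = BiocGenerics::end(frag),
                     score = sprintf("%.6g", v))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
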