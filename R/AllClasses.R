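#' @import methods
#' @importFrom GenomicRanges GRanges granges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#'   seqlevels<- seqinfo Seqinfo
NULL

#' GATC fragment map
#'
#' Tiling of a genome into half-open intervals delimited by consecutive
#' GATC motifs. Each chromosome is covered exactly: the first fragment
#' starts at position 0 and the last ends at the chromosome length, so
#' chromosome-terminal regions (before the first and after the last GATC)
#' are included as terminal fragments. A fragment starts at the start
#' coordinate of a GATC motif; the 4 bp motif belongs to the downstream
#' fragment. These fragments are the unit of DamID signal throughout the
#' package.
#'
#' @slot fragments A [GenomicRanges::GRanges] (1-based internally, exported
#'   as 0-based half-open BED) with a `fragment_id` metadata column of the
#'   form `chrom:index`, and seqlengths set for every chromosome.
#'
#' @seealso [gatcFragmentMap()], [buildFragmentMap()]
#' @export
setClass("FragmentMap", representation(fragments = "GRanges"))

setValidity("FragmentMap", function(object) {
    gr <- object@fragments
    if (length(gr) == 0L) return("fragment map is empty")
    if (is.null(mcols(gr)$fragment_id)) return("missing fragment_id column")
    sl <- seqlengths(gr)
    if (any(is.na(sl))) return("seqlengths must be set for all chromosomes")
    for (chr in seqlevels(gr)) {
        g <- gr[as.character(seqnames(gr)) == chr]
        if (length(g) == 0L) next
        s <- BiocGenerics::start(g); e <- BiocGenerics::end(g)
        if (s[1] != 1L) return(sprintf("first fragment on %s does not start at 0", chr))
        if (e[length(g)] != sl[[chr]]) return(sprintf("last fragment on %s does not reach chromosome end", chr))
        if (length(g) > 1L && any(s[-1] != e[-length(g)] + 1L))
            return(sprintf("fragments on %s do not tile without gaps/overlaps", chr))
    }
    TRUE
})

#' Per-fragment read counts for one sample
#'
#' @slot sampleId Sample identifier.
#' @slot counts Non-negative integer vector, index-aligned to the
#'   fragments of the [FragmentMap-class] the sample was counted on.
#'
#' @seealso [assignReadsToFragments()], [readCountTable()]
#' @export
setClass("BinnedCounts",
    representation(sampleId = "character", counts = "integer"))

setValidity("BinnedCounts", function(object) {
    if (length(object@sampleId) != 1L) return("sampleId must be a single string")
    if (any(is.na(object@counts)) || any(object@counts < 0L))
        return("counts must be non-negative and non-missing")
    TRUE
})

#' Per-fragment log2 fusion/control ratio track
#'
#' One pairwise comparison: a Dam-fusion replicate normalised against a
#' Dam-only control replicate with library-size scaling and a symmetric
#' pseudocount, so values are finite everywhere.
#'
#' @slot fusionId,controlId Sample identifiers of the pair.
#' @slot scores Per-fragment log2 ratios (dimensionless).
#' @slot pseudocount Pseudocount (reads) used in the ratio.
#' @export
setClass("RatioTrack",
    representation(fusionId = "character", controlId = "character",
                   scores = "numeric", pseudocount = "numeric"))

setValidity("RatioTrack", function(object) {
    if (any(!is.finite(object@scores))) return("scores must be finite")
    if (object@pseudocount <= 0) return("pseudocount must be positive")
    TRUE
})

#' Averaged binding profile for one condition
#'
#' Arithmetic mean over all quantile-normalised pairwise log2 ratio
#' tracks of one condition; the linear-scale profile is the backtransform
#' `2^meanLog2`.
#'
#' @slot conditionId Condition (e.g. the GFP-tagged factor).
#' @slot meanLog2 Per-fragment mean log2 binding intensity.
#' @slot nComparisons Number of pairwise comparisons averaged.
#' @export
setClass("AveragedProfile",
    representation(conditionId = "character", meanLog2 = "numeric",
                   nComparisons = "integer"))

setValidity("AveragedProfile", function(object) {
    if (any(!is.finite(object@meanLog2))) return("meanLog2 must be finite")
    if (object@nComparisons < 1L) return("nComparisons must be >= 1")
    TRUE
})

#' A set of scored enriched intervals
#'
#' Peaks carry a false-discovery rate, the number of pairwise
#' combinations supporting them (`support`, 1 for a single-comparison
#' set) and their source identifiers. After consensus merging the
#' intervals are pairwise disjoint and sorted.
#'
#' @slot peaks A [GenomicRanges::GRanges] with metadata columns `fdr`,
#'   `support` and `source_ids`.
#' @slot provenance List of the parameters the set was produced with.
#' @export
setClass("PeakSet", representation(peaks = "GRanges", provenance = "list"))

setValidity("PeakSet", function(object) {
    m <- mcols(object@peaks)
    need <- c("fdr", "support", "source_ids")
    if (!all(need %in% colnames(m)))
        return(paste("missing peak columns:", paste(setdiff(need, colnames(m)), collapse = ", ")))
    if (length(object@peaks)) {
        if (any(m$fdr < 0 | m$fdr > 1)) return("fdr must lie in [0, 1]")
        if (any(m$support < 1L)) return("support must be >= 1")
    }
    TRUE
})

#' Peaks-by-conditions binding intensity matrix
#'
#' Length-normalised, overlap-weighted mean log2 intensities per
#' consensus peak and condition, plus a column z-scored copy (each
#' condition centred and scaled across peaks; constant columns are left
#' as zeros).
#'
#' @slot intensity Numeric matrix, rows = peaks, columns = conditions.
#' @slot zscore Matrix of the same shape, column z-scores.
#' @export
setClass("PeakIntensityMatrix",
    representation(intensity = "matrix", zscore = "matrix"))

setValidity("PeakIntensityMatrix", function(object) {
    if (!identical(dim(object@intensity), dim(object@zscore)))
        return("intensity and zscore must have identical dimensions")
    if (any(!is.finite(object@intensity))) return("intensity must have no missing values")
    TRUE
})

#' Result of silhouette-guided k-means clustering
#'
#' @slot k Selected cluster count (argmax mean silhouette width, ties to
#'   the smaller k).
#' @slot labels Integer cluster label per peak, in `1..k`.
#' @slot centers Cluster centroid matrix (k x conditions, z-units).
#' @slot silhouette Named numeric vector of mean silhouette width per
#'   searched k.
#' @slot seed RNG seed used for the k-means restarts.
#' @export
setClass("ClusteringResult",
    representation(k = "integer", labels = "integer", centers = "matrix",
                   silhouette = "numeric", seed = "integer"))

setValidity("ClusteringResult", function(object) {
    if (any(object@labels < 1L | object@labels > object@k))
        return("labels must lie in 1..k")
    if (length(unique(object@labels)) != object@k)
        return("every cluster must be non-empty")
    if (any(object@silhouette < -1 | object@silhouette > 1))
        return("silhouette widths must lie in [-1, 1]")
    TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "FragmentMap", function(object) {
    gr <- object@fragments
    cat("FragmentMap with", length(gr), "fragments on",
        length(seqlevels(gr)), "chromosome(s)\n")
    cat("  mean fragment length:", round(mean(BiocGenerics::width(gr)), 1), "bp\n")
})

setMethod("show", "BinnedCounts", function(object) {
    cat("BinnedCounts for sample", object@sampleId, "-", length(object@counts),
        "fragments, library total", sum(object@counts), "\n")
})

setMethod("show", "RatioTrack", function(object) {
    cat("RatioTrack", object@fusionId, "vs", object@controlId,
        sprintf("(%d fragments, pseudocount %.3g)\n",
                length(object@scores), object@pseudocount))
})

setMethod("show", "AveragedProfile", function(object) {
    cat("AveragedProfile for", object@conditionId, "-",
        length(object@meanLog2), "fragments, mean of",
        object@nComparisons, "pairwise comparisons\n")
})

setMethod("show", "PeakSet", function(object) {
    cat("PeakSet with", length(object@peaks), "peaks")
    if (length(object@peaks))
        cat(sprintf(" (median width %d bp, min FDR %.3g)",
            as.integer(stats::median(BiocGenerics::width(object@peaks))),
            suppressWarnings(min(mcols(object@peaks)$fdr))))
    cat("\n")
})

setMethod("show", "PeakIntensityMatrix", function(object) {
    cat("PeakIntensityMatrix:", nrow(object@intensity), "peaks x",
        ncol(object@intensity), "conditions\n")
})

setMethod("show", "ClusteringResult", function(object) {
    cat("ClusteringResult: k =", object@k, "clusters over",
        length(object@labels), "peaks\n")
    cat("  mean silhouette by k:\n")
    print(round(object@silhouette, 3))
})
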