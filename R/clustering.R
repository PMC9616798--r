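#' Overlap-weighted mean binding intensity over one peak
#'
#' Aggregates the per-fragment log2 profile across a peak, weighting
#' each fragment by the number of base pairs it shares with the peak and
#' normalising by peak length:
#' `intensity = sum_i(v_i * o_i) / sum_i(o_i)` with `o_i` the bp overlap
#' of fragment `i` with the peak (`sum_i o_i` equals the peak length).
#' Fragments intersecting the peak borders thus contribute in proportion
#' to their overlap.
#'
#' @param profile An [AveragedProfile-class].
#' @param map The matching [FragmentMap-class].
#' @param peak A single-interval `GRanges` (or the i-th peak of a
#'   [PeakSet-class] via `peakRanges(ps)[i]`).
#' @return Length-normalised mean log2 intensity (scalar).
#' @importFrom IRanges pintersect
#' @export
aggregatePeakIntensity <- function(profile, map, peak) {
    frag <- fragments(map)
    v <- meanLog2(profile)
    if (length(v) != length(frag))
        stop("profile length does not match the fragment map")
    if (!methods::is(peak, "GRanges") || length(peak) != 1L)
        stop("'peak' must be a single GRanges interval")
    if (!(as.character(seqnames(peak)) %in% seqlevels(frag)))
        stop("peak chromosome absent from the fragment map")
    hits <- findOverlaps(peak, frag, ignore.strand = TRUE)
    idx <- S4Vectors::subjectHits(hits)
    if (!length(idx)) stop("peak overlaps no fragment")
    ov <- BiocGenerics::width(pintersect(rep(granges(peak), length(idx)),
                                         granges(frag[idx])))
    sum(v[idx] * ov) / sum(ov)
}

#' Build the peaks-by-conditions intensity matrix
#'
#' Applies [aggregatePeakIntensity()] for every (peak, condition) pair
#' on the log-scale averaged profiles, then z-scores each condition
#' column across peaks (centred, scaled by the sample standard
#' deviation) so the conditions are directly comparable. A constant
#' column cannot be scaled and is left as zeros with a warning.
#'
#' @param profiles List of [AveragedProfile-class] objects (one per
#'   condition); names default to their condition IDs.
#' @param map The shared [FragmentMap-class].
#' @param peaks A [PeakSet-class] of consensus peaks (>= 2 peaks).
#' @return A [PeakIntensityMatrix-class] with peak IDs as row names.
#' @export
buildPeakIntensityMatrix <- function(profiles, map, peaks) {
    if (!length(profiles)) stop("need at least one condition profile")
    gr <- peakRanges(peaks)
    if (length(gr) < 2L) stop("need at least two peaks")
    condIds <- vapply(profiles, function(p) p@conditionId, character(1))
    frag <- fragments(map)
    vmat <- vapply(profiles, meanLog2, numeric(length(frag)))
    hits <- findOverlaps(gr, frag, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- BiocGenerics::width(pintersect(granges(gr)[q], granges(frag)[s]))
    wsum <- as.numeric(tapply(ov, q, sum))
    mat <- matrix(NA_real_, nrow = length(gr), ncol = length(profiles),
                  dimnames = list(sprintf("peak_%d", seq_along(gr)), condIds))
    for (j in seq_along(profiles)) {
        num <- tapply(vmat[s, j] * ov, q, sum)
        mat[as.integer(names(num)), j] <- as.numeric(num) / wsum
    }
    if (any(is.na(mat))) stop("some peaks overlap no fragment of the map")
    z <- mat
    for (j in seq_len(ncol(mat))) {
        sdj <- stats::sd(mat[, j])
        if (!is.finite(sdj) || sdj == 0) {
            warning(sprintf("condition '%s' has constant intensity; z-scores set to 0",
                            condIds[j]))
            z[, j] <- 0
        } else {
            z[, j] <- (mat[, j] - mean(mat[, j])) / sdj
        }
    }
    new("PeakIntensityMatrix", intensity = mat, zscore = z)
}

#' Mean silhouette width of a clustering
#'
#' @param x Numeric matrix of observations (rows).
#' @param labels Integer cluster labels.
#' @return Mean silhouette width across observations.
#' @importFrom cluster silhouette
#' @export
meanSilhouetteWidth <- function(x, labels) {
    sil <- silhouette(labels, stats::dist(x))
    mean(sil[, "sil_width"])
}

#' K-means clustering with silhouette-guided selection of k
#'
#' For each candidate `k`, runs Euclidean k-means on the z-scored
#' peaks-by-conditions matrix with `nInit` random restarts under a fixed
#' seed and computes the mean silhouette width; the clustering with the
#' maximum mean silhouette is returned, ties broken towards the smaller
#' `k`. This is the combinatorial-binding analysis that groups peaks
#' into classes of shared factor-binding patterns.
#'
#' @param mat A [PeakIntensityMatrix-class] (its z-scored matrix is
#'   clustered), or a plain numeric matrix of z-scores.
#' @param kRange Candidate cluster counts (default `2:10`); must lie in
#'   `[2, n_peaks - 1]`.
#' @param nInit Number of k-means restarts per k (default 25).
#' @param seed RNG seed (default 1).
#' @return A [ClusteringResult-class].
#' @export
selectKAndCluster <- function(mat, kRange = 2:10, nInit = 25L, seed = 1L) {
    z <- if (methods::is(mat, "PeakIntensityMatrix")) zscoreMatrix(mat) else as.matrix(mat)
    n <- nrow(z)
    if (n < 3L) stop("need at least three peaks to cluster")
    kRange <- sort(unique(as.integer(kRange)))
    if (any(kRange < 2L) || any(kRange > n - 1L))
        stop("'kRange' must lie within [2, n_peaks - 1]")
    if (nInit < 1L) stop("'nInit' must be >= 1")
    d <- stats::dist(z)
    sil <- stats::setNames(numeric(length(kRange)), kRange)
    fits <- vector("list", length(kRange))
    for (i in seq_along(kRange)) {
        set.seed(seed)
        km <- stats::kmeans(z, centers = kRange[i], nstart = nInit,
                            iter.max = 100L)
        fits[[i]] <- km
        s <- silhouette(km$cluster, d)
        sil[i] <- mean(s[, "sil_width"])
    }
    best <- which.max(sil)   # which.max takes the first (smallest k) on ties
    km <- fits[[best]]
    new("ClusteringResult", k = kRange[best],
        labels = as.integer(km$cluster),
        centers = km$centers,
        silhouette = sil, seed = as.integer(seed))
}

#' Export clustering artefacts as TSV
#'
#' Writes the raw and z-scored intensity matrix, the per-peak cluster
#' assignments and the centroid matrix.
#'
#' @param mat A [PeakIntensityMatrix-class].
#' @param result A [ClusteringResult-class] for the same peaks.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
writeClusterTables <- function(mat, result, dir, prefix = "cluster") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    raw <- intensityMatrix(mat); z <- zscoreMatrix(mat)
    p1 <- file.path(dir, paste0(prefix, "_intensity.tsv"))
    p2 <- file.path(dir, paste0(prefix, "_zscore.tsv"))
    p3 <- file.path(dir, paste0(prefix, "_assignments.tsv"))
    p4 <- file.path(dir, paste0(prefix, "_centroids.tsv"))
    .writeMat <- function(m, path, idcol = "peak_id") {
        df <- data.frame(rownames(m), format(m, digits = 8, trim = TRUE),
                         check.names = FALSE)
        colnames(df) <- c(idcol, colnames(m))
        utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    .writeMat(raw, p1); .writeMat(z, p2)
    utils::write.table(
        data.frame(peak_id = rownames(raw), cluster = clusterLabels(result)),
        p3, sep = "\t", quote = FALSE, row.names = FALSE)
    cen <- result@centers
    rownames(cen) <- sprintf("ND%d", seq_len(nrow(cen)))
    .writeMat(cen, p4, idcol = "cluster")
    invisible(c(p1, p2, p3, p4))
}
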