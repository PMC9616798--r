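#' @importFrom GenomicAlignments readGAlignments
#' @importFrom Rsamtools ScanBamParam scanBamFlag asBam
NULL

## Load alignments from a SAM/BAM path (or pass through a GRanges/GAlignments)
## keeping primary mapped records with MAPQ >= minMapq. Returns a GRanges of
## full aligned spans with strand.
.loadAlignments <- function(x, minMapq = 0L) {
    if (methods::is(x, "GRanges")) return(x)
    if (methods::is(x, "GAlignments")) return(granges(x))
    if (!is.character(x) || length(x) != 1L)
        stop("alignments must be a SAM/BAM path, GAlignments or GRanges")
    path <- x
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile(fileext = "")
        path <- asBam(path, destination = dest, overwrite = TRUE,
                      indexDestination = TRUE)
    }
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE)
    param <- ScanBamParam(flag = flag, mapqFilter = as.integer(minMapq))
    granges(readGAlignments(path, param = param))
}

## 5'-most aligned base per read as width-1 GRanges (strand-aware).
.fivePrime <- function(gr) {
    GenomicRanges::resize(gr, width = 1L, fix = "start", ignore.strand = FALSE)
}

#' Assign aligned reads to GATC fragments
#'
#' Each primary, mapped alignment with `MAPQ >= minMapq` contributes
#' exactly one count to the fragment containing its 5'-most aligned base
#' (the leftmost base for + strand reads, the rightmost for - strand
#' reads). Reads are not extended at this stage: the GATC fragment, not
#' base-pair coverage, is the DamID signal unit. Alignments on
#' chromosomes absent from the map are skipped with a warning.
#'
#' @param alignments Path to a SAM/BAM file, a
#'   [GenomicAlignments::GAlignments], or a GRanges of aligned spans.
#' @param map A [FragmentMap-class].
#' @param minMapq Minimum mapping quality (applied when reading SAM/BAM;
#'   default 30, a conservative uniqueness proxy).
#' @param dedup If `TRUE`, collapse identical (chrom, 5' position,
#'   strand) triples to a single read before counting. Off by default:
#'   DamID libraries are typically sequenced well past saturation of
#'   distinct GATC fragments, so identical 5' ends are expected.
#' @param sampleId Sample identifier stored in the result.
#' @return A [BinnedCounts-class]; the number of skipped
#'   unknown-chromosome alignments is available as
#'   `attr(x, "n_skipped")`.
#' @importFrom GenomicRanges findOverlaps
#' @export
assignReadsToFragments <- function(alignments, map, minMapq = 30L,
                                   dedup = FALSE, sampleId = "sample") {
    gr <- .loadAlignments(alignments, minMapq = minMapq)
    frag <- fragments(map)
    known <- as.character(seqnames(gr)) %in% seqlevels(frag)
    nSkip <- sum(!known)
    if (nSkip > 0L) {
        warning(sprintf("%d alignment(s) on chromosomes absent from the fragment map were skipped", nSkip))
        gr <- gr[known]
    }
    if (length(gr) == 0L) stop("no usable alignments")
    p5 <- .fivePrime(gr)
    if (dedup) {
        key <- paste(as.character(seqnames(p5)), BiocGenerics::start(p5),
                     as.character(BiocGenerics::strand(p5)))
        p5 <- p5[!duplicated(key)]
    }
    hits <- findOverlaps(p5, frag, ignore.strand = TRUE)
    counts <- tabulate(S4Vectors::subjectHits(hits), nbins = length(frag))
    bc <- new("BinnedCounts", sampleId = sampleId, counts = as.integer(counts))
    attr(bc, "n_skipped") <- nSkip
    bc
}

#' Read / write a per-fragment count table
#'
#' TSV with header `chrom  start  end  count` in 0-based half-open
#' coordinates. On reading, every interval must match the fragment map
#' exactly (same order, same boundaries); any mismatch is rejected so a
#' table counted on a different digest cannot slip through.
#'
#' @param path TSV path.
#' @param map The [FragmentMap-class] the counts must align to.
#' @param sampleId Sample identifier for the returned object (default:
#'   file base name).
#' @return `readCountTable()` returns a [BinnedCounts-class];
#'   `writeCountTable()` returns `path` invisibly.
#' @export
readCountTable <- function(path, map, sampleId = NULL) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "integer", "integer", "integer"))
    if (!identical(colnames(df), c("chrom", "start", "end", "count")))
        stop("count table must have columns chrom, start, end, count")
    if (nrow(df) == 0L) stop("empty count table")
    frag <- fragments(map)
    if (nrow(df) != length(frag))
        stop("count table has a different number of intervals than the fragment map")
    ok <- identical(df$chrom, as.character(seqnames(frag))) &&
        identical(df$start, BiocGenerics::start(frag) - 1L) &&
        identical(df$end, BiocGenerics::end(frag))
    if (!ok) stop("count table intervals do not match the fragment map")
    if (any(df$count < 0L)) stop("counts must be non-negative")
    if (is.null(sampleId))
        sampleId <- sub("\\.[^.]*$", "", basename(path))
    new("BinnedCounts", sampleId = sampleId, counts = df$count)
}

#' @rdname readCountTable
#' @param counts A [BinnedCounts-class] to write.
#' @export
writeCountTable <- function(counts, map, path) {
    frag <- fragments(map)
    if (length(frag) != length(fragmentCounts(counts)))
        stop("counts length does not match the fragment map")
    df <- data.frame(chrom = as.character(seqnames(frag)),
                     start = BiocGenerics::start(frag) - 1L,
                     end = BiocGenerics::end(frag),
                     count = fragmentCounts(counts))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
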