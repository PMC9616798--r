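#' Find GATC motif start positions in a DNA sequence
#'
#' Exhaustive scan for the Dam methylase recognition motif. Positions are
#' 0-based. `N` (or any non-ACGT base) never matches, so assembly gaps do
#' not create spurious fragment boundaries. GATC cannot overlap itself,
#' so the scan is equivalent to a sliding 4-mer window.
#'
#' @param seq A single DNA sequence: a character string or a
#'   [Biostrings::DNAString].
#' @return Sorted integer vector of 0-based motif start positions.
#' @examples
#' findGATCSites("GGATCC")   # 1
#' findGATCSites("GATCGATC") # 0, 4
#' @importFrom Biostrings DNAString matchPattern
#' @export
findGATCSites <- function(seq) {
    if (is.character(seq)) {
        if (length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
            stop("'seq' must be a single non-empty DNA string")
        seq <- DNAString(toupper(seq))
    }
    if (length(seq) == 0L) stop("'seq' must be non-empty")
    m <- matchPattern("GATC", seq, fixed = TRUE)
    as.integer(BiocGenerics::start(m)) - 1L
}

#' Build the fragment intervals for one chromosome
#'
#' Fragment boundaries are `{0} U sites U {chrom_length}` (deduplicated);
#' fragments are the consecutive half-open spans between boundaries. With
#' no interior site the whole chromosome is a single terminal fragment.
#'
#' @param sites Sorted 0-based GATC start positions, all `< chromLength`.
#' @param chromLength Chromosome length in bp.
#' @param chrom Chromosome name used for fragment IDs.
#' @return A [FragmentMap-class] for the single chromosome.
#' @examples
#' buildFragmentMap(c(10, 50), 100)
#' @export
buildFragmentMap <- function(sites, chromLength, chrom = "chr") {
    chromLength <- as.integer(chromLength)
    if (is.na(chromLength) || chromLength <= 0L)
        stop("'chromLength' must be a positive integer")
    sites <- as.integer(sites)
    if (length(sites)) {
        if (is.unsorted(sites, strictly = FALSE)) stop("'sites' must be sorted")
        if (any(sites < 0L) || any(sites >= chromLength))
            stop("'sites' must lie in [0, chromLength)")
    }
    bounds <- unique(c(0L, sites, chromLength))
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1L]
    gr <- GRanges(chrom, IRanges(start = starts + 1L, end = ends),
                  seqinfo = Seqinfo(chrom, seqlengths = chromLength))
    mcols(gr)$fragment_id <- paste0(chrom, ":", seq_along(gr) - 1L)
    new("FragmentMap", fragments = gr)
}

#' Build the genome-wide GATC fragment map
#'
#' Scans every chromosome for GATC motifs and tiles it into fragments
#' delimited by consecutive motif starts, including the terminal regions
#' before the first and after the last motif.
#'
#' @param genome A named [Biostrings::DNAStringSet] (as returned by
#'   [readGenomeFasta()]).
#' @return A [FragmentMap-class] covering every chromosome.
#' @importFrom Biostrings DNAStringSet
#' @export
gatcFragmentMap <- function(genome) {
    if (!methods::is(genome, "DNAStringSet"))
        genome <- DNAStringSet(genome)
    if (length(genome) == 0L) stop("genome has no chromosomes")
    nms <- names(genome)
    if (is.null(nms) || anyDuplicated(nms) || any(!nzchar(nms)))
        stop("chromosome names must be present and unique")
    lens <- Biostrings::width(genome)
    if (any(lens == 0L)) stop("every chromosome must have length > 0")
    per <- lapply(seq_along(genome), function(i) {
        sites <- findGATCSites(genome[[i]])
        fragments(buildFragmentMap(sites, lens[i], chrom = nms[i]))
    })
    gr <- suppressWarnings(do.call(c, per))
    seqlengths(gr) <- stats::setNames(lens, nms)[seqlevels(gr)]
    new("FragmentMap", fragments = gr)
}

#' Read a genome FASTA file
#'
#' Multi-record, wrapped-line FASTA; sequence names are truncated at the
#' first whitespace and uppercased sequences are returned.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @importFrom Biostrings readDNAStringSet
#' @export
readGenomeFasta <- function(path) {
    g <- readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    g
}

#' Serialize / restore a fragment map as BED
#'
#' Fragments are written as 0-based half-open BED intervals with
#' `name = chrom:index`. `readFragmentMapBED()` reconstructs the map and
#' re-derives seqlengths from the terminal fragment ends.
#'
#' @param map A [FragmentMap-class].
#' @param path Output/input BED path.
#' @return `writeFragmentMapBED()` returns `path` invisibly;
#'   `readFragmentMapBED()` returns a [FragmentMap-class].
#' @export
writeFragmentMapBED <- function(map, path) {
    gr <- fragments(map)
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     name = mcols(gr)$fragment_id)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeFragmentMapBED
#' @export
readFragmentMapBED <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "name"),
                            colClasses = c("character", "integer", "integer", "character"))
    if (nrow(df) == 0L) stop("empty fragment map BED")
    chroms <- unique(df$chrom)
    lens <- vapply(chroms, function(ch) max(df$end[df$chrom == ch]), integer(1))
    gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end),
                  seqinfo = Seqinfo(chroms, seqlengths = lens))
    mcols(gr)$fragment_id <- df$name
    new("FragmentMap", fragments = gr)
}
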