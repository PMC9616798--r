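#' Parse gene models from GTF/GFF
#'
#' Extracts one record per gene with its canonical transcription start
#' site: the 5'-most TSS across the gene's transcripts (minimum start on
#' the + strand, maximum end on the - strand; the gene's own
#' coordinates are used when no transcript features are present). TSS
#' coordinates are returned 0-based.
#'
#' @param path Path to a GTF or GFF file with `gene` (and optionally
#'   `transcript`/`mRNA`) features carrying `gene_id` and a biotype
#'   attribute (`gene_biotype` or `gene_type`).
#' @return `data.frame` with columns `gene_id`, `symbol`, `chrom`,
#'   `strand`, `tss` (0-based bp) and `biotype`.
#' @importFrom rtracklayer import
#' @export
parseGeneModels <- function(path) {
    gr <- import(path)
    m <- mcols(gr)
    type <- as.character(m$type)
    isGene <- type == "gene"
    if (!any(isGene)) stop("no gene features found in ", path)
    genes <- gr[isGene]
    gm <- mcols(genes)
    gid <- as.character(gm$gene_id)
    bad <- is.na(gid) | !nzchar(gid)
    if (any(bad)) {
        warning(sum(bad), " gene feature(s) without gene_id skipped")
        genes <- genes[!bad]; gm <- mcols(genes); gid <- gid[!bad]
    }
    biotype <- if (!is.null(gm$gene_biotype)) as.character(gm$gene_biotype)
        else if (!is.null(gm$gene_type)) as.character(gm$gene_type)
        else rep(NA_character_, length(genes))
    symbol <- if (!is.null(gm$gene_name)) as.character(gm$gene_name) else gid
    strand <- as.character(BiocGenerics::strand(genes))
    if (any(!strand %in% c("+", "-")))
        stop("gene strand must be + or -")
    ## canonical TSS: 5'-most across the gene's transcripts
    start1 <- BiocGenerics::start(genes); end1 <- BiocGenerics::end(genes)
    isTx <- type %in% c("transcript", "mRNA")
    if (any(isTx)) {
        tx <- gr[isTx]
        txGid <- as.character(mcols(tx)$gene_id)
        txStart <- tapply(BiocGenerics::start(tx), txGid, min)
        txEnd <- tapply(BiocGenerics::end(tx), txGid, max)
        hit <- gid %in% names(txStart)
        start1[hit] <- as.integer(txStart[gid[hit]])
        end1[hit] <- as.integer(txEnd[gid[hit]])
    }
    tss <- ifelse(strand == "+", start1 - 1L, end1 - 1L)
    data.frame(gene_id = gid, symbol = symbol,
               chrom = as.character(seqnames(genes)),
               strand = strand, tss = as.integer(tss),
               biotype = biotype, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Nearest transcription start site for one peak
#'
#' Distance is 0 when the TSS lies inside the peak `[start, end)`,
#' otherwise the distance to the nearer peak boundary,
#' `min(|tss - start|, |tss - (end - 1)|)`. Ties are broken by
#' lexicographically smaller `gene_id`, so the assignment is
#' deterministic.
#'
#' @param peak Single `GRanges` interval or a vector
#'   `c(chrom, start0, end0)`; internally 0-based half-open.
#' @param genes Gene model `data.frame` from [parseGeneModels()].
#' @param biotypeFilter Keep only genes of this biotype (default
#'   `"protein_coding"`; `NULL` keeps all).
#' @return List with `gene_id`, `symbol` and `distance` (bp), or `NA`
#'   fields when no gene passes the filter on the peak's chromosome.
#' @export
nearestTSS <- function(peak, genes, biotypeFilter = "protein_coding") {
    if (methods::is(peak, "GRanges")) {
        chrom <- as.character(seqnames(peak))
        start0 <- BiocGenerics::start(peak) - 1L
        end0 <- BiocGenerics::end(peak)
    } else {
        chrom <- as.character(peak[[1]])
        start0 <- as.integer(peak[[2]]); end0 <- as.integer(peak[[3]])
    }
    g <- genes
    if (!is.null(biotypeFilter)) g <- g[g$biotype %in% biotypeFilter, , drop = FALSE]
    g <- g[g$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0L)
        return(list(gene_id = NA_character_, symbol = NA_character_,
                    distance = NA_integer_))
    inside <- g$tss >= start0 & g$tss < end0
    d <- pmin(abs(g$tss - start0), abs(g$tss - (end0 - 1L)))
    d[inside] <- 0L
    ord <- order(d, g$gene_id)
    list(gene_id = g$gene_id[ord[1]], symbol = g$symbol[ord[1]],
         distance = as.integer(d[ord[1]]))
}

#' Annotate every peak of a set with its nearest TSS
#'
#' @param peaks A [PeakSet-class].
#' @param genes Gene model `data.frame` from [parseGeneModels()].
#' @param biotypeFilter Biotype filter passed to [nearestTSS()].
#' @param clusters Optional integer cluster labels (one per peak), e.g.
#'   from [selectKAndCluster()], recorded as `ND<label>`.
#' @return `data.frame` with one row per peak: coordinates, FDR,
#'   support, nearest gene and distance (and `nd_cluster` if supplied).
#' @export
annotatePeaks <- function(peaks, genes, biotypeFilter = "protein_coding",
                          clusters = NULL) {
    gr <- peakRanges(peaks)
    res <- lapply(seq_along(gr), function(i)
        nearestTSS(gr[i], genes, biotypeFilter))
    df <- data.frame(peak_id = sprintf("peak_%d", seq_along(gr)),
                     chrom = as.character(seqnames(gr)),
                     start = BiocGenerics::start(gr) - 1L,
                     end = BiocGenerics::end(gr),
                     fdr = mcols(gr)$fdr,
                     support = mcols(gr)$support,
                     gene_id = vapply(res, `[[`, character(1), "gene_id"),
                     symbol = vapply(res, `[[`, character(1), "symbol"),
                     tss_distance = vapply(res, `[[`, integer(1), "distance"),
                     stringsAsFactors = FALSE)
    if (!is.null(clusters)) {
        if (length(clusters) != length(gr))
            stop("'clusters' must have one label per peak")
        df$nd_cluster <- sprintf("ND%d", as.integer(clusters))
    }
    df
}

#' Read a transcription-factor catalogue
#'
#' One gene ID per line (FlyTF-style list); lines starting with `#` and
#' blank lines are ignored.
#'
#' @param path TSV/plain-text path.
#' @return Character vector of unique gene IDs.
#' @export
readTFCatalog <- function(path) {
    x <- readLines(path)
    x <- x[nzchar(trimws(x))]
    x <- trimws(vapply(strsplit(x, "\t"), `[[`, character(1), 1))
    unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read an scRNA-seq marker table
#'
#' TSV with header `gene_id  cluster_id  log_fold_change  adjusted_p`,
#' the per-cluster differential-expression output of an upstream
#' single-cell analysis.
#'
#' @param path TSV path.
#' @return `data.frame` with those four columns.
#' @export
readMarkerTable <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "cluster_id", "log_fold_change", "adjusted_p")
    if (!all(need %in% colnames(df)))
        stop("marker table must have columns ", paste(need, collapse = ", "))
    if (any(df$adjusted_p < 0 | df$adjusted_p > 1, na.rm = TRUE))
        stop("adjusted_p must lie in [0, 1]")
    df[need]
}

#' Nominate candidate genes by intersecting binding, TF and expression
#'
#' A gene is a candidate iff it (a) is assigned to a binding cluster,
#' (b) appears in the transcription-factor catalogue, and (c) is a
#' significant marker of the target expression cluster
#' (`adjusted_p < pMax` and `log_fold_change >= lfcMin`). This is the
#' candidate-selection intersection that nominated new temporal factors.
#'
#' @param clusterGenes Named list: per binding-cluster character vectors
#'   of gene IDs (e.g. nearest-TSS genes per ND cluster), or a
#'   `data.frame` with columns `gene_id` and `nd_cluster` as returned by
#'   [annotatePeaks()].
#' @param tfCatalog Character vector of TF gene IDs.
#' @param markers Marker `data.frame` from [readMarkerTable()].
#' @param targetCluster The expression cluster whose markers to use.
#' @param pMax Adjusted-p threshold (default 0.05, strict `<`).
#' @param lfcMin Minimum log fold change (default 0, `>=`).
#' @return `data.frame` with columns `gene_id`, `nd_cluster`,
#'   `log_fold_change`, `adjusted_p`, sorted by gene ID.
#' @export
selectCandidates <- function(clusterGenes, tfCatalog, markers, targetCluster,
                             pMax = 0.05, lfcMin = 0) {
    if (is.data.frame(clusterGenes)) {
        if (!all(c("gene_id", "nd_cluster") %in% colnames(clusterGenes)))
            stop("'clusterGenes' data.frame needs gene_id and nd_cluster columns")
        cg <- clusterGenes[!is.na(clusterGenes$gene_id),
                           c("gene_id", "nd_cluster")]
    } else {
        if (!length(clusterGenes)) stop("'clusterGenes' is empty")
        cg <- data.frame(
            gene_id = unlist(clusterGenes, use.names = FALSE),
            nd_cluster = rep(names(clusterGenes), lengths(clusterGenes)),
            stringsAsFactors = FALSE)
    }
    if (!length(tfCatalog)) stop("'tfCatalog' is empty")
    if (!nrow(markers)) stop("'markers' is empty")
    if (!targetCluster %in% markers$cluster_id)
        stop("unknown target cluster: ", targetCluster)
    mk <- markers[markers$cluster_id == targetCluster &
                  markers$adjusted_p < pMax &
                  markers$log_fold_change >= lfcMin, , drop = FALSE]
    cg <- cg[cg$gene_id %in% tfCatalog & cg$gene_id %in% mk$gene_id, , drop = FALSE]
    cg <- unique(cg)
    out <- merge(cg, mk[, c("gene_id", "log_fold_change", "adjusted_p")],
                 by = "gene_id")
    out[order(out$gene_id, out$nd_cluster), , drop = FALSE]
}
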