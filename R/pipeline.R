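#' Read a per-fragment profile back from bedGraph
#'
#' Inverse of [writeProfileBedGraph()] for the log2 track: intervals
#' must match the fragment map exactly.
#'
#' @param path bedGraph path (log2 scale).
#' @param map The [FragmentMap-class] the track was written on.
#' @param conditionId Condition label (default: file base name).
#' @param nComparisons Number of comparisons recorded in the returned
#'   object (informational; default 1).
#' @return An [AveragedProfile-class].
#' @export
readProfileBedGraph <- function(path, map, conditionId = NULL,
                                nComparisons = 1L) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
        col.names = c("chrom", "start", "end", "score"),
        colClasses = c("character", "integer", "integer", "numeric"))
    frag <- fragments(map)
    if (nrow(df) != length(frag) ||
        !identical(df$chrom, as.character(seqnames(frag))) ||
        !identical(df$start, BiocGenerics::start(frag) - 1L) ||
        !identical(df$end, BiocGenerics::end(frag)))
        stop("bedGraph intervals do not match the fragment map")
    if (is.null(conditionId))
        conditionId <- sub("\\.[^.]*$", "", basename(path))
    new("AveragedProfile", conditionId = conditionId, meanLog2 = df$score,
        nComparisons = as.integer(nComparisons))
}

#' Union of peak sets across conditions
#'
#' Merges several (already filtered) consensus peak sets into one peak
#' universe without further filtering: overlapping intervals are
#' unified, support counts the contributing sets, and the FDR is the
#' minimum across contributors. Used to build the cross-condition peak
#' universe that the combinatorial-binding clustering operates on.
#'
#' @param peaksets List of [PeakSet-class] objects.
#' @return A [PeakSet-class].
#' @export
combinePeakSets <- function(peaksets) {
    mergeConsensus(peaksets, fdrMax = 1, minOccurrence = 0)
}

.defaultParameters <- function() {
    list(pseudocount = 0.5, q_max = 1e-25, gap_bp = 0L, min_frags = 1L,
         fdr_max = 1e-25, min_occurrence = 0.5, joint_quantile = FALSE,
         k_range = c(2L, 10L), n_init = 25L, bin_size = 500L, ext = 150L,
         min_mapq = 30L, p_max = 0.05, lfc_min = 0, n_points = 60L,
         flank_frac = 0.5, seed = 1L)
}

#' Read and validate a pipeline run configuration
#'
#' YAML with three optional blocks: `output_dir` (required), `simulate`
#' (parameters forwarded to [simulationSpec()], snake_case),
#' `paths` (genome / fragment_map / sample_sheet / annotation / tf_list
#' / markers) and `parameters` (stage parameters; missing entries take
#' the documented defaults). Every referenced file must exist at load
#' time and parameter ranges are validated against the stage
#' preconditions.
#'
#' @param path YAML path, or a list with the same structure.
#' @return Validated config list of class `RunConfig`.
#' @export
readRunConfig <- function(path) {
    cfg <- if (is.list(path)) path else yaml::read_yaml(path)
    if (is.null(cfg$output_dir)) stop("config must set output_dir")
    par <- utils::modifyList(.defaultParameters(),
                             if (is.null(cfg$parameters)) list() else cfg$parameters)
    if (par$pseudocount <= 0) stop("pseudocount must be positive")
    if (par$q_max <= 0 || par$q_max >= 1) stop("q_max must lie in (0, 1)")
    if (par$min_occurrence < 0 || par$min_occurrence >= 1)
        stop("min_occurrence must lie in [0, 1)")
    if (length(par$k_range) != 2L || par$k_range[1] < 2L ||
        par$k_range[2] < par$k_range[1])
        stop("k_range must be c(kmin, kmax) with kmin >= 2")
    if (par$n_init < 1L) stop("n_init must be >= 1")
    cfg$parameters <- par
    for (p in unlist(cfg$paths))
        if (!file.exists(p)) stop("configured path does not exist: ", p)
    class(cfg) <- c("RunConfig", "list")
    cfg
}

.manifest <- function(cfg, stage, inputs, outputs, seed) {
    dir.create(file.path(cfg$output_dir, "manifests"), showWarnings = FALSE,
               recursive = TRUE)
    jsonlite::write_json(
        list(stage = stage, inputs = inputs, outputs = outputs,
             parameters = cfg$parameters, seed = seed,
             package_version = as.character(utils::packageVersion("nanodam"))),
        file.path(cfg$output_dir, "manifests", paste0(stage, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.readSampleSheet <- function(cfg) {
    path <- file.path(cfg$output_dir, "samples.tsv")
    if (!is.null(cfg$paths$sample_sheet)) path <- cfg$paths$sample_sheet
    if (!file.exists(path)) stop("no sample sheet found; run 'simulate' or configure paths$sample_sheet")
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

.loadMap <- function(cfg) {
    p <- file.path(cfg$output_dir, "fragment_map.bed")
    if (!is.null(cfg$paths$fragment_map)) p <- cfg$paths$fragment_map
    if (!file.exists(p)) stop("no fragment map found; run 'gatc-map' first")
    readFragmentMapBED(p)
}

.loadCounts <- function(cfg, map) {
    sheet <- .readSampleSheet(cfg)
    bc <- lapply(seq_len(nrow(sheet)), function(i) {
        p <- sheet$path[i]
        if (!file.exists(p)) p <- file.path(cfg$output_dir, sheet$path[i])
        readCountTable(p, map, sampleId = sheet$sample_id[i])
    })
    split(bc, sheet$condition)
}

.conditionNames <- function(cfg) {
    sheet <- .readSampleSheet(cfg)
    setdiff(unique(sheet$condition), "control")
}

#' Run one pipeline stage
#'
#' Subcommands: `simulate` (synthetic experiment from `config$simulate`),
#' `gatc-map`, `count`, `normalize`, `callpeaks`, `consensus`,
#' `cluster`, `annotate` (only when annotation paths are configured),
#' `qc`, and `all` (everything after `simulate` in order). Each stage
#' reads its inputs from `output_dir` (or configured paths), writes its
#' artefacts there and records a JSON manifest; reruns with the same
#' config and seed reproduce TSV/BED/bedGraph outputs byte for byte.
#'
#' @param name Stage name.
#' @param config A `RunConfig` from [readRunConfig()] (or a path/list
#'   accepted by it).
#' @param seed Optional seed overriding the configured one.
#' @return Invisible character vector of written artefact paths.
#' @export
runSubcommand <- function(name, config, seed = NULL) {
    cfg <- if (inherits(config, "RunConfig")) config else readRunConfig(config)
    stages <- c("simulate", "gatc-map", "count", "normalize", "callpeaks",
                "consensus", "cluster", "annotate", "qc", "all")
    if (!name %in% stages)
        stop("unknown subcommand '", name, "'; expected one of: ",
             paste(stages, collapse = ", "))
    if (!is.null(seed)) cfg$parameters$seed <- as.integer(seed)
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (name == "all") {
        out <- unlist(lapply(c("gatc-map", "count", "normalize", "callpeaks",
                               "consensus", "cluster",
                               if (!is.null(cfg$paths$annotation)) "annotate",
                               "qc"),
                             function(s) runSubcommand(s, cfg)))
        return(invisible(out))
    }
    fun <- switch(name,
        "simulate" = .stageSimulate, "gatc-map" = .stageGatcMap,
        "count" = .stageCount, "normalize" = .stageNormalize,
        "callpeaks" = .stageCallPeaks, "consensus" = .stageConsensus,
        "cluster" = .stageCluster, "annotate" = .stageAnnotate,
        "qc" = .stageQc)
    invisible(fun(cfg))
}

.stageSimulate <- function(cfg) {
    sim <- if (is.null(cfg$simulate)) list() else cfg$simulate
    spec <- simulationSpec(
        nChroms = sim$n_chroms %||% 3L,
        chromLength = sim$chrom_length %||% 1e5,
        gatcMode = sim$gatc_mode %||% "random",
        gatcSpacing = sim$gatc_spacing %||% 200L,
        sitesPerArchetype = sim$sites_per_archetype %||% 10L,
        siteWidthFragments = sim$site_width_fragments %||% 3L,
        fusionReplicates = if (is.null(sim$fusion_replicates))
            c(D = 4L, Grh = 5L, Ey = 4L) else unlist(sim$fusion_replicates),
        controlReplicates = sim$control_replicates %||% 8L,
        depth = sim$depth %||% 50,
        dispersion = sim$dispersion %||% 10,
        accessibilitySd = sim$accessibility_sd %||% 0.5,
        seed = cfg$parameters$seed)
    ex <- simulateExperiment(spec)
    od <- cfg$output_dir
    dir.create(file.path(od, "counts"), showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(od, "genome.fa")
    Biostrings::writeXStringSet(ex$genome, fa)
    mapBed <- writeFragmentMapBED(ex$map, file.path(od, "fragment_map.bed"))
    truthBed <- writeTruthBed(ex$truth, file.path(od, "truth.bed"))
    allSamples <- c(ex$controls, unlist(ex$fusions, recursive = FALSE))
    conds <- c(rep("control", length(ex$controls)),
               rep(names(ex$fusions), vapply(ex$fusions, length, integer(1))))
    paths <- character(length(allSamples))
    for (i in seq_along(allSamples)) {
        paths[i] <- file.path("counts", paste0(sampleId(allSamples[[i]]), ".tsv"))
        writeCountTable(allSamples[[i]], ex$map, file.path(od, paths[i]))
    }
    sheet <- data.frame(sample_id = vapply(allSamples, sampleId, character(1)),
                        condition = conds, path = paths)
    utils::write.table(sheet, file.path(od, "samples.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outs <- c(fa, mapBed, truthBed, file.path(od, "samples.tsv"),
              file.path(od, paths))
    .manifest(cfg, "simulate", list(), outs, cfg$parameters$seed)
    outs
}

.stageGatcMap <- function(cfg) {
    fa <- cfg$paths$genome %||% file.path(cfg$output_dir, "genome.fa")
    if (!file.exists(fa)) stop("genome FASTA not found: ", fa)
    map <- gatcFragmentMap(readGenomeFasta(fa))
    out <- writeFragmentMapBED(map, file.path(cfg$output_dir, "fragment_map.bed"))
    .manifest(cfg, "gatc-map", list(genome = fa), out, cfg$parameters$seed)
    out
}

.stageCount <- function(cfg) {
    map <- .loadMap(cfg)
    sheet <- .readSampleSheet(cfg)
    od <- cfg$output_dir
    dir.create(file.path(od, "counts"), showWarnings = FALSE, recursive = TRUE)
    outs <- character(0)
    for (i in seq_len(nrow(sheet))) {
        p <- sheet$path[i]
        if (!file.exists(p)) p <- file.path(od, sheet$path[i])
        dest <- file.path(od, "counts", paste0(sheet$sample_id[i], ".tsv"))
        if (grepl("\\.(sam|bam)$", p, ignore.case = TRUE)) {
            bc <- assignReadsToFragments(p, map,
                minMapq = cfg$parameters$min_mapq,
                sampleId = sheet$sample_id[i])
            writeCountTable(bc, map, dest)
        } else {
            bc <- readCountTable(p, map, sampleId = sheet$sample_id[i])
            if (normalizePath(p) != suppressWarnings(normalizePath(dest, mustWork = FALSE)))
                writeCountTable(bc, map, dest)
        }
        outs <- c(outs, dest)
    }
    .manifest(cfg, "count", list(samples = sheet$path), outs, cfg$parameters$seed)
    outs
}

.stageNormalize <- function(cfg) {
    map <- .loadMap(cfg)
    byCond <- .loadCounts(cfg, map)
    conds <- setdiff(names(byCond), "control")
    if (!"control" %in% names(byCond)) stop("no control samples in sample sheet")
    od <- file.path(cfg$output_dir, "profiles")
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    p <- cfg$parameters
    perCond <- lapply(conds, function(cn)
        allPairwiseRatios(byCond[[cn]], byCond$control, p$pseudocount))
    if (isTRUE(p$joint_quantile)) {
        sizes <- vapply(perCond, length, integer(1))
        qn <- quantileNormalizeTracks(unlist(perCond, recursive = FALSE))
        perCond <- split(qn, rep(seq_along(conds), sizes))
    } else {
        perCond <- lapply(perCond, quantileNormalizeTracks)
    }
    outs <- character(0)
    for (i in seq_along(conds)) {
        prof <- averageProfiles(perCond[[i]], conditionId = conds[i])
        f1 <- file.path(od, paste0(conds[i], ".log2.bedgraph"))
        f2 <- file.path(od, paste0(conds[i], ".linear.bedgraph"))
        writeProfileBedGraph(prof, map, f1, scale = "log2")
        writeProfileBedGraph(prof, map, f2, scale = "linear")
        outs <- c(outs, f1, f2)
    }
    .manifest(cfg, "normalize", list(conditions = conds), outs, p$seed)
    outs
}

.stageCallPeaks <- function(cfg) {
    map <- .loadMap(cfg)
    byCond <- .loadCounts(cfg, map)
    conds <- setdiff(names(byCond), "control")
    p <- cfg$parameters
    outs <- character(0)
    for (cn in conds) {
        dir <- file.path(cfg$output_dir, "peaks", cn)
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        for (f in byCond[[cn]]) for (g in byCond$control) {
            ps <- callPeaks(f, g, map, qMax = p$q_max, gapBp = p$gap_bp,
                            minFrags = p$min_frags, pseudocount = p$pseudocount)
            dest <- file.path(dir, sprintf("%s_vs_%s.bed", sampleId(f), sampleId(g)))
            writePeakBed(ps, dest)
            outs <- c(outs, dest)
        }
    }
    .manifest(cfg, "callpeaks", list(conditions = conds), outs, p$seed)
    outs
}

.stageConsensus <- function(cfg) {
    p <- cfg$parameters
    conds <- .conditionNames(cfg)
    outs <- character(0)
    for (cn in conds) {
        dir <- file.path(cfg$output_dir, "peaks", cn)
        beds <- sort(list.files(dir, pattern = "_vs_.*\\.bed$", full.names = TRUE))
        if (!length(beds)) stop("no pairwise peak files for condition ", cn,
                                "; run 'callpeaks' first")
        sets <- lapply(beds, readPeakBed)
        cons <- mergeConsensus(sets, fdrMax = p$fdr_max,
                               minOccurrence = p$min_occurrence)
        dest <- file.path(cfg$output_dir, "peaks",
                          paste0("consensus_", cn, ".bed"))
        writePeakBed(cons, dest)
        outs <- c(outs, dest)
    }
    .manifest(cfg, "consensus", list(conditions = conds), outs, p$seed)
    outs
}

.stageCluster <- function(cfg) {
    map <- .loadMap(cfg)
    p <- cfg$parameters
    conds <- .conditionNames(cfg)
    profiles <- lapply(conds, function(cn) readProfileBedGraph(
        file.path(cfg$output_dir, "profiles", paste0(cn, ".log2.bedgraph")),
        map, conditionId = cn))
    consensus <- lapply(conds, function(cn) readPeakBed(
        file.path(cfg$output_dir, "peaks", paste0("consensus_", cn, ".bed"))))
    universe <- combinePeakSets(consensus)
    if (length(universe) < 3L)
        stop("fewer than three consensus peaks; nothing to cluster")
    mat <- buildPeakIntensityMatrix(profiles, map, universe)
    kmax <- min(p$k_range[2], nrow(intensityMatrix(mat)) - 1L)
    res <- selectKAndCluster(mat, kRange = p$k_range[1]:kmax,
                             nInit = p$n_init, seed = p$seed)
    dir <- file.path(cfg$output_dir, "clusters")
    outs <- writeClusterTables(mat, res, dir)
    uniBed <- writePeakBed(universe, file.path(dir, "peak_universe.bed"))
    .manifest(cfg, "cluster", list(conditions = conds),
              c(outs, uniBed), p$seed)
    c(outs, uniBed)
}

.stageAnnotate <- function(cfg) {
    if (is.null(cfg$paths$annotation))
        stop("'annotate' requires paths$annotation in the config")
    map <- .loadMap(cfg)
    genes <- parseGeneModels(cfg$paths$annotation)
    dir <- file.path(cfg$output_dir, "clusters")
    universe <- readPeakBed(file.path(dir, "peak_universe.bed"))
    assign <- utils::read.table(file.path(dir, "cluster_assignments.tsv"),
                                sep = "\t", header = TRUE)
    ann <- annotatePeaks(universe, genes, clusters = assign$cluster)
    outAnn <- file.path(cfg$output_dir, "annotated_peaks.tsv")
    utils::write.table(ann, outAnn, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- outAnn
    if (!is.null(cfg$paths$tf_list) && !is.null(cfg$paths$markers) &&
        !is.null(cfg$target_cluster)) {
        tf <- readTFCatalog(cfg$paths$tf_list)
        mk <- readMarkerTable(cfg$paths$markers)
        cand <- selectCandidates(ann, tf, mk, cfg$target_cluster,
                                 pMax = cfg$parameters$p_max,
                                 lfcMin = cfg$parameters$lfc_min)
        outCand <- file.path(cfg$output_dir, "candidates.tsv")
        utils::write.table(cand, outCand, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outs <- c(outs, outCand)
    }
    .manifest(cfg, "annotate", list(annotation = cfg$paths$annotation),
              outs, cfg$parameters$seed)
    outs
}

.stageQc <- function(cfg) {
    map <- .loadMap(cfg)
    byCond <- .loadCounts(cfg, map)
    conds <- setdiff(names(byCond), "control")
    p <- cfg$parameters
    od <- file.path(cfg$output_dir, "qc")
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    outs <- character(0)
    ## fingerprint curve per sample (from fragment counts)
    fp <- lapply(unlist(byCond, recursive = FALSE), function(bc)
        fingerprintAndComplexity(bc))
    ids <- vapply(unlist(byCond, recursive = FALSE), sampleId, character(1))
    fpDf <- data.frame(sample_id = rep(ids, vapply(fp, function(x) length(x$q), integer(1))),
                       q = unlist(lapply(fp, `[[`, "q")),
                       y = sprintf("%.8g", unlist(lapply(fp, `[[`, "y"))))
    f1 <- file.path(od, "fingerprint.tsv")
    utils::write.table(fpDf, f1, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, f1)
    ## ROC-like recovery of the consensus by each pairwise comparison
    for (cn in conds) {
        consPath <- file.path(cfg$output_dir, "peaks", paste0("consensus_", cn, ".bed"))
        if (!file.exists(consPath)) next
        cons <- readPeakBed(consPath)
        if (!length(cons)) next
        beds <- sort(list.files(file.path(cfg$output_dir, "peaks", cn),
                                pattern = "_vs_.*\\.bed$", full.names = TRUE))
        rows <- list()
        for (b in beds) {
            q <- readPeakBed(b)
            if (!length(q)) next
            rc <- rocLikeRecovery(cons, q)
            rows[[length(rows) + 1L]] <- data.frame(
                comparison = sub("\\.bed$", "", basename(b)),
                area = sprintf("%.8g", rc$area),
                final_recovery = sprintf("%.8g", rc$y[length(rc$y)]))
        }
        if (length(rows)) {
            f2 <- file.path(od, paste0("recovery_", cn, ".tsv"))
            utils::write.table(do.call(rbind, rows), f2, sep = "\t",
                               quote = FALSE, row.names = FALSE)
            outs <- c(outs, f2)
        }
        ## signal enrichment of the condition profile on its consensus peaks
        profPath <- file.path(cfg$output_dir, "profiles",
                              paste0(cn, ".log2.bedgraph"))
        if (file.exists(profPath)) {
            prof <- readProfileBedGraph(profPath, map, conditionId = cn)
            se <- signalEnrichment(prof, map, cons, nPoints = p$n_points,
                                   flankFrac = p$flank_frac)
            f3 <- file.path(od, paste0("enrichment_", cn, ".tsv"))
            utils::write.table(
                data.frame(position = sprintf("%.8g", se$position),
                           mean_signal = sprintf("%.8g", se$mean_signal)),
                f3, sep = "\t", quote = FALSE, row.names = FALSE)
            outs <- c(outs, f3)
        }
    }
    .manifest(cfg, "qc", list(conditions = conds), outs, p$seed)
    outs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
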