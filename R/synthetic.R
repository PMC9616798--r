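#' Default binding-combination archetypes
#'
#' Six combinatorial binding patterns of the three temporal factors
#' (D, Grh, Ey), mirroring the combinations observed for intermediate
#' neural progenitor peaks: ND1 strong D only; ND2 strong D and Grh;
#' ND3 strong Grh; ND4 strong binding of all three; ND5 Ey; ND6 minimal
#' binding of all three. "Strong" is 3.0 log2 units of enrichment and
#' the minimal baseline is 1.0 (peaks that survive peak calling retain
#' some residual enrichment over the Dam-only control).
#'
#' @return 6 x 3 numeric matrix of per-condition log2 enrichments with
#'   rows `ND1..ND6` and columns `D`, `Grh`, `Ey`.
#' @export
defaultArchetypes <- function() {
    strong <- 3.0; weak <- 1.0
    m <- rbind(ND1 = c(strong, weak, weak),
               ND2 = c(strong, strong, weak),
               ND3 = c(weak, strong, weak),
               ND4 = c(strong, strong, strong),
               ND5 = c(weak, weak, strong),
               ND6 = c(weak, weak, weak))
    colnames(m) <- c("D", "Grh", "Ey")
    m
}

#' Specification of a synthetic DamID experiment
#'
#' Bundles every parameter of the generator: genome layout, planted
#' binding archetypes, replicate structure, sequencing depth and noise.
#' Defaults reproduce the study design: fusion replicate counts of
#' 4 (D), 5 (Grh) and 4 (Ey) against 8 Dam-only controls, the six
#' default binding archetypes, negative-binomial counts at 50 expected
#' reads per fragment and a log-normal per-fragment accessibility
#' background.
#'
#' @param nChroms Number of chromosomes (default 3).
#' @param chromLength Chromosome length in bp (default 1e5).
#' @param gatcMode `"random"` (i.i.d. uniform ACGT sequence, mean
#'   fragment ~256 bp) or `"fixed"` (GATC every `gatcSpacing` bp).
#' @param gatcSpacing Spacing for `gatcMode = "fixed"` (default 200).
#' @param archetypes Archetype matrix (rows = archetypes, columns =
#'   conditions, values = log2 enrichment); default
#'   [defaultArchetypes()].
#' @param sitesPerArchetype Planted sites per archetype (default 10).
#' @param siteWidthFragments Consecutive fragments per site (default 3).
#' @param fusionReplicates Named integer vector of fusion replicate
#'   counts per condition (default `c(D = 4, Grh = 5, Ey = 4)`); names
#'   must match the archetype columns.
#' @param controlReplicates Dam-only control replicates (default 8).
#' @param depth Expected reads per fragment (default 50).
#' @param dispersion Negative-binomial size parameter (default 10;
#'   larger is closer to Poisson).
#' @param accessibilitySd Log-normal sd of the per-fragment
#'   accessibility background (default 0.5).
#' @param seed RNG seed; one global stream drives genome, site placement
#'   and counts in that order.
#' @return A validated `SimulationSpec` (list).
#' @export
simulationSpec <- function(nChroms = 3L, chromLength = 1e5, gatcMode = c("random", "fixed"),
                           gatcSpacing = 200L, archetypes = defaultArchetypes(),
                           sitesPerArchetype = 10L, siteWidthFragments = 3L,
                           fusionReplicates = c(D = 4L, Grh = 5L, Ey = 4L),
                           controlReplicates = 8L, depth = 50, dispersion = 10,
                           accessibilitySd = 0.5, seed = 1L) {
    gatcMode <- match.arg(gatcMode)
    spec <- list(nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
                 gatcMode = gatcMode, gatcSpacing = as.integer(gatcSpacing),
                 archetypes = as.matrix(archetypes),
                 sitesPerArchetype = as.integer(sitesPerArchetype),
                 siteWidthFragments = as.integer(siteWidthFragments),
                 fusionReplicates = fusionReplicates,
                 controlReplicates = as.integer(controlReplicates),
                 depth = depth, dispersion = dispersion,
                 accessibilitySd = accessibilitySd, seed = as.integer(seed))
    stopifnot(spec$nChroms >= 1L, spec$chromLength >= 1L,
              spec$sitesPerArchetype >= 0L, spec$siteWidthFragments >= 1L,
              all(spec$fusionReplicates >= 1L), spec$controlReplicates >= 1L,
              spec$depth > 0, spec$dispersion > 0, spec$accessibilitySd >= 0)
    if (is.null(colnames(spec$archetypes)))
        stop("archetype matrix needs condition column names")
    if (is.null(names(spec$fusionReplicates)) ||
        !setequal(names(spec$fusionReplicates), colnames(spec$archetypes)))
        stop("fusionReplicates names must match archetype conditions")
    class(spec) <- "SimulationSpec"
    spec
}

#' Simulate a genome and its GATC fragment map
#'
#' Draws the genome sequence (seeding the simulation's global RNG
#' stream from `spec$seed`) and derives its fragment map via
#' [gatcFragmentMap()]. With `gatcMode = "random"` bases are i.i.d.
#' uniform, giving a mean fragment length near `4^4 = 256` bp; with
#' `gatcMode = "fixed"` a GATC motif is placed every `gatcSpacing` bp.
#'
#' @param spec A [simulationSpec()].
#' @return List with `genome` (a `DNAStringSet`) and `map`
#'   (a [FragmentMap-class]).
#' @export
simulateGenome <- function(spec) {
    stopifnot(inherits(spec, "SimulationSpec"))
    set.seed(spec$seed)
    nms <- sprintf("chr%d", seq_len(spec$nChroms))
    seqs <- vapply(seq_len(spec$nChroms), function(i) {
        if (spec$gatcMode == "random") {
            paste(sample(c("A", "C", "G", "T"), spec$chromLength, replace = TRUE),
                  collapse = "")
        } else {
            s <- spec$gatcSpacing
            if (s < 4L) stop("gatcSpacing must be >= 4")
            block <- paste0("GATC", strrep("A", s - 4L))
            substr(strrep(block, ceiling(spec$chromLength / s)), 1L,
                   spec$chromLength)
        }
    }, character(1))
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, nms))
    list(genome = genome, map = gatcFragmentMap(genome))
}

#' Plant non-overlapping binding sites on a fragment map
#'
#' Places `sitesPerArchetype` sites per archetype, each spanning
#' `siteWidthFragments` consecutive fragments of one chromosome,
#' uniformly at random without overlap (bounded rejection sampling).
#' Draws from the current RNG stream, i.e. directly after
#' [simulateGenome()] under the spec's global seed.
#'
#' @param spec A [simulationSpec()].
#' @param map The [FragmentMap-class] to plant on.
#' @return Truth `data.frame`: one row per site with `site_id`,
#'   `archetype`, `chrom`, `start`/`end` (0-based bp), and
#'   `frag_first`/`frag_last` (global fragment indices); per-condition
#'   enrichments are recoverable from `spec$archetypes`.
#' @export
plantSites <- function(spec, map) {
    stopifnot(inherits(spec, "SimulationSpec"))
    frag <- fragments(map)
    w <- spec$siteWidthFragments
    chrom <- as.character(seqnames(frag))
    ## starts whose w-fragment run stays on one chromosome
    ok <- seq_len(length(frag) - w + 1L)
    ok <- ok[chrom[ok] == chrom[ok + w - 1L]]
    nSites <- nrow(spec$archetypes) * spec$sitesPerArchetype
    if (nSites == 0L)
        return(data.frame(site_id = character(0), archetype = character(0),
                          chrom = character(0), start = integer(0), end = integer(0),
                          frag_first = integer(0), frag_last = integer(0)))
    if (length(ok) < nSites * w)
        stop("not enough fragments for the requested sites")
    taken <- logical(length(frag))
    picks <- integer(nSites)
    tries <- 0L; maxTries <- 1000L * nSites
    i <- 1L
    while (i <= nSites) {
        cand <- ok[sample.int(length(ok), 1L)]
        tries <- tries + 1L
        if (tries > maxTries) stop("site placement failed after bounded retries")
        if (any(taken[cand:(cand + w - 1L)])) next
        taken[cand:(cand + w - 1L)] <- TRUE
        picks[i] <- cand
        i <- i + 1L
    }
    labels <- rep(rownames(spec$archetypes), each = spec$sitesPerArchetype)
    data.frame(site_id = sprintf("site_%d", seq_len(nSites)),
               archetype = labels,
               chrom = chrom[picks],
               start = BiocGenerics::start(frag)[picks] - 1L,
               end = BiocGenerics::end(frag)[picks + w - 1L],
               frag_first = picks, frag_last = picks + w - 1L,
               stringsAsFactors = FALSE)
}

## Per-fragment log2 enrichment for one condition, from the truth table.
.enrichmentVector <- function(spec, map, truth, condition) {
    e <- numeric(nFragments(map))
    if (nrow(truth))
        for (i in seq_len(nrow(truth)))
            e[truth$frag_first[i]:truth$frag_last[i]] <-
                spec$archetypes[truth$archetype[i], condition]
    e
}

#' Simulate replicate fragment counts with planted enrichment
#'
#' Per fragment `i` an accessibility factor `a_i ~ LogNormal(0, sd)` is
#' shared by all samples; control counts are drawn
#' `NegBin(mean = depth * a_i, size = dispersion)` and fusion counts of
#' condition `c` as `NegBin(mean = depth * a_i * 2^e_ic)` with `e_ic`
#' the planted enrichment (0 off-site). Replicates are independent.
#' Draw order under the spec's global stream: accessibility, then
#' controls in replicate order, then conditions in archetype-column
#' order with their replicates.
#'
#' @param spec A [simulationSpec()].
#' @param map The [FragmentMap-class].
#' @param truth Truth table from [plantSites()].
#' @return List with `controls` (list of [BinnedCounts-class]) and
#'   `fusions` (named list per condition of lists of
#'   [BinnedCounts-class]).
#' @export
simulateCounts <- function(spec, map, truth) {
    stopifnot(inherits(spec, "SimulationSpec"))
    n <- nFragments(map)
    a <- stats::rlnorm(n, meanlog = 0, sdlog = spec$accessibilitySd)
    controls <- lapply(seq_len(spec$controlReplicates), function(r) {
        new("BinnedCounts", sampleId = sprintf("control_rep%d", r),
            counts = as.integer(stats::rnbinom(n, mu = spec$depth * a,
                                               size = spec$dispersion)))
    })
    conds <- colnames(spec$archetypes)
    fusions <- stats::setNames(lapply(conds, function(cn) {
        e <- .enrichmentVector(spec, map, truth, cn)
        mu <- spec$depth * a * 2^e
        lapply(seq_len(spec$fusionReplicates[[cn]]), function(r) {
            new("BinnedCounts", sampleId = sprintf("%s_rep%d", cn, r),
                counts = as.integer(stats::rnbinom(n, mu = mu,
                                                   size = spec$dispersion)))
        })
    }), conds)
    list(controls = controls, fusions = fusions)
}

#' Simulate a complete experiment
#'
#' Runs [simulateGenome()], [plantSites()] and [simulateCounts()] in
#' order under the spec's single seeded RNG stream.
#'
#' @param spec A [simulationSpec()].
#' @return List with `genome`, `map`, `truth`, `controls`, `fusions`.
#' @export
simulateExperiment <- function(spec) {
    g <- simulateGenome(spec)
    truth <- plantSites(spec, g$map)
    cnt <- simulateCounts(spec, g$map, truth)
    list(genome = g$genome, map = g$map, truth = truth,
         controls = cnt$controls, fusions = cnt$fusions)
}

#' Simulate a peak-intensity matrix directly from the archetypes
#'
#' Draws `nPerArchetype` peaks per archetype as the archetype's
#' per-condition enrichment vector plus i.i.d. Gaussian noise. This is
#' the intensity-space shortcut used to study the clustering stage in
#' isolation from read-level noise.
#'
#' @param nPerArchetype Peaks per archetype (default 100).
#' @param noiseSd Gaussian noise sd in log2 units (default 0.3).
#' @param archetypes Archetype matrix (default [defaultArchetypes()]).
#' @param seed RNG seed.
#' @return List with `matrix` (peaks x conditions) and `labels`
#'   (archetype of each row).
#' @export
simulateArchetypeMatrix <- function(nPerArchetype = 100L, noiseSd = 0.3,
                                    archetypes = defaultArchetypes(),
                                    seed = 1L) {
    set.seed(seed)
    k <- nrow(archetypes)
    labels <- rep(rownames(archetypes), each = nPerArchetype)
    mat <- archetypes[labels, , drop = FALSE] +
        matrix(stats::rnorm(k * nPerArchetype * ncol(archetypes), sd = noiseSd),
               ncol = ncol(archetypes))
    rownames(mat) <- sprintf("peak_%d", seq_len(nrow(mat)))
    list(matrix = mat, labels = labels)
}

#' Write the truth table as BED
#'
#' @param truth Truth table from [plantSites()].
#' @param path Output BED path (0-based half-open; name = site id,
#'   score column reused for the archetype label).
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(truth, path) {
    df <- data.frame(chrom = truth$chrom, start = truth$start, end = truth$end,
                     name = truth$site_id, archetype = truth$archetype)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Emit synthetic SAM records for a counted sample
#'
#' Writes one single-end read per count, placed at its fragment's start
#' on the + strand, to exercise the alignment-reading path end to end.
#' Read length is capped by the chromosome end.
#'
#' @param counts A [BinnedCounts-class].
#' @param map The matching [FragmentMap-class].
#' @param path Output SAM path.
#' @param readLength Read length in bp (default 50).
#' @return `path`, invisibly.
#' @export
writeSyntheticSAM <- function(counts, map, path, readLength = 50L) {
    frag <- fragments(map)
    cnt <- fragmentCounts(counts)
    if (length(cnt) != length(frag))
        stop("counts length does not match the fragment map")
    sl <- seqlengths(frag)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", names(sl), sl)), con)
    idx <- which(cnt > 0L)
    if (length(idx)) {
        chrom <- as.character(seqnames(frag))[idx]
        pos <- BiocGenerics::start(frag)[idx]   # 1-based SAM POS
        len <- pmin(readLength, sl[chrom] - pos + 1L)
        reps <- cnt[idx]
        lines <- sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                         paste0("read_", idx), chrom, pos, len,
                         strrep("A", len))
        lines <- rep(lines, reps)
        writeLines(lines, con)
    }
    invisible(path)
}
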