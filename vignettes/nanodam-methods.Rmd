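---
title: "NanoDam profiling of combinatorial transcription-factor binding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NanoDam profiling of combinatorial transcription-factor binding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanodam)
```

# Background

DamID-based methods such as NanoDam profile protein–DNA interactions
without antibodies or fixation. A trace amount of *E. coli* Dam
methylase, tethered to a transcription factor (TF) of interest, deposits
adenine methylation at GATC motifs near the factor's binding sites.
Sequencing methylation-marked fragments therefore reads out binding as
counts over the genomic intervals between consecutive GATC motifs — the
**GATC fragments** that are the atomic signal unit of the whole
pipeline. A Dam-only control, expressed in the same cells, captures
accessibility-driven background methylation; binding is quantified as a
fusion/control ratio.

This package implements the complete computational chain for a
three-factor experiment of this design — here the *Drosophila*
transcription factors D, Grh and Ey profiled in intermediate neural
progenitors against shared Dam-only controls — from genome
preprocessing through combinatorial-binding clusters (`ND1`–`ND6`) and
candidate gene selection, plus a calibrated synthetic-data generator
with planted ground truth that the test suite uses to validate every
stage.

# Pipeline model

## Fragment map and counting

`findGATCSites()` scans each chromosome for the 4-mer `GATC` (`N`
bases never match); `buildFragmentMap()` turns the motif start
coordinates plus the chromosome ends into a complete, gap-free tiling
of half-open fragments. A fragment starts at the start of a GATC motif,
so the motif belongs to its downstream fragment. Internally coordinates
are 1-based `GRanges`; every file format (BED, bedGraph, TSV) is
written and read 0-based half-open.

Alignments (BAM/SAM, primary and mapped only, default `min_mapq = 30`)
are reduced to their strand-aware 5′ base and assigned to the unique
fragment containing that base (`assignReadsToFragments()`). Duplicates
are kept by default; an optional `dedup` collapses identical
(chromosome, 5′ position, strand) triples. No read extension happens
here — extension is used only in the binned QC correlation below.

## Normalisation

For every (fusion replicate, control replicate) pair,
`pairwiseLogRatio()` computes per fragment

\[ r_i = \log_2\frac{f_i + p}{g_i + p} - \log_2\frac{F}{G}, \]

with pseudocount \(p = 0.5\) and library totals \(F, G\). The
pseudocount keeps 0/0 fragments at exactly zero; the library term
removes sequencing-depth differences. All pairwise tracks of one
condition are then **quantile normalised jointly**
(`quantileNormalizeTracks()`): at each rank position, every track's
value is replaced by the mean across tracks of the values at that rank,
and tied values share the mean of the rank means their tie group spans.
The tie rule is implemented directly (sort, rank means,
`ties.method = "first"` ranks, per-group averaging) because commonly
used interpolating implementations place ties at the value interpolated
at the *average* rank, which differs whenever the rank means are not
locally linear. After normalisation all tracks have identical sorted
values and the operation is idempotent.

`averageProfiles()` averages the normalised tracks per fragment in log
space; the linear profile is the backtransform \(2^{\bar r_i}\) and is
only used for export.

Note that the ratio tracks carry a constant offset determined by the
composition of the library: genuinely bound fragments inflate \(F\), so
unbound fragments sit slightly below zero and planted or expected
enrichments must always be read *relative to the background level*, not
against zero.

## Peak calling and consensus

`callPeaks()` tests, per fragment, the fusion count against a Poisson
null with mean \((g_i + p)\,F/G\), adjusts genome-wide with
Benjamini–Hochberg, and merges adjacent significant fragments
(`gapBp = 0` by default) into broad peaks whose score is the best
fragment FDR. The default threshold is deliberately extreme,
`q_max = 1e-25`: fragment counts are overdispersed relative to Poisson
(biological and accessibility noise), so moderate p-values are
unreliable, and only astronomically significant fragments are treated
as bound. `mergeConsensus()` unions the peaks of all pairwise
combinations of a condition and keeps an interval only if its best FDR
is below `fdr_max = 1e-25` **and** it occurs in strictly more than half
(`min_occurrence = 0.5`, strict `>`) of the combinations — a peak
supported by exactly 2 of 4 combinations is dropped.

## Clustering into binding-combination classes

The consensus sets of all conditions are unioned into a peak universe.
For each (peak, condition), `buildPeakIntensityMatrix()` aggregates the
averaged log2 profile over the peak, weighting each fragment by its
base-pair overlap and normalising by peak length, then z-scores each
condition column (sample standard deviation). `selectKAndCluster()`
runs Euclidean k-means (25 restarts, fixed seed) for each
\(k \in \{2,\dots,10\}\) and selects the \(k\) maximising the mean
silhouette width, ties towards the smaller \(k\). The resulting groups
are labelled `ND1`, `ND2`, … and represent classes of shared
combinatorial binding (e.g. strong D only; D and Grh; all three
factors; minimal binding of all three).

## Annotation and candidate selection

Peaks are assigned to the nearest transcription start site of a
protein-coding gene (`nearestTSS()`): distance zero if the TSS lies
inside the peak, otherwise the distance to the closest peak boundary,
ties broken to the lexicographically smaller gene ID. The canonical TSS
of a gene is the 5′-most TSS across its transcripts.
`selectCandidates()` is a strict three-way intersection: genes whose
peaks fall in a chosen ND cluster, that appear in a TF catalogue, and
that are significant markers (adjusted p below `p_max`, log fold change
at least `lfc_min`) of a chosen cell cluster in an external single-cell
expression table.

## Quality control

`binnedCorrelation()` computes Pearson correlations of bp-weighted
coverage in fixed 500-bp bins after extending reads 150 bp from their
5′ end (strand-aware). `rocLikeRecovery()` ranks one peak set by score
and traces the fraction of a reference set recovered.
`signalEnrichment()` builds a length-rescaled meta-profile over peaks
with ±50 % flanks. `fingerprintAndComplexity()` reports the cumulative
coverage curve of ascending-sorted bins (the diagonal for uniform
coverage) and the unique-read fraction.

# The synthetic generator

`simulationSpec()` fixes the study design as defaults: three
chromosomes of 100 kb with random uniform A/C/G/T sequence (expected
GATC spacing \(4^4 = 256\) bp, matching the genome-wide density of a
4-mer), 4 D, 5 Grh and 4 Ey fusion replicates against 8 shared Dam-only
controls, mean depth 50 reads/fragment, negative-binomial dispersion
`size = 10`, and log-normal fragment accessibility (sd 0.5) shared by
all samples — accessibility is a property of the chromatin, not of a
library.

Binding is planted as 10 disjoint 3-fragment sites per archetype from
the default archetype matrix `defaultArchetypes()`: six qualitative
D/Grh/Ey combination patterns with "strong" = 3.0 and
"weak/minimal" = 1.0 log2 units (`ND1` strong D; `ND2` strong D+Grh;
`ND3` strong Grh; `ND4` strong all; `ND5` strong Ey; `ND6` minimal
all). Control counts are
\( \mathrm{NB}(\mu = d\,a_i, \text{size}) \) and fusion counts
\( \mathrm{NB}(\mu = d\,a_i 2^{e_{ic}}, \text{size}) \). All draws come
from one global RNG stream seeded once, in documented order, so a spec
is fully reproducible. `simulateArchetypeMatrix()` is the
intensity-space shortcut (archetype row + Gaussian noise, default sd
0.3) used to study the clustering stage in isolation.

```{r archetypes}
defaultArchetypes()
```

Realism and limitations: the generator reproduces the count
overdispersion, shared accessibility background, replicate structure
and composition bias of the real assay, but does not model sequencing
errors, mappability, fragment-length selection or methylation
spreading. At the default strict consensus threshold, `ND6` sites
(2-fold in every condition, further shrunk by the composition offset)
are frequently *not* detected — a faithful property of the design, not
a bug; end-to-end validation therefore scores recovered, unambiguous
peaks.

# Numerical and design choices

- **Pseudocount 0.5** maps 0/0 fragments to exactly zero and keeps
  ratios finite without dominating counts at realistic depth.
- **Quantile normalisation is per condition by default**; passing all
  conditions' tracks at once normalises jointly instead.
- **Consensus FDR is the minimum contributor FDR** over the merged
  interval — consensus peaks answer "was any part of this region
  overwhelmingly significant, reproducibly?".
- **Strict `>` occurrence** makes "half of the combinations" fail, by
  construction, for even numbers of combinations.
- **Sample (n−1) standard deviation** in column z-scores, the `scale()`
  convention.
- **Silhouette-only model selection** with fixed restarts and seed:
  simple, deterministic given the seed, and validated on ground truth
  (the default archetype set yields a modal selection of 6 clusters
  across seeds).
- **Problem sizes**: the test suite runs genomes of 40–500 kb and
  matrices of up to 600 peaks; everything is exact small-scale
  validation against brute-force oracles plus distribution-level checks
  of the generator.

# A worked example

```{r example, eval = FALSE}
spec <- simulationSpec(seed = 1)
ex <- simulateExperiment(spec)

profiles <- list(); consensus <- list()
for (cn in colnames(spec$archetypes)) {
    tracks <- quantileNormalizeTracks(
        allPairwiseRatios(ex$fusions[[cn]], ex$controls))
    profiles[[cn]] <- averageProfiles(tracks, cn)
    sets <- list()
    for (f in ex$fusions[[cn]]) for (g in ex$controls)
        sets[[length(sets) + 1L]] <- callPeaks(f, g, ex$map)
    consensus[[cn]] <- mergeConsensus(sets)
}
universe <- combinePeakSets(consensus)
mat <- buildPeakIntensityMatrix(profiles, ex$map, universe)
res <- selectKAndCluster(mat)
res
```

The same chain is available as a configured pipeline
(`readRunConfig()` + `runSubcommand()`) and through the command-line
wrapper `inst/scripts/nanodam.R`.

# Session info

```{r session}
sessionInfo()
```
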