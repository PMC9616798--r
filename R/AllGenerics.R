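#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `fragments()` returns the GRanges backing a [FragmentMap-class],
#' `nFragments()` its length, `sampleId()` / `fragmentCounts()` /
#' `libraryTotal()` read a [BinnedCounts-class], `trackScores()` a
#' [RatioTrack-class], `meanLog2()` / `linearIntensity()` an
#' [AveragedProfile-class], `peakRanges()` a [PeakSet-class],
#' `intensityMatrix()` / `zscoreMatrix()` a [PeakIntensityMatrix-class],
#' and `clusterLabels()` / `selectedK()` / `silhouetteWidths()` a
#' [ClusteringResult-class].
#'
#' @param object An object of the matching class.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("nFragments", function(object) standardGeneric("nFragments"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("fragmentCounts", function(object) standardGeneric("fragmentCounts"))
#' @rdname accessors
#' @export
setGeneric("libraryTotal", function(object) standardGeneric("libraryTotal"))
#' @rdname accessors
#' @export
setGeneric("trackScores", function(object) standardGeneric("trackScores"))
#' @rdname accessors
#' @export
setGeneric("meanLog2", function(object) standardGeneric("meanLog2"))
#' @rdname accessors
#' @export
setGeneric("linearIntensity", function(object) standardGeneric("linearIntensity"))
#' @rdname accessors
#' @export
setGeneric("peakRanges", function(object) standardGeneric("peakRanges"))
#' @rdname accessors
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))
#' @rdname accessors
#' @export
setGeneric("zscoreMatrix", function(object) standardGeneric("zscoreMatrix"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("selectedK", function(object) standardGeneric("selectedK"))
#' @rdname accessors
#' @export
setGeneric("silhouetteWidths", function(object) standardGeneric("silhouetteWidths"))

#' @rdname accessors
setMethod("fragments", "FragmentMap", function(object) object@fragments)
#' @rdname accessors
setMethod("nFragments", "FragmentMap", function(object) length(object@fragments))
#' @rdname accessors
setMethod("sampleId", "BinnedCounts", function(object) object@sampleId)
#' @rdname accessors
setMethod("fragmentCounts", "BinnedCounts", function(object) object@counts)
#' @rdname accessors
setMethod("libraryTotal", "BinnedCounts", function(object) sum(object@counts))
#' @rdname accessors
setMethod("trackScores", "RatioTrack", function(object) object@scores)
#' @rdname accessors
setMethod("meanLog2", "AveragedProfile", function(object) object@meanLog2)
#' @rdname accessors
setMethod("linearIntensity", "AveragedProfile", function(object) 2^object@meanLog2)
#' @rdname accessors
setMethod("peakRanges", "PeakSet", function(object) object@peaks)
#' @rdname accessors
setMethod("intensityMatrix", "PeakIntensityMatrix", function(object) object@intensity)
#' @rdname accessors
setMethod("zscoreMatrix", "PeakIntensityMatrix", function(object) object@zscore)
#' @rdname accessors
setMethod("clusterLabels", "ClusteringResult", function(object) object@labels)
#' @rdname accessors
setMethod("selectedK", "ClusteringResult", function(object) object@k)
#' @rdname accessors
setMethod("silhouetteWidths", "ClusteringResult", function(object) object@silhouette)

#' @rdname accessors
#' @export
setMethod("length", "PeakSet", function(x) length(x@peaks))
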