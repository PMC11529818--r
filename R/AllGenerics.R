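#' Frame rate of a time-resolved object
#'
#' @param x a [Keypoint3DTrack-class], [ObservableSeries-class] or
#'   [Ethogram-class] object.
#' @return Frame rate in Hz (scalar numeric).
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Number of frames
#'
#' @param x a time-resolved object.
#' @return Integer number of frames.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Body-part names of a keypoint track
#'
#' @param x a [Keypoint3DTrack-class].
#' @return Character vector of part names.
#' @export
setGeneric("partNames", function(x) standardGeneric("partNames"))

#' Extract the 3D coordinate series of one body part
#'
#' @param x a [Keypoint3DTrack-class].
#' @param part part name.
#' @return numeric matrix (frames x 3), `NA` rows where invalid.
#' @export
setGeneric("partCoords", function(x, part) standardGeneric("partCoords"))

#' Per-frame, per-part validity flags
#'
#' @param x a [Keypoint3DTrack-class].
#' @return logical matrix (frames x parts).
#' @export
setGeneric("partValid", function(x) standardGeneric("partValid"))

#' Extract one derived signal from an observable series
#'
#' @param x an [ObservableSeries-class].
#' @param signal signal name (see [observableNames()]).
#' @return numeric vector, `NA` at invalid frames.
#' @export
setGeneric("getSignal", function(x, signal) standardGeneric("getSignal"))

#' Per-frame action flags of an ethogram
#'
#' @param x an [Ethogram-class].
#' @return logical matrix (frames x actions) with `NA` where the action is
#'   indeterminate because a required observable is invalid.
#' @export
setGeneric("actionFlags", function(x) standardGeneric("actionFlags"))

#' Per-frame unknown mask of an ethogram
#'
#' @param x an [Ethogram-class].
#' @return logical vector, `TRUE` where any action flag is indeterminate.
#' @export
setGeneric("unknownMask", function(x) standardGeneric("unknownMask"))

#' Node metadata table of a connectome graph
#'
#' @param x a [ConnectomeGraph-class].
#' @return data.frame with columns `id`, `type`, `hemisphere`.
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' Edge table of a connectome graph
#'
#' @param x a [ConnectomeGraph-class].
#' @return data.frame with columns `pre`, `post`, `count` and the six
#'   per-neurotransmitter synapse counts.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Synapse-count cutoff applied to a connectome graph
#'
#' @param x a [ConnectomeGraph-class].
#' @return scalar numeric.
#' @export
setGeneric("synapseCutoff", function(x) standardGeneric("synapseCutoff"))

#' Equivalent-weight matrix values
#'
#' @param x an [EquivalentWeightMatrix-class].
#' @return numeric matrix (sources x targets).
#' @export
setGeneric("eqWeights", function(x) standardGeneric("eqWeights"))

#' Neurotransmitter path-type tensor
#'
#' @param x an [EquivalentWeightMatrix-class] computed with `ntPaths = TRUE`.
#' @return 4-d array (sources x targets x 6 x 6), first-edge NT by
#'   second-edge NT; `NULL` when not computed.
#' @export
setGeneric("ntPathArray", function(x) standardGeneric("ntPathArray"))

#' Cluster labels
#'
#' @param x a [ClusterResult-class].
#' @return named integer vector of cluster indices.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
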