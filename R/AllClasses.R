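#' @include AllGenerics.R
NULL

## Canonical orderings used throughout the package.

#' Neurotransmitter channel names
#'
#' Order of the six per-synapse neurotransmitter predictions used in edge
#' tables and path-type tensors: GABA, acetylcholine, glutamate, octopamine,
#' serotonin, dopamine.
#' @return character vector of length 6.
#' @export
ntNames <- function() c("gaba", "ach", "glut", "oct", "ser", "da")

#' Action label names
#'
#' The four rule-based action labels of the ethogram. The three wing labels
#' are mutually exclusive; the alert stance may co-occur with any of them.
#' @return character vector of length 4.
#' @export
actionNames <- function() c("wing_threat", "wing_extension", "low_wing_threat", "alert")

#' Observable signal names
#'
#' @return character vector naming the derived kinematic signals.
#' @export
observableNames <- function() {
  c("speed", "left_pitch", "right_pitch", "offset_angle", "elevation",
    "left_wing_elevation", "right_wing_elevation",
    "left_wing_azimuth", "right_wing_azimuth", "wingspan")
}

## ---------------------------------------------------------------------------
## Pixel statistics (video foreground segmentation)

#' Per-pixel temporal statistics of a video
#'
#' Holds the per-pixel temporal mean, standard deviation and log10
#' coefficient of variation (LCV) of a grayscale frame stack, the inputs to
#' the LCV foreground rule.
#'
#' @slot mean per-pixel temporal mean (matrix, intensity units).
#' @slot sd per-pixel temporal standard deviation (matrix).
#' @slot lcv per-pixel \eqn{\log_{10}(\sigma/\mu)} (matrix, dimensionless);
#'   `NA` where undefined.
#' @slot defined logical matrix, `FALSE` where \eqn{\mu \le 0} or
#'   \eqn{\sigma = 0} so the LCV is undefined.
#' @slot nFrames number of frames the statistics were computed over.
#' @seealso [pixelStats()], [lcvForegroundMask()]
#' @export
setClass("PixelStatsImage",
  slots = c(mean = "matrix", sd = "matrix", lcv = "matrix",
            defined = "matrix", nFrames = "integer"))

setValidity("PixelStatsImage", function(object) {
  d <- dim(object@mean)
  if (!identical(dim(object@sd), d) || !identical(dim(object@lcv), d) ||
      !identical(dim(object@defined), d))
    return("mean, sd, lcv and defined must share dimensions")
  if (any(object@sd < 0, na.rm = TRUE)) return("sd must be nonnegative")
  TRUE
})

setMethod("show", "PixelStatsImage", function(object) {
  cat(sprintf("PixelStatsImage: %d x %d pixels over %d frames; %.1f%% LCV-defined\n",
              nrow(object@mean), ncol(object@mean), object@nFrames,
              100 * mean(object@defined)))
})

## ---------------------------------------------------------------------------
## Cameras and calibration

#' DLT camera model
#'
#' Standard 11-parameter direct linear transformation camera: a 3D point
#' `(x,y,z)` projects to pixel coordinates
#' \deqn{u = (L_1 x + L_2 y + L_3 z + L_4)/(L_9 x + L_{10} y + L_{11} z + 1)}
#' \deqn{v = (L_5 x + L_6 y + L_7 z + L_8)/(L_9 x + L_{10} y + L_{11} z + 1)}
#' Lens distortion is not modelled.
#'
#' @slot coef numeric vector of the 11 DLT coefficients.
#' @slot id camera label.
#' @seealso [dltCalibrate()], [dltProject()], [triangulatePoints()]
#' @export
setClass("CameraModel", slots = c(coef = "numeric", id = "character"))

setValidity("CameraModel", function(object) {
  if (length(object@coef) != 11L) return("coef must have length 11")
  if (any(!is.finite(object@coef))) return("coef must be finite")
  TRUE
})

setMethod("show", "CameraModel", function(object) {
  cat(sprintf("CameraModel '%s': 11-parameter DLT\n", object@id))
})

#' Calibration point set
#'
#' Known 3D positions (e.g. a microbead moved through a box of positions)
#' with their observed 2D pixel positions in each camera. A point is
#' reconstructable only if visible in at least two cameras.
#'
#' @slot points3d numeric matrix (n x 3) of known 3D positions.
#' @slot observations named list, one entry per camera, each a list with
#'   `uv` (n x 2 pixel positions) and `visible` (logical n).
#' @slot units length unit of `points3d` ("mm" or "um"); declared, never
#'   inferred.
#' @export
setClass("CalibrationSet",
  slots = c(points3d = "matrix", observations = "list", units = "character"))

setValidity("CalibrationSet", function(object) {
  if (ncol(object@points3d) != 3L) return("points3d must be n x 3")
  n <- nrow(object@points3d)
  for (cam in names(object@observations)) {
    ob <- object@observations[[cam]]
    if (!all(c("uv", "visible") %in% names(ob)))
      return("each observation entry needs uv and visible")
    if (nrow(ob$uv) != n || length(ob$visible) != n)
      return(sprintf("camera '%s': observation length mismatch", cam))
  }
  if (!object@units %in% c("mm", "um"))
    return("units must be 'mm' or 'um'")
  TRUE
})

setMethod("show", "CalibrationSet", function(object) {
  vis <- vapply(object@observations, function(o) sum(o$visible), 0)
  cat(sprintf("CalibrationSet: %d points (%s), %d cameras (visible: %s)\n",
              nrow(object@points3d), object@units, length(object@observations),
              paste(vis, collapse = "/")))
})

## ---------------------------------------------------------------------------
## Arena geometry

#' Arena wall geometry
#'
#' The walls of the behavioural arena, each given as a set of >= 3 coplanar
#' 3D points (typically the four corners of a rectangular wall). Wall normals
#' are computed as the third right-singular vector of the zero-centred point
#' set. Nearest-wall ties are broken by list order.
#'
#' @slot walls list of numeric matrices (>= 3 x 3), one per wall, in the
#'   order used for tie-breaking.
#' @seealso [arenaBox()], [elevationAngle()]
#' @export
setClass("ArenaGeometry", slots = c(walls = "list"))

setValidity("ArenaGeometry", function(object) {
  if (length(object@walls) < 1L) return("at least one wall required")
  for (w in object@walls) {
    if (!is.matrix(w) || ncol(w) != 3L || nrow(w) < 3L)
      return("each wall must be a >=3 x 3 point matrix")
    ctr <- scale(w, center = TRUE, scale = FALSE)
    sv <- svd(ctr)$d
    if (length(sv) >= 3 && sv[3] > 1e-6 * max(sv[1], 1))
      return("wall points must be coplanar")
  }
  TRUE
})

setMethod("show", "ArenaGeometry", function(object) {
  cat(sprintf("ArenaGeometry: %d walls\n", length(object@walls)))
})

## ---------------------------------------------------------------------------
## Keypoint tracks

#' Triangulated 3D body-part track
#'
#' Per-frame 3D positions and validity flags for the named body parts of one
#' fly over one trial. Parts are invalid where the originating 2D confidence
#' fell below threshold or fewer than two camera views saw the part.
#'
#' @slot frameRate acquisition rate in Hz (100 for the free-walking rig,
#'   25 for the head-fixed DMD rig).
#' @slot coords numeric array (frames x 3 x parts); coordinates in the rig's
#'   declared length unit.
#' @slot valid logical matrix (frames x parts).
#' @seealso [keypointTrack()], [interpolateGaps()], [computeObservables()]
#' @export
setClass("Keypoint3DTrack",
  slots = c(frameRate = "numeric", coords = "array", valid = "matrix"))

setValidity("Keypoint3DTrack", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3L || d[2] != 3L) return("coords must be frames x 3 x parts")
  if (!identical(dim(object@valid), d[c(1L, 3L)]))
    return("valid must be frames x parts")
  if (is.null(dimnames(object@coords)[[3]])) return("parts must be named")
  if (!identical(colnames(object@valid), dimnames(object@coords)[[3]]))
    return("valid column names must match part names")
  if (length(object@frameRate) != 1L || object@frameRate <= 0)
    return("frameRate must be a positive scalar")
  TRUE
})

#' Construct a Keypoint3DTrack
#'
#' @param coords numeric array (frames x 3 x parts) with named parts, or a
#'   named list of (frames x 3) matrices.
#' @param valid logical matrix (frames x parts); defaults to rows with all
#'   finite coordinates.
#' @param frameRate frames per second.
#' @return a [Keypoint3DTrack-class].
#' @examples
#' xyz <- array(rnorm(10 * 3 * 2), c(10, 3, 2),
#'              dimnames = list(NULL, c("x", "y", "z"), c("head", "thorax")))
#' keypointTrack(xyz, frameRate = 100)
#' @export
keypointTrack <- function(coords, valid = NULL, frameRate) {
  if (is.list(coords)) {
    parts <- names(coords)
    coords <- array(unlist(coords, use.names = FALSE),
                    dim = c(nrow(coords[[1]]), 3L, length(parts)),
                    dimnames = list(NULL, c("x", "y", "z"), parts))
  }
  if (is.null(dimnames(coords)[[2]])) dimnames(coords)[[2]] <- c("x", "y", "z")
  if (is.null(valid)) {
    valid <- apply(is.finite(coords), c(1L, 3L), all)
  }
  colnames(valid) <- dimnames(coords)[[3]]
  methods::new("Keypoint3DTrack", frameRate = frameRate,
               coords = coords, valid = valid)
}

#' @rdname frameRate
setMethod("frameRate", "Keypoint3DTrack", function(x) x@frameRate)
#' @rdname nFrames
setMethod("nFrames", "Keypoint3DTrack", function(x) dim(x@coords)[1])
#' @rdname partNames
setMethod("partNames", "Keypoint3DTrack", function(x) dimnames(x@coords)[[3]])
#' @rdname partValid
setMethod("partValid", "Keypoint3DTrack", function(x) x@valid)

#' @rdname partCoords
setMethod("partCoords", "Keypoint3DTrack", function(x, part) {
  if (!part %in% partNames(x)) stop("unknown part: ", part)
  m <- x@coords[, , part, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
  colnames(m) <- c("x", "y", "z")
  m[!x@valid[, part], ] <- NA_real_
  m
})

setMethod("show", "Keypoint3DTrack", function(object) {
  cat(sprintf("Keypoint3DTrack: %d frames @ %g Hz, parts: %s (%.1f%% valid)\n",
              nFrames(object), object@frameRate,
              paste(partNames(object), collapse = ", "),
              100 * mean(object@valid)))
})

## ---------------------------------------------------------------------------
## Observable series

#' Derived kinematic observables
#'
#' Time-aligned signals derived from a [Keypoint3DTrack-class]: speed (mm/s),
#' left/right wing pitch (deg, 0-180), wing offset angle (deg, 0-45), body
#' elevation vs. the nearest arena surface (deg, 0-90), wing
#' elevation/azimuth from frontal/medial plane projections (deg), and
#' wingspan (length units). Invalidity is encoded as `NA` and propagates
#' exactly from the body parts each signal depends on.
#'
#' @slot frameRate Hz.
#' @slot signals numeric matrix (frames x signals); columns named as in
#'   [observableNames()] (a subset may be present).
#' @seealso [computeObservables()], [classifyFrames()]
#' @export
setClass("ObservableSeries",
  slots = c(frameRate = "numeric", signals = "matrix"))

setValidity("ObservableSeries", function(object) {
  if (is.null(colnames(object@signals))) return("signals must have column names")
  if (!all(colnames(object@signals) %in% observableNames()))
    return("unknown signal name")
  ok <- function(v, lo, hi) all(v >= lo - 1e-9 & v <= hi + 1e-9, na.rm = TRUE)
  s <- object@signals
  if ("left_pitch" %in% colnames(s) && !ok(s[, "left_pitch"], 0, 180))
    return("left_pitch out of [0,180]")
  if ("right_pitch" %in% colnames(s) && !ok(s[, "right_pitch"], 0, 180))
    return("right_pitch out of [0,180]")
  if ("offset_angle" %in% colnames(s) && !ok(s[, "offset_angle"], 0, 45))
    return("offset_angle out of [0,45]")
  TRUE
})

#' Construct an ObservableSeries
#'
#' @param signals numeric matrix or data.frame of signals (frames x signals),
#'   `NA` marking invalid frames.
#' @param frameRate frames per second.
#' @return an [ObservableSeries-class].
#' @export
observableSeries <- function(signals, frameRate) {
  methods::new("ObservableSeries", frameRate = frameRate,
               signals = as.matrix(signals))
}

#' @rdname frameRate
setMethod("frameRate", "ObservableSeries", function(x) x@frameRate)
#' @rdname nFrames
setMethod("nFrames", "ObservableSeries", function(x) nrow(x@signals))

#' @rdname getSignal
setMethod("getSignal", "ObservableSeries", function(x, signal) {
  if (!signal %in% colnames(x@signals)) stop("signal not present: ", signal)
  x@signals[, signal]
})

#' Per-signal validity masks
#'
#' @param x an [ObservableSeries-class].
#' @return logical matrix (frames x signals), `TRUE` where valid.
#' @export
validMask <- function(x) {
  stopifnot(methods::is(x, "ObservableSeries"))
  !is.na(x@signals)
}

setMethod("show", "ObservableSeries", function(object) {
  cat(sprintf("ObservableSeries: %d frames @ %g Hz, signals: %s\n",
              nFrames(object), object@frameRate,
              paste(colnames(object@signals), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Ethogram

#' Rule-based action ethogram
#'
#' Per-frame labels for the four scored actions. The three wing labels
#' (wing threat, wing extension, low wing threat) are mutually exclusive;
#' the alert stance is scored independently and may co-occur. A label is `NA`
#' at frames where an observable it depends on is invalid; the unknown mask
#' marks frames where any label is indeterminate.
#'
#' @slot frameRate Hz.
#' @slot labels logical matrix (frames x 4), columns as in [actionNames()];
#'   `NA` where indeterminate.
#' @seealso [classifyFrames()], [extractBouts()], [firstBoutLatency()]
#' @export
setClass("Ethogram", slots = c(frameRate = "numeric", labels = "matrix"))

setValidity("Ethogram", function(object) {
  if (!identical(colnames(object@labels), actionNames()))
    return("labels columns must be the four action names")
  wing <- object@labels[, c("wing_threat", "wing_extension", "low_wing_threat"),
                        drop = FALSE]
  n_true <- rowSums(wing, na.rm = TRUE)
  if (any(n_true > 1L)) return("wing labels must be mutually exclusive")
  TRUE
})

#' Construct an Ethogram
#'
#' @param labels logical matrix (frames x 4) with columns [actionNames()];
#'   `NA` marks indeterminate frames.
#' @param frameRate frames per second.
#' @return an [Ethogram-class].
#' @export
ethogram <- function(labels, frameRate) {
  methods::new("Ethogram", frameRate = frameRate, labels = labels)
}

#' @rdname frameRate
setMethod("frameRate", "Ethogram", function(x) x@frameRate)
#' @rdname nFrames
setMethod("nFrames", "Ethogram", function(x) nrow(x@labels))
#' @rdname actionFlags
setMethod("actionFlags", "Ethogram", function(x) x@labels)
#' @rdname unknownMask
setMethod("unknownMask", "Ethogram", function(x) rowSums(is.na(x@labels)) > 0L)

setMethod("show", "Ethogram", function(object) {
  fr <- colMeans(object@labels, na.rm = TRUE)
  cat(sprintf("Ethogram: %d frames @ %g Hz (%.1f%% unknown)\n",
              nFrames(object), object@frameRate,
              100 * mean(unknownMask(object))))
  for (a in actionNames())
    cat(sprintf("  %-16s %.1f%% of determinate frames\n", a, 100 * fr[[a]]))
})

## ---------------------------------------------------------------------------
## Connectome graph

#' Directed synapse graph
#'
#' Nodes are neurons with an id, a type label (e.g. CL062, pC1a, aIPg1 or a
#' DN name) and a hemisphere. Edges are directed pre -> post connections
#' carrying a synapse count and its decomposition into the six
#' neurotransmitter channels ([ntNames()]); each synapse is assigned exactly
#' one most-confident NT, so the six counts sum to the synapse count. Edges
#' below the synapse cutoff are dropped at construction, before any path
#' computation.
#'
#' @slot nodes data.frame with columns `id` (character), `type`, `hemisphere`.
#' @slot edges data.frame with columns `pre`, `post`, `count` and the six
#'   NT count columns.
#' @slot synapseCutoff the cutoff applied (default 10).
#' @seealso [connectomeGraph()], [equivalentWeight()]
#' @export
setClass("ConnectomeGraph",
  slots = c(nodes = "data.frame", edges = "data.frame", synapseCutoff = "numeric"))

setValidity("ConnectomeGraph", function(object) {
  if (!all(c("id", "type", "hemisphere") %in% names(object@nodes)))
    return("nodes needs id, type, hemisphere")
  if (anyDuplicated(object@nodes$id)) return("node ids must be unique")
  req <- c("pre", "post", "count", ntNames())
  if (!all(req %in% names(object@edges)))
    return("edges needs pre, post, count and the six NT columns")
  e <- object@edges
  if (nrow(e)) {
    if (!all(e$pre %in% object@nodes$id) || !all(e$post %in% object@nodes$id))
      return("edge referencing unknown node")
    nt_sum <- rowSums(as.matrix(e[, ntNames()]))
    if (any(abs(nt_sum - e$count) > 1e-9)) return("inconsistent NT counts")
    if (any(e$count < object@synapseCutoff))
      return("edge below synapse cutoff retained")
    if (any(e$pre == e$post)) return("self-loops must be dropped")
    if (anyDuplicated(paste(e$pre, e$post))) return("duplicate edges")
  }
  TRUE
})

#' @rdname nodeTable
setMethod("nodeTable", "ConnectomeGraph", function(x) x@nodes)
#' @rdname edgeTable
setMethod("edgeTable", "ConnectomeGraph", function(x) x@edges)
#' @rdname synapseCutoff
setMethod("synapseCutoff", "ConnectomeGraph", function(x) x@synapseCutoff)

setMethod("show", "ConnectomeGraph", function(object) {
  cat(sprintf("ConnectomeGraph: %d neurons, %d edges (cutoff %g synapses)\n",
              nrow(object@nodes), nrow(object@edges), object@synapseCutoff))
  tt <- sort(table(object@nodes$type), decreasing = TRUE)
  cat("  types: ", paste(sprintf("%s(%d)", names(tt), tt), collapse = " "),
      "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Equivalent weights

#' Source-by-target equivalent weight matrix
#'
#' Resistor-circuit equivalent connection weights from each source neuron to
#' each target neuron, summing the direct edge weight and the series weights
#' \eqn{W_1 W_2/(W_1+W_2)} of all one-intermediate paths. Optionally carries
#' the neurotransmitter path-type tensor: for each (source, target), a 6 x 6
#' matrix over (first-edge NT, second-edge NT) with direct edges placed on
#' the diagonal; the tensor sums to the scalar weight.
#'
#' @slot weights numeric matrix (sources x targets).
#' @slot ntPaths numeric array (sources x targets x 6 x 6), or a
#'   zero-length array when the decomposition was not requested.
#' @seealso [equivalentWeightMatrix()], [ntPathwaySummary()]
#' @export
setClass("EquivalentWeightMatrix",
  slots = c(weights = "matrix", ntPaths = "array"))

setValidity("EquivalentWeightMatrix", function(object) {
  if (is.null(rownames(object@weights)) || is.null(colnames(object@weights)))
    return("weights must have source/target dimnames")
  if (any(object@weights < 0)) return("weights must be nonnegative")
  if (length(object@ntPaths)) {
    d <- dim(object@ntPaths)
    if (length(d) != 4L || !identical(d[1:2], dim(object@weights)) ||
        any(d[3:4] != 6L))
      return("ntPaths must be sources x targets x 6 x 6")
    tot <- apply(object@ntPaths, c(1L, 2L), sum)
    if (max(abs(tot - object@weights)) > 1e-6 * max(1, max(object@weights)))
      return("ntPaths must sum to weights (conservation)")
  }
  TRUE
})

#' @rdname eqWeights
setMethod("eqWeights", "EquivalentWeightMatrix", function(x) x@weights)
#' @rdname ntPathArray
setMethod("ntPathArray", "EquivalentWeightMatrix",
          function(x) if (length(x@ntPaths)) x@ntPaths else NULL)

setMethod("show", "EquivalentWeightMatrix", function(object) {
  cat(sprintf("EquivalentWeightMatrix: %d sources x %d targets%s\n",
              nrow(object@weights), ncol(object@weights),
              if (length(object@ntPaths)) " (NT-resolved)" else ""))
  cat(sprintf("  weight range: [%.3g, %.3g]\n",
              min(object@weights), max(object@weights)))
})

## ---------------------------------------------------------------------------
## Clustering / biplot results

#' Hierarchical clustering of sources by target-connectivity similarity
#'
#' @slot labels named integer vector of cluster indices.
#' @slot similarity cosine similarity matrix among sources.
#' @slot linkage the `hclust` merge record.
#' @seealso [clusterSources()]
#' @export
setClass("ClusterResult",
  slots = c(labels = "integer", similarity = "matrix", linkage = "ANY"))

#' @rdname clusterLabels
setMethod("clusterLabels", "ClusterResult", function(x) x@labels)

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: %d sources in %d clusters (sizes %s)\n",
              length(object@labels), length(unique(object@labels)),
              paste(table(object@labels), collapse = "/")))
})

#' PCA biplot of an equivalent-weight matrix
#'
#' Scores are the top-3 principal-component scores of the Euclidean-row-
#' normalized weight matrix, rescaled so the most extreme score lies at the
#' radius of the most extreme loading (biplot convention); loadings are
#' unscaled.
#'
#' @slot scores numeric matrix (rows x 3), scaled scores.
#' @slot loadings numeric matrix (targets x 3).
#' @slot varianceExplained fractions of variance of the first three PCs.
#' @slot rowTotals total equivalent weight per retained row.
#' @slot centered logical; whether rows were mean-centred before the
#'   eigendecomposition.
#' @seealso [pcaBiplot()], [svmPlanes()], [topLoadings()]
#' @export
setClass("BiplotResult",
  slots = c(scores = "matrix", loadings = "matrix",
            varianceExplained = "numeric", rowTotals = "numeric",
            centered = "logical"))

setValidity("BiplotResult", function(object) {
  v <- object@varianceExplained
  if (length(v) != 3L || any(v <= 0) || any(v > 1 + 1e-9))
    return("varianceExplained must be 3 fractions in (0,1]")
  if (any(diff(v) > 1e-9)) return("varianceExplained must be non-increasing")
  TRUE
})

setMethod("show", "BiplotResult", function(object) {
  cat(sprintf("BiplotResult: %d rows, %d targets; PC1-3 variance %.2f%%/%.2f%%/%.2f%% (%s)\n",
              nrow(object@scores), nrow(object@loadings),
              100 * object@varianceExplained[1], 100 * object@varianceExplained[2],
              100 * object@varianceExplained[3],
              if (object@centered) "centred" else "uncentred"))
})
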