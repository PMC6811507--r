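#' @name accessors
#' @title Accessors for cvrflow data objects
#' @description Slot accessors for the S4 containers: velocity and magnitude
#'   arrays, voxel spacing, Venc, angiogram intensity, tree nodes/edges and
#'   phantom-truth tables.
#' @param object a cvrflow S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("velocityData", function(object) standardGeneric("velocityData"))
#' @rdname accessors
#' @export
setGeneric("magnitudeData", function(object) standardGeneric("magnitudeData"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("venc", function(object) standardGeneric("venc"))
#' @rdname accessors
#' @export
setGeneric("phaseData", function(object) standardGeneric("phaseData"))
#' @rdname accessors
#' @export
setGeneric("intensityData", function(object) standardGeneric("intensityData"))
#' @rdname accessors
#' @export
setGeneric("treeNodes", function(object) standardGeneric("treeNodes"))
#' @rdname accessors
#' @export
setGeneric("treeEdges", function(object) standardGeneric("treeEdges"))
#' @rdname accessors
#' @export
setGeneric("truthMeasurements", function(object) standardGeneric("truthMeasurements"))
#' @rdname accessors
#' @export
setGeneric("truthSlopes", function(object) standardGeneric("truthSlopes"))
#' @rdname accessors
#' @export
setGeneric("truthGlobalFlow", function(object) standardGeneric("truthGlobalFlow"))
#' @rdname accessors
#' @export
setGeneric("studyVolumes", function(object) standardGeneric("studyVolumes"))
#' @rdname accessors
#' @export
setGeneric("studyConditions", function(object) standardGeneric("studyConditions"))
#' @rdname accessors
#' @export
setGeneric("studySeeds", function(object) standardGeneric("studySeeds"))
#' @rdname accessors
#' @export
setGeneric("studyTruth", function(object) standardGeneric("studyTruth"))

#' @rdname accessors
setMethod("velocityData", "VelocityVolume", function(object) object@velocity)
#' @rdname accessors
setMethod("magnitudeData", "VelocityVolume", function(object) object@magnitude)
#' @rdname accessors
setMethod("voxelSize", "VelocityVolume", function(object) object@voxelSize)
#' @rdname accessors
setMethod("venc", "VelocityVolume", function(object) object@venc)
#' @rdname accessors
setMethod("phaseData", "EncodedVolume", function(object) object@phase)
#' @rdname accessors
setMethod("magnitudeData", "EncodedVolume", function(object) object@magnitude)
#' @rdname accessors
setMethod("voxelSize", "EncodedVolume", function(object) object@voxelSize)
#' @rdname accessors
setMethod("venc", "EncodedVolume", function(object) object@venc)
#' @rdname accessors
setMethod("intensityData", "Angiogram", function(object) object@intensity)
#' @rdname accessors
setMethod("voxelSize", "Angiogram", function(object) object@voxelSize)
#' @rdname accessors
setMethod("treeNodes", "VesselTree", function(object) object@nodes)
#' @rdname accessors
setMethod("treeEdges", "VesselTree", function(object) object@edges)
#' @rdname accessors
setMethod("voxelSize", "VesselTree", function(object) object@voxelSize)
#' @rdname accessors
setMethod("truthMeasurements", "PhantomTruth", function(object) object@measurements)
#' @rdname accessors
setMethod("truthSlopes", "PhantomTruth", function(object) object@slopes)
#' @rdname accessors
setMethod("truthGlobalFlow", "PhantomTruth", function(object) object@globalFlow)
#' @rdname accessors
setMethod("studyVolumes", "PhantomStudy", function(object) object@volumes)
#' @rdname accessors
setMethod("studyConditions", "PhantomStudy", function(object) object@conditions)
#' @rdname accessors
setMethod("studySeeds", "PhantomStudy", function(object) object@seeds)
#' @rdname accessors
setMethod("studyTruth", "PhantomStudy", function(object) object@truth)
#' @rdname accessors
setMethod("truthMeasurements", "PhantomStudy", function(object) object@truth@measurements)

setMethod("show", "VelocityVolume", function(object) {
  d <- dim(object@velocity)
  cat(
    "VelocityVolume:", paste(d[1:3], collapse = " x "), "voxels,",
    format(object@voxelSize, digits = 3), "cm isotropic, Venc",
    object@venc, "cm/s\n"
  )
  vn <- max(abs(object@velocity))
  cat("  max |velocity component|:", format(vn, digits = 4), "cm/s\n")
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  }
})

setMethod("show", "EncodedVolume", function(object) {
  d <- dim(object@phase)
  cat(
    "EncodedVolume:", paste(d[1:3], collapse = " x "),
    "voxels, 3 encoding axes, Venc", object@venc, "cm/s\n"
  )
})

setMethod("show", "Angiogram", function(object) {
  cat(
    "Angiogram (", object@provenance, "): ",
    paste(dim(object@intensity), collapse = " x "),
    " voxels, max intensity ", format(max(object@intensity), digits = 4),
    "\n",
    sep = ""
  )
})

setMethod("show", "VesselTree", function(object) {
  nd <- object@nodes
  cat(
    "VesselTree:", nrow(nd), "nodes,", nrow(object@edges), "edges;",
    sum(nd$flag == "junction"), "junctions,",
    sum(nd$flag == "endpoint"), "endpoints\n"
  )
  labs <- setdiff(unique(nd$label), "unlabeled")
  if (length(labs)) {
    for (l in sort(labs)) {
      cat(
        "  ", l, ": ", sum(nd$label == l), " nodes (",
        sum(nd$label == l & nd$measurement), " measurement)\n",
        sep = ""
      )
    }
  }
})

setMethod("show", "PhantomStudy", function(object) {
  cat(
    "PhantomStudy:", length(object@volumes), "conditions,",
    length(object@seeds), "labeled vessels\n"
  )
  print(object@conditions, row.names = FALSE)
})

setMethod("show", "CVRFit", function(object) {
  cat(
    "CVRFit [", object@scope, "]: slope ",
    format(object@slope, digits = 5), " CVC-units/mmHg, intercept ",
    format(object@intercept, digits = 5), " (", object@nPoints,
    " points, ", object@mode, ")\n",
    sep = ""
  )
})

setMethod("show", "BackgroundModel", function(object) {
  cat(
    "BackgroundModel: order", object@order, "fit on", object@nMask,
    "static voxels; residual RMS (cm/s):",
    paste(format(object@residualRMS, digits = 3), collapse = ", "), "\n"
  )
})
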