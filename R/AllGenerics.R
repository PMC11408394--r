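#' Accessors for volumetric objects
#'
#' `voxelData()` returns the raw array, `voxelSpacing()` the per-axis voxel
#' size in mm, `volumeOrigin()` the physical position of the first voxel,
#' and `channelNames()` the ordered channel names of a label or prediction
#' volume.
#'
#' @param x an ImageVolume, LabelVolume, PredictionVolume or CaseRecord.
#' @return The corresponding slot value.
#' @name volume-accessors
NULL

#' @rdname volume-accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname volume-accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname volume-accessors
#' @export
setGeneric("volumeOrigin", function(x) standardGeneric("volumeOrigin"))
#' @rdname volume-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname volume-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname volume-accessors
#' @export
setGeneric("seriesId", function(x) standardGeneric("seriesId"))
#' @rdname volume-accessors
#' @export
setGeneric("isOutlier", function(x) standardGeneric("isOutlier"))
#' @rdname volume-accessors
#' @export
setGeneric("classVector", function(x) standardGeneric("classVector"))

#' @rdname volume-accessors
#' @export
setMethod("voxelData", "ImageVolume", function(x) x@data)
#' @rdname volume-accessors
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@data)
#' @rdname volume-accessors
#' @export
setMethod("voxelData", "PredictionVolume", function(x) x@data)
#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "LabelVolume", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("voxelSpacing", "PredictionVolume", function(x) x@spacing)
#' @rdname volume-accessors
#' @export
setMethod("volumeOrigin", "ImageVolume", function(x) x@origin)
#' @rdname volume-accessors
#' @export
setMethod("channelNames", "LabelVolume", function(x) x@channelNames)
#' @rdname volume-accessors
#' @export
setMethod("channelNames", "PredictionVolume", function(x) x@channelNames)
#' @rdname volume-accessors
#' @export
setMethod("patientId", "CaseRecord", function(x) x@patientId)
#' @rdname volume-accessors
#' @export
setMethod("seriesId", "CaseRecord", function(x) x@seriesId)
#' @rdname volume-accessors
#' @export
setMethod("isOutlier", "CaseRecord", function(x) x@isOutlier)
#' @rdname volume-accessors
#' @export
setMethod("classVector", "CaseRecord", function(x) x@classVector)

#' @rdname volume-accessors
#' @param object a CaseRecord.
#' @export
setGeneric("caseImage", function(object) standardGeneric("caseImage"))
#' @rdname volume-accessors
#' @export
setMethod("caseImage", "CaseRecord", function(object) object@image)
#' @rdname volume-accessors
#' @export
setGeneric("caseLabels", function(object) standardGeneric("caseLabels"))
#' @rdname volume-accessors
#' @export
setMethod("caseLabels", "CaseRecord", function(object) object@labels)

#' @rdname volume-accessors
#' @export
setGeneric("lossTotal", function(x) standardGeneric("lossTotal"))
#' @rdname volume-accessors
#' @export
setMethod("lossTotal", "LossValue", function(x) x@total)
#' @rdname volume-accessors
#' @export
setGeneric("lossComponents", function(x) standardGeneric("lossComponents"))
#' @rdname volume-accessors
#' @export
setMethod("lossComponents", "LossValue", function(x) x@components)
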