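#' @useDynLib PelvicSeg3D, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.default_channels <- c("background", "bladder", "CGU", "rectum")

#' ImageVolume: a 3D scalar intensity grid with voxel geometry
#'
#' Holds a 3D image in stored voxel order (X, Y, Z), its per-axis voxel
#' spacing in mm and the physical position (mm) of voxel (1,1,1).
#'
#' @slot data 3D numeric array (X, Y, Z).
#' @slot spacing numeric(3), voxel size in mm per axis; all > 0.
#' @slot origin numeric(3), physical position of the first voxel in mm.
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0))
)

setValidity("ImageVolume", function(object) {
  msg <- NULL
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, sprintf("data must be a 3D array, got %dD",
                          length(dim(object@data))))
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(object@origin) != 3L)
    msg <- c(msg, "origin must have length 3")
  if (anyNA(object@data) || any(!is.finite(object@data)))
    msg <- c(msg, "data contains NaN/Inf or missing values")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn ImageVolume-class Constructor.
#' @param data,spacing,origin see slots.
#' @export
imageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' LabelVolume: a one-hot multi-channel label grid
#'
#' Channel-last 4D binary array (X, Y, Z, C); over channels every voxel sums
#' to exactly one. Default channel order is background, bladder, CGU
#' (merged cervix-GTV-uterus), rectum.
#'
#' @slot data 4D array of 0/1 values.
#' @slot channelNames character vector, one name per channel.
#' @slot spacing numeric(3), voxel size in mm.
#' @export
setClass("LabelVolume",
  representation(data = "array", channelNames = "character",
                 spacing = "numeric"),
  prototype(channelNames = .default_channels, spacing = c(1, 1, 1))
)

setValidity("LabelVolume", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, sprintf("data must be a 4D array, got %dD", length(d)))
  else {
    if (length(object@channelNames) != d[4])
      msg <- c(msg, "channelNames length must equal channel count")
    if (!all(object@data %in% c(0, 1)))
      msg <- c(msg, "label values must be 0 or 1")
    else {
      sums <- .channel_sums(object@data)
      if (any(sums != 1))
        msg <- c(msg, "labels must be one-hot (channel sums all 1)")
    }
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn LabelVolume-class Constructor.
#' @param data,channelNames,spacing see slots.
#' @export
labelVolume <- function(data, channelNames = .default_channels,
                        spacing = c(1, 1, 1)) {
  new("LabelVolume", data = data, channelNames = channelNames,
      spacing = as.numeric(spacing))
}

#' PredictionVolume: per-channel probability field
#'
#' Same layout as [labelVolume()] but real-valued: every value lies in
#' [0, 1] and per-voxel channel sums equal 1 within 1e-5 (softmax output).
#'
#' @slot data 4D numeric array of probabilities.
#' @slot channelNames character vector.
#' @slot spacing numeric(3), mm.
#' @export
setClass("PredictionVolume",
  representation(data = "array", channelNames = "character",
                 spacing = "numeric"),
  prototype(channelNames = .default_channels, spacing = c(1, 1, 1))
)

setValidity("PredictionVolume", function(object) {
  msg <- NULL
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, sprintf("data must be a 4D array, got %dD", length(d)))
  else {
    if (length(object@channelNames) != d[4])
      msg <- c(msg, "channelNames length must equal channel count")
    rng <- range(object@data)
    if (rng[1] < 0 || rng[2] > 1)
      msg <- c(msg, "probabilities must lie in [0, 1]")
    sums <- .channel_sums(object@data)
    if (max(abs(sums - 1)) > 1e-5)
      msg <- c(msg, "per-voxel channel sums must equal 1 within 1e-5")
  }
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn PredictionVolume-class Constructor.
#' @param data,channelNames,spacing see slots.
#' @export
predictionVolume <- function(data, channelNames = .default_channels,
                             spacing = c(1, 1, 1)) {
  new("PredictionVolume", data = data, channelNames = channelNames,
      spacing = as.numeric(spacing))
}

#' CaseRecord: one labelled image series
#'
#' Couples an image with its labels and bookkeeping: patient and series
#' identifiers, the per-case binary class-label vector, optionally the raw
#' cervix/GTV/uterus component masks (kept by the phantom generator so the
#' class rule can be re-derived), and an outlier flag. Outlier series are
#' used for training but excluded from test sets.
#'
#' @slot patientId,seriesId opaque identifier strings.
#' @slot image an ImageVolume.
#' @slot labels a LabelVolume on the same grid.
#' @slot classVector numeric binary vector, one entry per label channel.
#' @slot componentMasks list of logical arrays (may be empty).
#' @slot isOutlier logical flag.
#' @export
setClass("CaseRecord",
  representation(patientId = "character", seriesId = "character",
                 image = "ImageVolume", labels = "LabelVolume",
                 classVector = "numeric", componentMasks = "list",
                 isOutlier = "logical"),
  prototype(classVector = numeric(0), componentMasks = list(),
            isOutlier = FALSE)
)

#' @describeIn CaseRecord-class Constructor.
#' @param patientId,seriesId,image,labels,classVector,componentMasks,isOutlier
#'   see slots.
#' @export
caseRecord <- function(patientId, seriesId, image, labels,
                       classVector = numeric(0), componentMasks = list(),
                       isOutlier = FALSE) {
  new("CaseRecord", patientId = as.character(patientId),
      seriesId = as.character(seriesId), image = image, labels = labels,
      classVector = as.numeric(classVector),
      componentMasks = componentMasks, isOutlier = isOutlier)
}

#' LossValue: a loss total with named components
#'
#' @slot total nonnegative numeric scalar; always equals the sum of
#'   `components` within 1e-9.
#' @slot components named numeric vector (e.g. dice, bbox, cross_entropy).
#' @export
setClass("LossValue",
  representation(total = "numeric", components = "numeric"))

setValidity("LossValue", function(object) {
  if (length(object@total) != 1L) return("total must be a scalar")
  if (abs(object@total - sum(object@components)) > 1e-9)
    return("total must equal the sum of its components")
  TRUE
})

lossValue <- function(components) {
  new("LossValue", total = sum(components), components = components)
}

# ---- configuration objects -------------------------------------------------

#' PreprocessConfig: target grid and class-label thresholds
#'
#' Defaults follow the working resolution of 256 x 256 x 64 voxels at
#' 1.64 x 1.64 x 3 mm, a 17 mm bladder maximum-inscribed-radius threshold
#' and a 4x GTV/uterus volume ratio threshold.
#'
#' @slot targetShape integer(3) voxel counts.
#' @slot targetSpacing numeric(3) mm.
#' @slot bladderRadiusThreshold mm; bladder class flag is 1 iff the maximum
#'   inscribed-sphere radius is strictly above this.
#' @slot gtvUterusRatioThreshold unitless; CGU class flag is 1 iff GTV
#'   volume is strictly larger than this multiple of the uterus volume.
#' @slot biasCorrection logical, run the bias-field hook during
#'   preprocessing.
#' @export
setClass("PreprocessConfig",
  representation(targetShape = "integer", targetSpacing = "numeric",
                 bladderRadiusThreshold = "numeric",
                 gtvUterusRatioThreshold = "numeric",
                 biasCorrection = "logical"),
  prototype(targetShape = c(256L, 256L, 64L),
            targetSpacing = c(1.64, 1.64, 3.0),
            bladderRadiusThreshold = 17,
            gtvUterusRatioThreshold = 4,
            biasCorrection = FALSE)
)

setValidity("PreprocessConfig", function(object) {
  if (any(object@targetShape <= 0) || any(object@targetSpacing <= 0) ||
      object@bladderRadiusThreshold <= 0 ||
      object@gtvUterusRatioThreshold <= 0)
    return("shapes, spacings and thresholds must be strictly positive")
  TRUE
})

#' @describeIn PreprocessConfig-class Constructor.
#' @param targetShape,targetSpacing,bladderRadiusThreshold,gtvUterusRatioThreshold,biasCorrection
#'   see slots.
#' @export
preprocessConfig <- function(targetShape = c(256L, 256L, 64L),
                             targetSpacing = c(1.64, 1.64, 3.0),
                             bladderRadiusThreshold = 17,
                             gtvUterusRatioThreshold = 4,
                             biasCorrection = FALSE) {
  new("PreprocessConfig", targetShape = as.integer(targetShape),
      targetSpacing = as.numeric(targetSpacing),
      bladderRadiusThreshold = bladderRadiusThreshold,
      gtvUterusRatioThreshold = gtvUterusRatioThreshold,
      biasCorrection = biasCorrection)
}

# ---- shared helpers --------------------------------------------------------

# per-voxel sums over the channel axis of a 4D array
.channel_sums <- function(a) {
  d <- dim(a)
  rowSums(matrix(a, nrow = prod(d[1:3]), ncol = d[4]))
}

# logical foreground mask of channel ch
.channel_mask <- function(vol, ch) {
  if (is.character(ch)) ch <- match(ch, vol@channelNames)
  vol@data[, , , ch] > 0.5
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume %dx%dx%d @ %.3gx%.3gx%.3g mm, intensity [%.3g, %.3g]\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3], min(object@data), max(object@data)))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@data)
  counts <- apply(object@data, 4, sum)
  cat(sprintf("LabelVolume %dx%dx%dx%d @ %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], d[4], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat("  voxels:", paste(sprintf("%s=%d", object@channelNames, counts),
                         collapse = ", "), "\n")
})

setMethod("show", "PredictionVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("PredictionVolume %dx%dx%dx%d @ %.3gx%.3gx%.3g mm\n",
              d[1], d[2], d[3], d[4], object@spacing[1], object@spacing[2],
              object@spacing[3]))
})

setMethod("show", "CaseRecord", function(object) {
  cat(sprintf("CaseRecord patient=%s series=%s%s\n", object@patientId,
              object@seriesId, if (object@isOutlier) " [outlier]" else ""))
  show(object@image)
  show(object@labels)
  if (length(object@classVector))
    cat("  class vector: [", paste(object@classVector, collapse = ", "),
        "]\n")
})

setMethod("show", "LossValue", function(object) {
  cat(sprintf("LossValue total=%.6g (%s)\n", object@total,
              paste(sprintf("%s=%.6g", names(object@components),
                            object@components), collapse = ", ")))
})
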