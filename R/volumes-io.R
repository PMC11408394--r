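#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file (optionally gzip-compressed) into an
#' [imageVolume()]. The grid is kept in stored voxel order (no anatomical
#' reorientation); spacing is taken from the header `pixdim`, the origin
#' from the stored transform's translation.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An ImageVolume.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D NIfTI payload, got ", length(d), "D in ", path)
  sp <- abs(RNifti::pixdim(img))[1:3]
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4])
  imageVolume(array(as.numeric(img), dim = d), spacing = sp, origin = org)
}

#' Write a 3D volume to NIfTI
#'
#' @param volume an ImageVolume, or a 3D numeric/integer array (then
#'   `spacing`/`origin` apply).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing,origin geometry used when `volume` is a bare array.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(volume, path, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (is(volume, "ImageVolume")) {
    a <- volume@data
    spacing <- volume@spacing
    origin <- volume@origin
  } else {
    a <- volume
    if (length(dim(a)) != 3L) stop("expected a 3D array")
  }
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- spacing
  m <- structure(diag(c(spacing, 1)), code = 2L)
  m[1:3, 4] <- origin
  img <- RNifti::`sform<-`(img, m)
  img <- RNifti::`qform<-`(img, m)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' One-hot encode an integer label index map
#'
#' Channel `c` of the result is 1 exactly where `indexmap == c - 1`
#' (labels are 0-based integer codes, channels 1-based in R).
#'
#' @param indexmap 3D integer array with values in `[0, nChannels)`.
#' @param nChannels number of output channels.
#' @param channelNames optional channel names.
#' @param spacing voxel spacing in mm.
#' @return A LabelVolume.
#' @export
labelsFromIndexMap <- function(indexmap, nChannels,
                               channelNames = NULL, spacing = c(1, 1, 1)) {
  d <- dim(indexmap)
  if (length(d) != 3L) stop("indexmap must be a 3D array")
  vals <- as.integer(indexmap)
  bad <- vals < 0L | vals >= nChannels
  if (any(bad))
    stop("label value out of range [0, ", nChannels, "): found ",
         vals[which(bad)[1]])
  onehot <- matrix(0, nrow = prod(d), ncol = nChannels)
  onehot[cbind(seq_along(vals), vals + 1L)] <- 1
  if (is.null(channelNames))
    channelNames <- if (nChannels == 4L) .default_channels else
      paste0("channel", seq_len(nChannels) - 1L)
  labelVolume(array(onehot, dim = c(d, nChannels)),
              channelNames = channelNames, spacing = spacing)
}

# inverse of labelsFromIndexMap: 0-based integer codes
indexMapFromLabels <- function(labels) {
  a <- if (is(labels, "LabelVolume") || is(labels, "PredictionVolume"))
    labels@data else labels
  d <- dim(a)
  m <- matrix(a, nrow = prod(d[1:3]), ncol = d[4])
  array(max.col(m, ties.method = "first") - 1L, dim = d[1:3])
}

#' Harden a probability field into one-hot labels
#'
#' Selects the maximal channel per voxel; exact ties go to the lowest
#' channel index.
#'
#' @param pred a PredictionVolume.
#' @return A LabelVolume on the same grid.
#' @export
argmaxLabels <- function(pred) {
  stopifnot(is(pred, "PredictionVolume"))
  idx <- indexMapFromLabels(pred)
  labelsFromIndexMap(idx, dim(pred@data)[4],
                     channelNames = pred@channelNames,
                     spacing = pred@spacing)
}

#' Dataset manifests
#'
#' A dataset on disk is a JSON manifest listing cases
#' (`patient_id`, `series_id`, `image_path`, `label_path`, `is_outlier`)
#' next to NIfTI image and integer label-index-map files.
#'
#' @param cases list of CaseRecord objects.
#' @param dir output directory (created if needed).
#' @param nChannels number of label channels encoded in the index maps.
#' @return `writeDataset` returns the manifest path; `readDataset` a list
#'   of CaseRecord objects.
#' @name dataset-manifest
NULL

#' @rdname dataset-manifest
#' @export
writeDataset <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cases, function(cs) {
    stem <- paste0(cs@patientId, "_", cs@seriesId)
    ipath <- file.path(dir, paste0(stem, "_img.nii.gz"))
    lpath <- file.path(dir, paste0(stem, "_lab.nii.gz"))
    writeVolume(cs@image, ipath)
    writeVolume(array(as.numeric(indexMapFromLabels(cs@labels)),
                      dim = dim(cs@labels@data)[1:3]),
                lpath, spacing = cs@labels@spacing)
    list(patient_id = cs@patientId, series_id = cs@seriesId,
         image_path = basename(ipath), label_path = basename(lpath),
         is_outlier = cs@isOutlier,
         class_vector = as.numeric(cs@classVector))
  })
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(rows, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' @rdname dataset-manifest
#' @param manifest path to a `manifest.json`.
#' @export
readDataset <- function(manifest, nChannels = 4L) {
  rows <- jsonlite::read_json(manifest)
  dir <- dirname(manifest)
  lapply(rows, function(r) {
    img <- readVolume(file.path(dir, r$image_path))
    lab <- readVolume(file.path(dir, r$label_path))
    labels <- labelsFromIndexMap(array(as.integer(round(lab@data)),
                                       dim = dim(lab@data)),
                                 nChannels, spacing = lab@spacing)
    caseRecord(r$patient_id, r$series_id, img, labels,
               classVector = as.numeric(unlist(r$class_vector)),
               isOutlier = isTRUE(r$is_outlier))
  })
}
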