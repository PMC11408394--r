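# Preprocessing: bias-field hook, grid resampling, structure merging,
# per-case class-label assignment, and largest-component post-processing.

# ---- interpolation helpers (0-based voxel coordinates) ---------------------

.sample_trilinear <- function(a, cx, cy, cz, fill = 0) {
  d <- dim(a)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  out <- numeric(length(cx))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
         (if (dz) fz else 1 - fz)
    inb <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
    v <- rep.int(fill, length(cx))
    if (any(inb))
      v[inb] <- a[cbind(xi[inb] + 1L, yi[inb] + 1L, zi[inb] + 1L)]
    out <- out + w * v
  }
  out
}

.sample_nearest <- function(a, cx, cy, cz, fill = 0) {
  d <- dim(a)
  xi <- round(cx); yi <- round(cy); zi <- round(cz)
  inb <- xi >= 0 & xi < d[1] & yi >= 0 & yi < d[2] & zi >= 0 & zi < d[3]
  out <- rep.int(fill, length(cx))
  if (any(inb))
    out[inb] <- a[cbind(xi[inb] + 1L, yi[inb] + 1L, zi[inb] + 1L)]
  out
}

# 0-based voxel-centre grid of a shape, as long vectors
.grid_coords <- function(shape) {
  list(x = rep.int(seq_len(shape[1]) - 1, prod(shape[2:3])),
       y = rep.int(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]),
       z = rep(seq_len(shape[3]) - 1, each = prod(shape[1:2])))
}

# ---- bias-field correction hook -------------------------------------------

#' Intensity bias-field correction hook
#'
#' `biasCorrect()` applies a pluggable multiplicative bias-field corrector.
#' When no corrector is supplied (or the configured one fails) the image is
#' passed through unchanged with a message/warning, so pipelines degrade
#' gracefully. `n4Corrector()` builds a corrector that delegates to an
#' external N4 implementation (SimpleITK, called through a `python`
#' interpreter) via temporary NIfTI files.
#'
#' @param image an ImageVolume.
#' @param corrector `NULL` or a function `ImageVolume -> ImageVolume`.
#' @return A corrected ImageVolume with identical shape and spacing.
#' @export
biasCorrect <- function(image, corrector = NULL) {
  stopifnot(is(image, "ImageVolume"))
  if (is.null(corrector)) {
    message("bias correction disabled; returning image unchanged")
    return(image)
  }
  out <- tryCatch(corrector(image), error = function(e) {
    warning("bias corrector failed (", conditionMessage(e),
            "); returning image unchanged")
    image
  })
  if (!identical(dim(out@data), dim(image@data))) {
    warning("bias corrector changed the grid; returning image unchanged")
    return(image)
  }
  out
}

#' @rdname biasCorrect
#' @param python path to a python interpreter with SimpleITK available.
#' @param iterations N4 iterations per resolution level.
#' @export
n4Corrector <- function(python = "python", iterations = 20L) {
  force(python); force(iterations)
  function(image) {
    td <- tempfile("n4")
    dir.create(td)
    on.exit(unlink(td, recursive = TRUE), add = TRUE)
    fin <- file.path(td, "in.nii.gz")
    fout <- file.path(td, "out.nii.gz")
    writeVolume(image, fin)
    script <- paste(
      "import sys",
      "import SimpleITK as sitk",
      "img = sitk.ReadImage(sys.argv[1], sitk.sitkFloat64)",
      "corr = sitk.N4BiasFieldCorrectionImageFilter()",
      sprintf("corr.SetMaximumNumberOfIterations([%d] * 4)", iterations),
      "out = corr.Execute(img)",
      "sitk.WriteImage(out, sys.argv[2])",
      sep = "\n")
    status <- system2(python, c("-c", shQuote(script), shQuote(fin),
                                shQuote(fout)),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(fout))
      stop("external N4 corrector exited with status ", status)
    corrected <- readVolume(fout)
    imageVolume(corrected@data, spacing = image@spacing,
                origin = image@origin)
  }
}

# ---- resampling ------------------------------------------------------------

#' Resample a case onto the working grid
#'
#' Places the target grid so its physical centre coincides with the input's
#' physical centre, then samples the image trilinearly and the labels by
#' nearest neighbour on the label index map (re-one-hotted afterwards).
#' Voxels outside the input get intensity 0 / background label.
#'
#' @param image an ImageVolume.
#' @param labels a LabelVolume on the same grid.
#' @param cfg a [preprocessConfig()] providing `targetShape` and
#'   `targetSpacing`.
#' @return `list(image =, labels =)` on the target grid.
#' @export
resampleToGrid <- function(image, labels, cfg = preprocessConfig()) {
  stopifnot(is(image, "ImageVolume"), is(labels, "LabelVolume"))
  inshape <- dim(image@data)
  if (!identical(inshape, dim(labels@data)[1:3]))
    stop("image and labels must share a grid")
  tshape <- cfg@targetShape
  tsp <- cfg@targetSpacing
  if (identical(as.integer(inshape), as.integer(tshape)) &&
      max(abs(image@spacing - tsp)) < 1e-9)
    return(list(image = image, labels = labels))

  centre_in <- image@origin + (inshape - 1) / 2 * image@spacing
  out_origin <- centre_in - (tshape - 1) / 2 * tsp
  g <- .grid_coords(tshape)
  # physical position of each output voxel, mapped to input voxel coords
  cx <- (out_origin[1] + g$x * tsp[1] - image@origin[1]) / image@spacing[1]
  cy <- (out_origin[2] + g$y * tsp[2] - image@origin[2]) / image@spacing[2]
  cz <- (out_origin[3] + g$z * tsp[3] - image@origin[3]) / image@spacing[3]

  newimg <- array(.sample_trilinear(image@data, cx, cy, cz, fill = 0),
                  dim = tshape)
  idx <- indexMapFromLabels(labels)
  newidx <- array(as.integer(.sample_nearest(idx, cx, cy, cz, fill = 0)),
                  dim = tshape)
  list(image = imageVolume(newimg, spacing = tsp, origin = out_origin),
       labels = labelsFromIndexMap(newidx, dim(labels@data)[4],
                                   channelNames = labels@channelNames,
                                   spacing = tsp))
}

#' Per-volume z-score intensity normalisation
#'
#' @param image an ImageVolume.
#' @return The image scaled to mean 0, SD 1 over the whole volume.
#' @export
zscoreNormalize <- function(image) {
  a <- image@data
  s <- stats::sd(a)
  if (s == 0) s <- 1
  imageVolume((a - mean(a)) / s, spacing = image@spacing,
              origin = image@origin)
}

# ---- structure merging -----------------------------------------------------

#' Merge cervix, GTV and uterus into a single CGU channel
#'
#' The merged channel is the voxelwise union of the three structures
#' (overlaps counted once). Accepts either a named list of binary masks or
#' a one-hot LabelVolume whose channel names include the three structures;
#' for a LabelVolume the CGU channel replaces the three merged channels at
#' the position of the first one, other channels are unchanged.
#'
#' @param labels a LabelVolume or a named list of logical/0-1 3D arrays.
#' @param channels names of the cervix, GTV and uterus channels.
#' @return Same type as the input, with a single `CGU` entry.
#' @export
mergeCGU <- function(labels, channels = c("cervix", "GTV", "uterus")) {
  if (is.list(labels)) {
    missing <- setdiff(channels, names(labels))
    if (length(missing))
      stop("mergeCGU: missing channel(s): ", paste(missing, collapse = ", "))
    cgu <- (labels[[channels[1]]] > 0) | (labels[[channels[2]]] > 0) |
      (labels[[channels[3]]] > 0)
    out <- labels[setdiff(names(labels), channels)]
    out$CGU <- cgu
    return(out)
  }
  stopifnot(is(labels, "LabelVolume"))
  idx <- match(channels, labels@channelNames)
  if (anyNA(idx))
    stop("mergeCGU: missing channel(s): ",
         paste(channels[is.na(idx)], collapse = ", "))
  d <- dim(labels@data)
  # one-hot channels are disjoint, so union == sum
  cgu <- labels@data[, , , idx[1]] + labels@data[, , , idx[2]] +
    labels@data[, , , idx[3]]
  cgu[cgu > 1] <- 1
  keep <- setdiff(seq_len(d[4]), idx)
  pos <- min(idx)
  newnames <- append(labels@channelNames[keep], "CGU",
                     after = sum(keep < pos))
  newdata <- array(0, dim = c(d[1:3], length(keep) + 1L))
  j <- 1L
  for (nm in newnames) {
    newdata[, , , j] <- if (nm == "CGU") cgu else
      labels@data[, , , match(nm, labels@channelNames)]
    j <- j + 1L
  }
  labelVolume(newdata, channelNames = newnames, spacing = labels@spacing)
}

# ---- class-label assignment ------------------------------------------------

#' Maximum inscribed-sphere radius of a mask
#'
#' Returns the largest distance (in mm, honouring anisotropic spacing) from
#' any mask voxel to its nearest background voxel, i.e. the radius of the
#' largest sphere centred on a voxel that fits inside the structure. The
#' volume border counts as background.
#'
#' @param mask logical/0-1 3D array, non-empty.
#' @param spacing numeric(3), mm.
#' @return Radius in mm.
#' @export
maxInscribedRadius <- function(mask, spacing = c(1, 1, 1)) {
  mask <- mask > 0
  if (!any(mask)) stop("maxInscribedRadius: empty mask")
  d <- dim(mask)
  padded <- array(FALSE, dim = d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  dist2 <- .edt3d_sq(!padded, dim(padded), as.numeric(spacing))
  sqrt(max(dist2[padded]))
}

#' Assign the per-case class-label vector
#'
#' Encodes gross anatomical state as a binary vector with one entry per
#' output channel: the bladder entry is 1 iff the bladder's maximum
#' inscribed radius strictly exceeds `cfg@bladderRadiusThreshold` (default
#' 17 mm); the CGU entry is 1 iff the GTV volume is strictly larger than
#' `cfg@gtvUterusRatioThreshold` (default 4) times the uterus volume.
#' Background and rectum entries are always 0. A non-empty GTV with an
#' empty uterus degenerates to flag 1 with a warning.
#'
#' @param bladderMask,gtvMask,uterusMask logical/0-1 3D arrays.
#' @param spacing numeric(3), mm.
#' @param cfg a [preprocessConfig()].
#' @return Numeric binary vector `(background, bladder, CGU, rectum)`.
#' @export
assignClassLabels <- function(bladderMask, gtvMask, uterusMask,
                              spacing = c(1, 1, 1),
                              cfg = preprocessConfig()) {
  vvol <- prod(spacing)
  bl_r <- maxInscribedRadius(bladderMask, spacing)
  gtv_v <- sum(gtvMask > 0) * vvol
  ut_v <- sum(uterusMask > 0) * vvol
  if (ut_v == 0 && gtv_v > 0) {
    warning("empty uterus with non-empty GTV; ratio degenerate, flag set")
    cgu_flag <- 1
  } else if (ut_v == 0) {
    cgu_flag <- 0
  } else {
    cgu_flag <- as.numeric(gtv_v > cfg@gtvUterusRatioThreshold * ut_v)
  }
  c(background = 0,
    bladder = as.numeric(bl_r > cfg@bladderRadiusThreshold),
    CGU = cgu_flag, rectum = 0)
}

#' Broadcast a class-label vector to a constant 4D volume
#'
#' Channel `c` of the result is constant `vec[c]` over the grid; this is
#' the second input of the masked networks.
#'
#' @param vec binary numeric vector, one entry per output channel.
#' @param shape integer(3) grid shape.
#' @return 4D array `(X, Y, Z, length(vec))`.
#' @export
classVectorToVolume <- function(vec, shape) {
  array(rep(as.numeric(vec), each = prod(shape)),
        dim = c(shape, length(vec)))
}

# ---- post-processing -------------------------------------------------------

#' Keep only the largest connected component of each structure
#'
#' For every foreground channel independently, retains the largest
#' 26-connected component (size ties resolved by first-encountered
#' component in column-major scan order) and relabels removed voxels as
#' background. Mirrors the post-processing of removing external contours
#' disconnected from the main body of a structure.
#'
#' @param labels a LabelVolume.
#' @param background name or index of the background channel.
#' @return A LabelVolume.
#' @export
keepLargestComponent <- function(labels, background = "background") {
  stopifnot(is(labels, "LabelVolume"))
  d <- dim(labels@data)
  bg <- if (is.character(background))
    match(background, labels@channelNames) else as.integer(background)
  if (is.na(bg)) bg <- 1L
  idx <- indexMapFromLabels(labels)
  for (ch in setdiff(seq_len(d[4]), bg)) {
    mask <- labels@data[, , , ch] > 0
    if (!any(mask)) next
    lab <- .label_cc26(mask, dim(mask))
    sizes <- tabulate(lab[lab > 0L])
    if (length(sizes) <= 1L) next
    keep <- which.max(sizes)  # ties -> lowest label = first encountered
    idx[mask & lab != keep] <- bg - 1L
  }
  labelsFromIndexMap(idx, d[4], channelNames = labels@channelNames,
                     spacing = labels@spacing)
}

#' Preprocess one case end-to-end
#'
#' Optional bias correction, resampling to the working grid, z-score
#' intensity normalisation, and class-vector pass-through.
#'
#' @param case a CaseRecord.
#' @param cfg a [preprocessConfig()].
#' @param corrector optional bias corrector (see [biasCorrect()]).
#' @return A preprocessed CaseRecord.
#' @export
preprocessCase <- function(case, cfg = preprocessConfig(),
                           corrector = NULL) {
  img <- case@image
  if (cfg@biasCorrection) img <- biasCorrect(img, corrector)
  rs <- resampleToGrid(img, case@labels, cfg)
  caseRecord(case@patientId, case@seriesId, zscoreNormalize(rs$image),
             rs$labels, classVector = case@classVector,
             componentMasks = case@componentMasks,
             isOutlier = case@isOutlier)
}
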