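# Random augmentation: elastic deformation, affine warping, uni-axial
# rotation and integer shift, applied identically to image (trilinear) and
# label index map (nearest neighbour), with labels re-one-hotted.

#' AugmentConfig: augmentation operations and parameter ranges
#'
#' @slot nCopies augmented variants per input case (default 9; the
#'   original is kept alongside, so 42 inputs yield 420 series).
#' @slot rotationDeg maximum rotation magnitude about one random grid
#'   axis, degrees.
#' @slot shiftMax integer(3) maximum voxel shift per axis.
#' @slot elasticSD control-point displacement SD, mm.
#' @slot elasticSpacing control-grid spacing, mm.
#' @slot scaleRange,shearRange affine per-axis scale and shear ranges.
#' @slot seed RNG seed.
#' @export
setClass("AugmentConfig",
  representation(nCopies = "integer", rotationDeg = "numeric",
                 shiftMax = "integer", elasticSD = "numeric",
                 elasticSpacing = "numeric", scaleRange = "numeric",
                 shearRange = "numeric", seed = "integer"),
  prototype(nCopies = 9L, rotationDeg = 15, shiftMax = c(10L, 10L, 3L),
            elasticSD = 4, elasticSpacing = 32, scaleRange = c(0.9, 1.1),
            shearRange = c(-0.05, 0.05), seed = 1L)
)

setValidity("AugmentConfig", function(object) {
  if (object@nCopies < 0L) return("nCopies must be >= 0")
  if (!all(is.finite(c(object@rotationDeg, object@shiftMax,
                       object@elasticSD, object@elasticSpacing,
                       object@scaleRange, object@shearRange))))
    return("all parameter ranges must be finite")
  TRUE
})

#' @describeIn AugmentConfig-class Constructor.
#' @param nCopies,rotationDeg,shiftMax,elasticSD,elasticSpacing,scaleRange,shearRange,seed
#'   see slots.
#' @export
augmentConfig <- function(nCopies = 9L, rotationDeg = 15,
                          shiftMax = c(10L, 10L, 3L), elasticSD = 4,
                          elasticSpacing = 32, scaleRange = c(0.9, 1.1),
                          shearRange = c(-0.05, 0.05), seed = 1L) {
  new("AugmentConfig", nCopies = as.integer(nCopies),
      rotationDeg = rotationDeg, shiftMax = as.integer(shiftMax),
      elasticSD = elasticSD, elasticSpacing = elasticSpacing,
      scaleRange = scaleRange, shearRange = shearRange,
      seed = as.integer(seed))
}

# resample image + labels at given 0-based source voxel coordinates
.warp_case <- function(image, labels, cx, cy, cz) {
  shape <- dim(image@data)
  newimg <- array(.sample_trilinear(image@data, cx, cy, cz, fill = 0),
                  dim = shape)
  idx <- indexMapFromLabels(labels)
  newidx <- array(as.integer(.sample_nearest(idx, cx, cy, cz, fill = 0)),
                  dim = shape)
  list(image = imageVolume(newimg, spacing = image@spacing,
                           origin = image@origin),
       labels = labelsFromIndexMap(newidx, dim(labels@data)[4],
                                   channelNames = labels@channelNames,
                                   spacing = labels@spacing))
}

#' Elastic deformation
#'
#' Draws independent Gaussian displacements (SD `sd` mm per axis) on a
#' coarse control grid (`controlSpacing` mm apart), upsamples them
#' trilinearly to a smooth dense displacement field, and warps image and
#' labels through it.
#'
#' @param image an ImageVolume.
#' @param labels the matching LabelVolume.
#' @param sd displacement standard deviation, mm.
#' @param controlSpacing control-point spacing, mm.
#' @param seed RNG seed.
#' @return `list(image =, labels =)`.
#' @export
elasticDeform <- function(image, labels, sd = 4, controlSpacing = 32,
                          seed = 1L) {
  .with_seed(seed, {
    shape <- dim(image@data)
    sp <- image@spacing
    if (sd == 0) return(list(image = image, labels = labels))
    nctrl <- pmax(2L, as.integer(ceiling(shape * sp / controlSpacing)) + 1L)
    g <- .grid_coords(shape)
    # voxel position in control-grid units
    ccoords <- lapply(1:3, function(a)
      list(g$x, g$y, g$z)[[a]] * sp[a] / controlSpacing)
    disp <- lapply(1:3, function(a) {
      ctrl <- array(stats::rnorm(prod(nctrl), sd = sd), dim = nctrl)
      .sample_trilinear(ctrl, ccoords[[1]], ccoords[[2]], ccoords[[3]],
                        fill = 0)
    })
    cx <- g$x + disp[[1]] / sp[1]
    cy <- g$y + disp[[2]] / sp[2]
    cz <- g$z + disp[[3]] / sp[3]
    .warp_case(image, labels, cx, cy, cz)
  })
}

# shared affine application: map output physical coords through A^-1
# about the grid centre
.apply_linear <- function(image, labels, A) {
  shape <- dim(image@data)
  sp <- image@spacing
  centre <- (shape - 1) / 2 * sp
  g <- .grid_coords(shape)
  px <- g$x * sp[1] - centre[1]
  py <- g$y * sp[2] - centre[2]
  pz <- g$z * sp[3] - centre[3]
  Ai <- solve(A)
  sx <- Ai[1, 1] * px + Ai[1, 2] * py + Ai[1, 3] * pz + centre[1]
  sy <- Ai[2, 1] * px + Ai[2, 2] * py + Ai[2, 3] * pz + centre[2]
  sz <- Ai[3, 1] * px + Ai[3, 2] * py + Ai[3, 3] * pz + centre[3]
  .warp_case(image, labels, sx / sp[1], sy / sp[2], sz / sp[3])
}

#' Affine warp
#'
#' Random per-axis scaling and small shears about the grid centre, in
#' physical coordinates.
#'
#' @inheritParams elasticDeform
#' @param scaleRange,shearRange uniform draw ranges.
#' @export
affineWarp <- function(image, labels, scaleRange = c(0.9, 1.1),
                       shearRange = c(-0.05, 0.05), seed = 1L) {
  .with_seed(seed, {
    A <- diag(stats::runif(3, scaleRange[1], scaleRange[2]))
    off <- which(diag(3) == 0)
    A[off] <- stats::runif(6, shearRange[1], shearRange[2])
    .apply_linear(image, labels, A)
  })
}

#' Uni-axial rotation
#'
#' Rotation about exactly one randomly chosen grid axis, in physical
#' coordinates about the grid centre.
#'
#' @inheritParams elasticDeform
#' @param maxDeg maximum rotation magnitude (degrees).
#' @param axis 1, 2 or 3 to fix the axis; `NULL` picks one at random.
#' @param deg fixed angle in degrees; `NULL` draws uniformly in
#'   `[-maxDeg, maxDeg]`.
#' @export
uniaxialRotate <- function(image, labels, maxDeg = 15, axis = NULL,
                           deg = NULL, seed = 1L) {
  .with_seed(seed, {
    if (is.null(axis)) axis <- sample(1:3, 1)
    if (is.null(deg)) deg <- stats::runif(1, -maxDeg, maxDeg)
    th <- deg * pi / 180
    c2 <- cos(th); s2 <- sin(th)
    R2 <- matrix(c(c2, s2, -s2, c2), 2, 2)
    A <- diag(3)
    oth <- setdiff(1:3, axis)
    A[oth, oth] <- R2
    .apply_linear(image, labels, A)
  })
}

#' Integer voxel shift
#'
#' Pure translation by whole voxels with zero-intensity / background fill
#' (voxel-exact for the shifted content).
#'
#' @inheritParams elasticDeform
#' @param maxShift integer(3) maximum magnitude per axis.
#' @param shift fixed integer(3) shift; `NULL` draws uniformly.
#' @export
shiftVolume <- function(image, labels, maxShift = c(10L, 10L, 3L),
                        shift = NULL, seed = 1L) {
  .with_seed(seed, {
    if (is.null(shift))
      shift <- vapply(maxShift, function(m)
        sample(seq(-m, m), 1), numeric(1))
    shift <- as.integer(round(shift))
    shape <- dim(image@data)
    newimg <- array(0, shape)
    idx <- indexMapFromLabels(labels)
    newidx <- array(0L, shape)
    src <- lapply(1:3, function(a) {
      rng <- seq_len(shape[a]) - shift[a]
      rng[rng >= 1 & rng <= shape[a]]
    })
    dst <- lapply(1:3, function(a) src[[a]] + shift[a])
    if (all(lengths(src) > 0)) {
      newimg[dst[[1]], dst[[2]], dst[[3]]] <-
        image@data[src[[1]], src[[2]], src[[3]]]
      newidx[dst[[1]], dst[[2]], dst[[3]]] <-
        idx[src[[1]], src[[2]], src[[3]]]
    }
    list(image = imageVolume(newimg, spacing = image@spacing,
                             origin = image@origin),
         labels = labelsFromIndexMap(newidx, dim(labels@data)[4],
                                     channelNames = labels@channelNames,
                                     spacing = labels@spacing))
  })
}

.fg_single_components <- function(labels, background = "background") {
  bg <- match(background, labels@channelNames)
  if (is.na(bg)) bg <- 1L
  for (ch in setdiff(seq_len(dim(labels@data)[4]), bg)) {
    m <- labels@data[, , , ch] > 0
    if (any(m) && !.single_component(m)) return(FALSE)
  }
  TRUE
}

#' Augment a dataset
#'
#' For each input case, emits the original plus `cfg@nCopies` augmented
#' variants. Each variant applies a random non-empty subset of the four
#' operations (elastic, affine, uni-axial rotation, shift) with parameters
#' drawn from the config. Variants that split a structure into several
#' components are redrawn. Augmented series inherit the patient id.
#'
#' @param cases list of CaseRecord objects.
#' @param cfg an [augmentConfig()].
#' @return List of `length(cases) * (1 + nCopies)` CaseRecord objects.
#' @export
augmentDataset <- function(cases, cfg = augmentConfig()) {
  out <- vector("list", length(cases) * (1L + cfg@nCopies))
  pos <- 1L
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    out[[pos]] <- cs; pos <- pos + 1L
    for (j in seq_len(cfg@nCopies)) {
      base_seed <- (cfg@seed %% 100000L) * 10000L + ci * 100L + j
      for (attempt in 0:19) {
        sd_ <- base_seed + attempt * 1000003L
        aug <- .with_seed(sd_, {
          ops <- which(stats::runif(4) < 0.5)
          if (length(ops) == 0) ops <- sample(1:4, 1)
          sub <- sample.int(.Machine$integer.max %/% 2, 4)
          cur <- list(image = cs@image, labels = cs@labels)
          if (1 %in% ops)
            cur <- elasticDeform(cur$image, cur$labels, cfg@elasticSD,
                                 cfg@elasticSpacing, seed = sub[1])
          if (2 %in% ops)
            cur <- affineWarp(cur$image, cur$labels, cfg@scaleRange,
                              cfg@shearRange, seed = sub[2])
          if (3 %in% ops)
            cur <- uniaxialRotate(cur$image, cur$labels, cfg@rotationDeg,
                                  seed = sub[3])
          if (4 %in% ops)
            cur <- shiftVolume(cur$image, cur$labels, cfg@shiftMax,
                               seed = sub[4])
          cur
        })
        if (.fg_single_components(aug$labels)) break
        if (attempt == 19L)
          stop("augmentation repeatedly split a structure for series ",
               cs@seriesId)
      }
      out[[pos]] <- caseRecord(cs@patientId,
                               paste0(cs@seriesId, "_aug", j),
                               aug$image, aug$labels,
                               classVector = cs@classVector,
                               isOutlier = cs@isOutlier)
      pos <- pos + 1L
    }
  }
  out
}
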