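# Synthetic pelvic phantoms: ellipsoidal bladder, a merged
# cervix-GTV-uterus complex built from overlapping ellipsoids, and a curved
# tubular rectum, rasterized on an anisotropic grid with per-structure
# intensities, a smooth multiplicative bias field and Gaussian noise.
# Structure sizes are specified as physical volumes and met by calibrating
# the rasterization, so populations can span the wide clinical volume
# ranges (bladder ~30-722 cm^3, GTV ~11-712 cm^3, rectum ~19-213 cm^3).

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' PhantomSpec: parameters of one synthetic pelvic phantom
#'
#' Volumes are physical (cm^3); geometry is placed in the grid's physical
#' field of view with anatomically ordered anterior-to-posterior layout
#' (bladder, CGU complex, rectum). The default grid, 64 x 64 x 32 voxels
#' at 6.56 x 6.56 x 6 mm, spans the same field of view as a
#' 256 x 256 x 64 grid at 1.64 x 1.64 x 3 mm.
#'
#' @slot shape integer(3) grid extents.
#' @slot spacing numeric(3) voxel size, mm.
#' @slot bladderVolume,uterusVolume,cervixVolume,gtvVolume,rectumVolume
#'   requested structure volumes, cm^3.
#' @slot intensities named means (background, bladder, CGU, rectum) of a
#'   loosely T2-like piecewise-constant image (bright urine-filled
#'   bladder, intermediate CGU, dark rectum).
#' @slot noiseSD additive Gaussian noise SD (intensity units).
#' @slot biasOrder,biasAmplitude polynomial order and relative amplitude
#'   of the multiplicative bias field.
#' @slot seed RNG seed; generation is deterministic given the spec.
#' @export
setClass("PhantomSpec",
  representation(shape = "integer", spacing = "numeric",
                 bladderVolume = "numeric", uterusVolume = "numeric",
                 cervixVolume = "numeric", gtvVolume = "numeric",
                 rectumVolume = "numeric", intensities = "numeric",
                 noiseSD = "numeric", biasOrder = "integer",
                 biasAmplitude = "numeric", seed = "integer"),
  prototype(shape = c(64L, 64L, 32L), spacing = c(6.56, 6.56, 6.0),
            bladderVolume = 200, uterusVolume = 80, cervixVolume = 20,
            gtvVolume = 111.7, rectumVolume = 57.95,
            intensities = c(background = 100, bladder = 200, CGU = 140,
                            rectum = 60),
            noiseSD = 10, biasOrder = 2L, biasAmplitude = 0.2, seed = 1L)
)

#' @describeIn PhantomSpec-class Constructor (defaults are the study
#'   medians: bladder 200, GTV 111.7, rectum 57.95 cm^3).
#' @param shape,spacing,bladderVolume,uterusVolume,cervixVolume,gtvVolume,rectumVolume,intensities,noiseSD,biasOrder,biasAmplitude,seed
#'   see slots.
#' @export
phantomSpec <- function(shape = c(64L, 64L, 32L),
                        spacing = c(6.56, 6.56, 6.0),
                        bladderVolume = 200, uterusVolume = 80,
                        cervixVolume = 20, gtvVolume = 111.7,
                        rectumVolume = 57.95,
                        intensities = c(background = 100, bladder = 200,
                                        CGU = 140, rectum = 60),
                        noiseSD = 10, biasOrder = 2L, biasAmplitude = 0.2,
                        seed = 1L) {
  new("PhantomSpec", shape = as.integer(shape),
      spacing = as.numeric(spacing), bladderVolume = bladderVolume,
      uterusVolume = uterusVolume, cervixVolume = cervixVolume,
      gtvVolume = gtvVolume, rectumVolume = rectumVolume,
      intensities = intensities, noiseSD = noiseSD,
      biasOrder = as.integer(biasOrder), biasAmplitude = biasAmplitude,
      seed = as.integer(seed))
}

# physical voxel-centre coordinate vectors (mm) of a grid
.phys_axes <- function(shape, spacing) {
  list(x = (seq_len(shape[1]) - 1) * spacing[1],
       y = (seq_len(shape[2]) - 1) * spacing[2],
       z = (seq_len(shape[3]) - 1) * spacing[3])
}

# rasterize an axis-aligned ellipsoid; returns logical array
.rasterize_ellipsoid <- function(shape, spacing, centre, semi) {
  ax <- .phys_axes(shape, spacing)
  ux <- ((ax$x - centre[1]) / semi[1])^2
  uy <- ((ax$y - centre[2]) / semi[2])^2
  uz <- ((ax$z - centre[3]) / semi[3])^2
  outer(outer(ux, uy, "+"), uz, "+") <= 1
}

# calibrate a scale factor so the rasterized voxel volume meets the target
# (bisection; counts grow monotonically with scale)
.calibrate_scale <- function(target_mm3, vvol, raster_fn) {
  lo <- 0.5; hi <- 1.6
  count_at <- function(s) sum(raster_fn(s))
  # widen until bracketed
  while (count_at(hi) * vvol < target_mm3 && hi < 4) hi <- hi * 1.25
  while (count_at(lo) * vvol > target_mm3 && lo > 0.1) lo <- lo * 0.8
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (count_at(mid) * vvol < target_mm3) lo <- mid else hi <- mid
  }
  hi
}

# random per-axis aspect factors with product 1
.aspect <- function(jitter = 0.2) {
  f <- exp(stats::runif(3, -jitter, jitter))
  f / prod(f)^(1 / 3)
}

.single_component <- function(mask) {
  if (!any(mask)) return(TRUE)
  lab <- .label_cc26(mask, dim(mask))
  max(lab) == 1L
}

# build one ellipsoidal structure of a requested volume
.make_ellipsoid_structure <- function(shape, spacing, centre, volume_cm3,
                                      aspect) {
  vvol <- prod(spacing)
  r0 <- (3 * volume_cm3 * 1000 / (4 * pi))^(1 / 3)
  raster <- function(s)
    .rasterize_ellipsoid(shape, spacing, centre, s * r0 * aspect)
  s <- .calibrate_scale(volume_cm3 * 1000, vvol, raster)
  list(mask = raster(s), semi = s * r0 * aspect)
}

# curved tube along z: slice-wise disks around a perturbed centreline
.make_tube_structure <- function(shape, spacing, centre_xy, volume_cm3,
                                 amplitude) {
  ax <- .phys_axes(shape, spacing)
  fovz <- shape[3] * spacing[3]
  zmargin <- 2.5 * spacing[3]
  zin <- ax$z >= zmargin & ax$z <= fovz - zmargin
  len <- sum(zin) * spacing[3]
  r0 <- sqrt(volume_cm3 * 1000 / (pi * len))
  phase <- stats::runif(1, 0, 2 * pi)
  cx <- centre_xy[1] + amplitude * sin(2 * pi * ax$z / fovz + phase)
  cy <- centre_xy[2] + 0.5 * amplitude * cos(2 * pi * ax$z / fovz + phase)
  raster <- function(s) {
    m <- array(FALSE, shape)
    for (k in seq_len(shape[3])) {
      if (!zin[k]) next
      d2 <- outer((ax$x - cx[k])^2, (ax$y - cy[k])^2, "+")
      m[, , k] <- d2 <= (s * r0)^2
    }
    m
  }
  s <- .calibrate_scale(volume_cm3 * 1000, prod(spacing), raster)
  list(mask = raster(s), radius = s * r0)
}

.check_in_bounds <- function(mask, shape, name, margin = 2L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    stop("phantom structure '", name, "' rasterized to zero voxels")
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  if (any(lo <= margin) || any(hi > shape - margin))
    stop("phantom structure '", name,
         "' extends outside the grid margin; enlarge the grid or shrink ",
         "the structure")
}

# smooth random multiplicative bias field, normalised to max |.| = 1
.bias_field <- function(shape, spacing, order) {
  ax <- .phys_axes(shape, spacing)
  nx <- 2 * ax$x / max(ax$x) - 1
  ny <- 2 * ax$y / max(ax$y) - 1
  nz <- 2 * ax$z / max(ax$z) - 1
  field <- array(0, shape)
  for (i in 0:order) for (j in 0:order) for (k in 0:order) {
    if (i + j + k == 0 || i + j + k > order) next
    coef <- stats::rnorm(1)
    field <- field + coef * outer(outer(nx^i, ny^j), nz^k)
  }
  m <- max(abs(field))
  if (m > 0) field / m else field
}

#' Generate one synthetic pelvic phantom
#'
#' Deterministic given `spec@seed`. Returns a [caseRecord()] holding the
#' image (structure intensities, multiplicative bias field, Gaussian
#' noise), the one-hot labels (background, bladder, CGU, rectum), the raw
#' cervix/GTV/uterus component masks, and the class-label vector derived
#' from the generated geometry via [assignClassLabels()].
#'
#' @param spec a [phantomSpec()].
#' @param patientId,seriesId identifiers for the CaseRecord.
#' @return A CaseRecord.
#' @export
generatePhantom <- function(spec, patientId = "P01", seriesId = "S1") {
  stopifnot(is(spec, "PhantomSpec"))
  .with_seed(spec@seed, {
    shape <- spec@shape
    sp <- spec@spacing
    fov <- shape * sp
    cm3 <- function(mask) sum(mask) * prod(sp) / 1000

    # CGU complex: uterus with cervix below and GTV bridging the two
    ut_aspect <- .aspect(0.2) * c(1, 1, 1.15)
    cgu_y <- 0.52 * fov[2] + stats::runif(1, -0.02, 0.02) * fov[2]
    cgu_c <- c(0.5 * fov[1] + stats::runif(1, -0.03, 0.03) * fov[1],
               cgu_y, 0.52 * fov[3])
    ut <- .make_ellipsoid_structure(shape, sp, cgu_c, spec@uterusVolume,
                                    ut_aspect)
    cx_c <- cgu_c + c(0, 0, -0.85 * ut$semi[3])
    cx <- .make_ellipsoid_structure(shape, sp, cx_c, spec@cervixVolume,
                                    .aspect(0.15))
    gtv_c <- cgu_c + c(0, 0, -0.45 * ut$semi[3])
    gtv <- .make_ellipsoid_structure(shape, sp, gtv_c, spec@gtvVolume,
                                     .aspect(0.2))
    cgu_mask <- ut$mask | cx$mask | gtv$mask

    # bladder anterior of the CGU complex, separation from drawn extents
    bl_aspect <- .aspect(0.25)
    bl_r0 <- (3 * spec@bladderVolume * 1000 / (4 * pi))^(1 / 3)
    cgu_ymin <- if (any(cgu_mask)) {
      (min(which(cgu_mask, arr.ind = TRUE)[, 2]) - 1) * sp[2]
    } else cgu_y
    bl_c <- c(0.5 * fov[1] + stats::runif(1, -0.03, 0.03) * fov[1],
              cgu_ymin - bl_r0 * bl_aspect[2] - 1.5 * sp[2],
              0.5 * fov[3])
    bl <- .make_ellipsoid_structure(shape, sp, bl_c, spec@bladderVolume,
                                    bl_aspect)

    # rectum posterior, curved tube along z
    cgu_ymax <- (max(which(cgu_mask, arr.ind = TRUE)[, 2]) - 1) * sp[2]
    amp <- 0.015 * fov[1]
    re_r0 <- sqrt(spec@rectumVolume * 1000 /
                    (pi * (shape[3] - 5) * sp[3]))
    re <- .make_tube_structure(shape, sp,
      c(0.5 * fov[1], cgu_ymax + re_r0 + amp + 1.5 * sp[2]),
      spec@rectumVolume, amp)

    # precedence order: bladder, CGU, rectum (later loses contested voxels)
    cgu_mask <- cgu_mask & !bl$mask
    re_mask <- re$mask & !bl$mask & !cgu_mask

    .check_in_bounds(bl$mask, shape, "bladder")
    .check_in_bounds(cgu_mask, shape, "CGU")
    .check_in_bounds(re_mask, shape, "rectum")
    for (nm in c("bladder", "CGU", "rectum")) {
      m <- switch(nm, bladder = bl$mask, CGU = cgu_mask, rectum = re_mask)
      if (!.single_component(m))
        stop("phantom structure '", nm, "' is not a single component")
    }

    idx <- array(0L, shape)
    idx[bl$mask] <- 1L
    idx[cgu_mask] <- 2L
    idx[re_mask] <- 3L
    labels <- labelsFromIndexMap(idx, 4L, spacing = sp)

    mu <- spec@intensities
    img <- array(mu[["background"]], shape)
    img[bl$mask] <- mu[["bladder"]]
    img[cgu_mask] <- mu[["CGU"]]
    img[re_mask] <- mu[["rectum"]]
    if (spec@biasAmplitude > 0)
      img <- img * (1 + spec@biasAmplitude *
                      .bias_field(shape, sp, spec@biasOrder))
    if (spec@noiseSD > 0)
      img <- img + array(stats::rnorm(prod(shape), sd = spec@noiseSD),
                         shape)

    cvec <- suppressWarnings(
      assignClassLabels(bl$mask, gtv$mask, ut$mask, sp))
    caseRecord(patientId, seriesId,
               imageVolume(img, spacing = sp), labels,
               classVector = as.numeric(cvec),
               componentMasks = list(cervix = cx$mask, GTV = gtv$mask,
                                     uterus = ut$mask,
                                     bladder = bl$mask, rectum = re_mask))
  })
}

#' Sample a phantom population
#'
#' Draws per-patient structure volumes log-uniformly and generates
#' `seriesPerPatient` phantoms per patient with small per-series jitter
#' (~8 percent) around the patient's anatomy, emulating repeat scans.
#' `variation = "paper-range"` spans bladder 30.08-721.8, GTV
#' 11.42-712.31 and rectum 19.3-213.45 cm^3; `"small"` stays within
#' +/- 20 percent of the population medians.
#'
#' @param n number of patients.
#' @param seed RNG seed; draws are reproducible.
#' @param variation `"small"` or `"paper-range"`.
#' @param shape,spacing phantom grid.
#' @param seriesPerPatient series generated per patient.
#' @return List of CaseRecord objects (length `n * seriesPerPatient`).
#' @export
samplePhantomPopulation <- function(n, seed = 1L,
                                    variation = c("small", "paper-range"),
                                    shape = c(64L, 64L, 32L),
                                    spacing = c(6.56, 6.56, 6.0),
                                    seriesPerPatient = 1L) {
  stopifnot(n >= 1)
  variation <- match.arg(variation)
  rng <- switch(variation,
    "paper-range" = list(bladder = c(30.08, 721.8),
                         gtv = c(11.42, 712.31),
                         rectum = c(19.3, 213.45),
                         uterus = c(40, 150), cervix = c(10, 30)),
    "small" = list(bladder = c(160, 240), gtv = c(89, 134),
                   rectum = c(46, 70), uterus = c(64, 96),
                   cervix = c(16, 24)))
  loguni <- function(lim) exp(stats::runif(1, log(lim[1]), log(lim[2])))
  .with_seed(seed, {
    cases <- list()
    for (i in seq_len(n)) {
      vols <- lapply(rng, loguni)
      for (s in seq_len(seriesPerPatient)) {
        jit <- function(v) v * exp(stats::runif(1, -0.08, 0.08))
        sub <- as.integer((seed %% 100000L) * 10000L + i * 100L + s)
        # an unlucky jitter can push a structure against the grid margin;
        # such draws are redrawn with a perturbed sub-seed
        for (attempt in 0:9) {
          spec <- phantomSpec(shape = shape, spacing = spacing,
                              bladderVolume = jit(vols$bladder),
                              uterusVolume = jit(vols$uterus),
                              cervixVolume = jit(vols$cervix),
                              gtvVolume = jit(vols$gtv),
                              rectumVolume = jit(vols$rectum),
                              seed = sub + attempt * 999983L)
          cs <- tryCatch(
            generatePhantom(spec, patientId = sprintf("P%02d", i),
                            seriesId = sprintf("S%d", s)),
            error = function(e) if (attempt == 9) stop(e) else NULL)
          if (!is.null(cs)) break
        }
        cases[[length(cases) + 1L]] <- cs
      }
    }
    cases
  })
}
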