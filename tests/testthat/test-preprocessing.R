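# Resampling, CGU merging, class-label assignment, inscribed radius and
# largest-component post-processing.

test_that("bias hook passes through untouched when disabled and on failure", {
  img <- imageVolume(array(5, dim = c(8, 8, 4)))
  expect_message(out <- biasCorrect(img, NULL), "unchanged")
  expect_identical(out@data, img@data)
  failing <- function(image) stop("boom")
  expect_warning(out2 <- biasCorrect(img, failing), "failed")
  expect_identical(out2@data, img@data)
})

test_that("external N4 correction reduces the bias-induced intensity spread", {
  # phantom with a strong multiplicative bias field; coefficient of
  # variation inside the homogeneous bladder should drop after correction
  cs <- generatePhantom(phantomSpec(shape = c(32L, 32L, 16L),
                                    spacing = c(13.125, 13.125, 12),
                                    noiseSD = 0, biasAmplitude = 0.4,
                                    seed = 11L))
  bl <- cs@componentMasks$bladder
  cv <- function(img) stats::sd(img@data[bl]) / mean(img@data[bl])
  corrected <- biasCorrect(caseImage(cs), n4Corrector())
  expect_lt(cv(corrected), cv(caseImage(cs)))
})

test_that("resampling is exact on the identity and preserves one-hot labels", {
  cs <- small_phantom(2)
  cfg <- preprocessConfig(targetShape = dim(voxelData(caseImage(cs))),
                          targetSpacing = voxelSpacing(caseImage(cs)))
  rs <- resampleToGrid(caseImage(cs), caseLabels(cs), cfg)
  expect_identical(rs$image@data, voxelData(caseImage(cs)))
  expect_identical(rs$labels@data, voxelData(caseLabels(cs)))

  cfg2 <- preprocessConfig(targetShape = c(24L, 24L, 12L),
                           targetSpacing = c(17.5, 17.5, 16))
  rs2 <- resampleToGrid(caseImage(cs), caseLabels(cs), cfg2)
  expect_equal(dim(rs2$labels@data), c(24L, 24L, 12L, 4L))
  sums <- .channel_sums(rs2$labels@data)
  expect_true(all(sums == 1))
})

test_that("a centred sphere keeps its volume through in-plane resampling", {
  # sphere of radius 24 mm on a 1.2 mm grid, resampled to 1.64 mm
  shape <- c(48L, 48L, 24L)
  sp <- c(1.2, 1.2, 3.0)
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) -
                                   (shape[a] - 1) / 2) * sp[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  sphere <- r2 <= 24^2
  img <- imageVolume(array(100 * sphere, dim = shape), spacing = sp)
  lab <- labelsFromIndexMap(array(as.integer(sphere), dim = shape), 4L,
                            spacing = sp)
  cfg <- preprocessConfig(targetShape = c(36L, 36L, 24L),
                          targetSpacing = c(1.64, 1.64, 3.0))
  rs <- resampleToGrid(img, lab, cfg)
  vol_in <- sum(lab@data[, , , 2]) * prod(sp)
  vol_out <- sum(rs$labels@data[, , , 2]) * prod(c(1.64, 1.64, 3.0))
  expect_lt(abs(vol_out - vol_in) / vol_in, 0.05)
})

test_that("CGU merging is the voxelwise union", {
  shape <- c(8L, 8L, 8L)
  # disjoint structures: counts add
  masks <- list(bladder = cuboid_mask(shape, 1, 1:2, 1:5),
                cervix = cuboid_mask(shape, 3, 1:2, 1:5),
                GTV = cuboid_mask(shape, 5, 1:4, 1:5),
                uterus = cuboid_mask(shape, 7, 1:6, 1:5))
  merged <- mergeCGU(masks)
  expect_equal(sum(merged$CGU), 10 + 20 + 30)
  expect_named(merged, c("bladder", "CGU"))

  # GTV inside the uterus: union equals the uterus
  masks2 <- list(cervix = array(FALSE, shape),
                 GTV = cuboid_mask(shape, 3:4, 3:4, 3:4),
                 uterus = cuboid_mask(shape, 2:5, 2:5, 2:5))
  expect_equal(sum(mergeCGU(masks2)$CGU), sum(masks2$uterus))

  # random overlaps: brute-force logical OR
  set.seed(51)
  for (rep in 1:5) {
    ms <- list(cervix = array(runif(512) > 0.7, dim = shape),
               GTV = array(runif(512) > 0.7, dim = shape),
               uterus = array(runif(512) > 0.7, dim = shape))
    expect_equal(mergeCGU(ms)$CGU, ms$cervix | ms$GTV | ms$uterus)
  }

  expect_error(mergeCGU(masks2[c("GTV", "uterus")]), "missing channel")
})

test_that("CGU merging on a one-hot LabelVolume preserves one-hot layout", {
  shape <- c(6L, 6L, 6L)
  idx <- array(0L, dim = shape)
  idx[1, 1, 1] <- 1L  # bladder
  idx[2, 1, 1] <- 2L  # cervix
  idx[3, 1, 1] <- 3L  # GTV
  idx[4, 1, 1] <- 4L  # uterus
  idx[5, 1, 1] <- 5L  # rectum
  lab <- labelsFromIndexMap(idx, 6L,
    channelNames = c("background", "bladder", "cervix", "GTV", "uterus",
                     "rectum"))
  merged <- mergeCGU(lab)
  expect_equal(channelNames(merged),
               c("background", "bladder", "CGU", "rectum"))
  expect_equal(sum(merged@data[, , , "CGU" == channelNames(merged)]), 3)
  expect_true(all(.channel_sums(merged@data) == 1))
})

test_that("maximum inscribed radius follows the anisotropic distance transform", {
  shape <- c(9L, 9L, 9L)
  single <- cuboid_mask(shape, 5, 5, 5)
  expect_equal(maxInscribedRadius(single, c(1, 1, 1)), 1)

  # digitised 20 mm ball at unit spacing: radius within one voxel of 20
  ax <- (0:40) - 20
  ball <- outer(outer(ax^2, ax^2, "+"), ax^2, "+") <= 20^2
  r <- maxInscribedRadius(array(ball, dim = c(41, 41, 41)), c(1, 1, 1))
  expect_lt(abs(r - 20), 1.0001)

  # thin one-voxel slab: limited by the out-of-plane spacing
  slab <- array(FALSE, c(9L, 9L, 5L))
  slab[2:8, 2:8, 3] <- TRUE
  expect_equal(maxInscribedRadius(slab, c(1, 1, 3)), 3)

  expect_error(maxInscribedRadius(array(FALSE, shape)), "empty")
})

test_that("class labels follow the strict radius and volume-ratio rules", {
  shape <- c(48L, 48L, 24L)
  sp <- c(2, 2, 2)
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) -
                                   (shape[a] - 1) / 2) * sp[a])
  ball <- function(r, centre = c(0, 0, 0)) {
    outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, "+"),
          (ax[[3]] - centre[3])^2, "+") <= r^2
  }
  # inflated bladder (r = 20 mm > 17) and GTV 5x the uterus volume
  bladder <- ball(20)
  gtv <- ball(17.1, c(30, 30, 0))       # ~5x the 10 mm uterus volume
  uterus <- ball(10, c(-30, -30, 0))
  vec <- assignClassLabels(bladder, gtv, uterus, sp)
  expect_equal(unname(vec), c(0, 1, 1, 0))

  # small bladder, small tumour -> both flags 0
  vec0 <- assignClassLabels(ball(10), uterus, gtv, sp)
  expect_equal(unname(vec0), c(0, 0, 0, 0))

  # thresholds are strict: equality does not set the flag
  cfg <- preprocessConfig()
  slab_r <- maxInscribedRadius(bladder, sp)
  cfg_eq <- preprocessConfig(bladderRadiusThreshold = slab_r,
                             gtvUterusRatioThreshold =
                               sum(gtv) / sum(uterus))
  vec_eq <- assignClassLabels(bladder, gtv, uterus, sp, cfg_eq)
  expect_equal(unname(vec_eq), c(0, 0, 0, 0))

  # empty uterus with a tumour: degenerate ratio flags 1 with a warning
  expect_warning(
    vec_d <- assignClassLabels(bladder, gtv, array(FALSE, shape), sp),
    "degenerate")
  expect_equal(unname(vec_d["CGU"]), 1)

  # translation invariance on the voxel grid
  sh <- function(m) {
    out <- array(FALSE, dim(m))
    out[, , c(2:dim(m)[3], 1)] <- m  # circular shift stays in-grid here
    out
  }
  vec_t <- assignClassLabels(sh(bladder), sh(gtv), sh(uterus), sp)
  expect_equal(vec_t, vec)
})

test_that("class vectors broadcast to constant volumes", {
  v <- classVectorToVolume(c(0, 1, 1, 0), c(16, 16, 8))
  expect_equal(dim(v), c(16, 16, 8, 4))
  expect_true(all(v[, , , 2] == 1) && all(v[, , , 3] == 1))
  expect_true(all(v[, , , c(1, 4)] == 0))
  expect_equal(apply(v, 4, sum), c(0, 1, 1, 0) * prod(c(16, 16, 8)))
  expect_true(all(classVectorToVolume(c(0, 0, 0, 0), c(4, 4, 4)) == 0))
})

test_that("largest-component retention matches an independent component oracle", {
  skip_if_not_installed("igraph")
  set.seed(52)
  shape <- c(10L, 10L, 6L)
  # two components of 100 and 5 voxels in one channel
  m <- array(FALSE, shape)
  m[1:5, 1:5, 1:4] <- TRUE
  m[9:10, 9:10, 5] <- FALSE
  m[9, 9, 5] <- TRUE; m[10, 9, 5] <- TRUE; m[9, 10, 5] <- TRUE
  lab <- labelsFromIndexMap(array(as.integer(m), dim = shape), 4L)
  out <- keepLargestComponent(lab)
  expect_equal(sum(out@data[, , , 2]), 100)
  expect_true(all(.channel_sums(out@data) == 1))

  # igraph 26-connectivity oracle on a random blob field
  rnd <- array(runif(prod(shape)) > 0.75, dim = shape)
  lab2_ <- labelsFromIndexMap(array(as.integer(rnd), dim = shape), 4L)
  out2 <- keepLargestComponent(lab2_)
  coords <- which(rnd, arr.ind = TRUE)
  n <- nrow(coords)
  edges <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && all(abs(coords[i, ] - coords[j, ]) <= 1))
      edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)
  expect_equal(sum(out2@data[, , , 2]), max(comp$csize))

  # single component and empty channels pass through unchanged
  single <- labelsFromIndexMap(array(as.integer(m & FALSE), dim = shape), 4L)
  expect_equal(keepLargestComponent(single)@data, single@data)
})
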