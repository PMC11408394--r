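# DSC / Hausdorff / mean-surface-distance metrics and paired statistics.

test_that("dsc reproduces hand values and degenerate conventions", {
  shape <- c(6L, 6L, 6L)
  a <- cuboid_mask(shape, 1:2, 1, 1)   # 2 voxels
  b <- cuboid_mask(shape, 1, 1, 1)     # 1 voxel, inside a
  expect_equal(dsc(a, a), 1)
  expect_equal(dsc(a, b), 2 / 3)
  expect_equal(dsc(a, cuboid_mask(shape, 5, 5, 5)), 0)
  empty <- array(FALSE, shape)
  expect_equal(dsc(empty, empty), 1)
})

test_that("surface voxels follow the face-adjacency definition", {
  shape <- c(7L, 7L, 7L)
  cube <- cuboid_mask(shape, 3:5, 3:5, 3:5)
  s <- surfaceVoxels(cube)
  expect_equal(sum(s), 26)             # all but the centre voxel
  expect_false(s[4, 4, 4])
  single <- cuboid_mask(shape, 2, 2, 2)
  expect_equal(which(surfaceVoxels(single)), which(single))
  expect_equal(sum(surfaceVoxels(array(FALSE, shape))), 0)
  # grid-border voxels count the outside as background: a full 3x3x3
  # grid is all surface except its centre
  border <- cuboid_mask(c(3L, 3L, 3L), 1:3, 1:3, 1:3)
  sb <- surfaceVoxels(border)
  expect_equal(sum(sb), 26)
  expect_false(sb[2, 2, 2])
})

test_that("HD and MSD match the tabulated anisotropic example", {
  shape <- c(6L, 4L, 4L)
  a <- cuboid_mask(shape, 1, 1, 1)
  b <- cuboid_mask(shape, 4, 1, 1)     # 3 voxels apart along x
  sp <- c(1.64, 1.64, 3.0)
  expect_equal(hausdorffDistance(a, b, sp), 4.92)
  expect_equal(meanSurfaceDistance(a, b, sp), 4.92)
  expect_equal(hausdorffDistance(a, a, sp), 0)
  expect_equal(meanSurfaceDistance(a, a, sp), 0)
  expect_equal(hausdorffDistance(a, b, sp), hausdorffDistance(b, a, sp))
  expect_error(hausdorffDistance(a, array(FALSE, shape), sp), "non-empty")
  expect_error(meanSurfaceDistance(array(FALSE, shape), b, sp),
               "non-empty")
})

test_that("HD/MSD agree with brute-force all-pairs surface distances", {
  set.seed(31)
  sp <- c(1.3, 0.8, 2.1)
  for (rep in 1:5) {
    a <- array(stats::runif(8^3) > 0.8, dim = c(8L, 8L, 8L))
    b <- array(stats::runif(8^3) > 0.8, dim = c(8L, 8L, 8L))
    if (!any(a)) a[2, 2, 2] <- TRUE
    if (!any(b)) b[5, 5, 5] <- TRUE
    oracle <- surface_metrics_oracle(a, b, sp)
    expect_equal(hausdorffDistance(a, b, sp), oracle$hd, tolerance = 1e-9)
    expect_equal(meanSurfaceDistance(a, b, sp), oracle$msd,
                 tolerance = 1e-9)
    expect_lte(meanSurfaceDistance(a, b, sp), hausdorffDistance(a, b, sp))
    # scaling the spacing scales both distances exactly
    expect_equal(hausdorffDistance(a, b, 2.5 * sp),
                 2.5 * hausdorffDistance(a, b, sp))
    expect_equal(meanSurfaceDistance(a, b, 2.5 * sp),
                 2.5 * meanSurfaceDistance(a, b, sp))
  }
})

test_that("dsc complements the single-channel Dice loss", {
  set.seed(32)
  for (rep in 1:10) {
    a <- array(stats::runif(6^3) > 0.6, dim = c(6L, 6L, 6L))
    b <- array(stats::runif(6^3) > 0.6, dim = c(6L, 6L, 6L))
    if (!any(a) && !any(b)) a[1, 1, 1] <- TRUE
    expect_equal(dsc(a, b),
                 1 - diceLoss(lab2(a), lab2(b),
                              excludeBackground = TRUE)@total,
                 tolerance = 1e-12)
  }
})

test_that("aggregation reports mean/median and sample SD", {
  rows <- data.frame(series_id = c("s1", "s2", "s3"),
                     structure = "bladder",
                     dsc = c(0.8, 0.9, 1.0), hd = c(2, 4, 6),
                     msd = c(1, 1, 1))
  agg <- aggregateMetrics(rows)
  d <- agg[agg$metric == "dsc", ]
  expect_equal(d$mean, 0.9)
  expect_equal(d$median, 0.9)
  expect_equal(d$sd, 0.1)
  m <- agg[agg$metric == "msd", ]
  expect_equal(m$mean, 1)
  expect_equal(m$sd, 0)
  single <- aggregateMetrics(rows[1, ])
  expect_true(all(single$sd_degenerate))
  expect_true(all(single$sd == 0))
})

test_that("paired Wilcoxon matches the exact tail and the reference implementation", {
  # n = 6 all-positive differences: exact two-sided p = 2/2^6
  x <- c(1.1, 2.3, 3.7, 4.1, 5.9, 6.2)
  y <- x - c(0.5, 0.4, 0.9, 0.11, 0.23, 0.35)
  expect_equal(pairedWilcoxon(x, y), 0.03125)
  expect_equal(pairedWilcoxon(x, y),
               stats::wilcox.test(x, y, paired = TRUE)$p.value)
  # two-sided symmetry under swapping
  expect_equal(pairedWilcoxon(x, y), pairedWilcoxon(y, x))

  # general exact case against the reference implementation
  set.seed(33)
  for (rep in 1:5) {
    a <- rnorm(12)
    b <- a + rnorm(12)
    expect_equal(pairedWilcoxon(a, b),
                 stats::wilcox.test(a, b, paired = TRUE,
                                    exact = TRUE)$p.value)
  }

  # large-sample normal approximation with ties
  set.seed(34)
  a <- round(rnorm(40), 1)
  b <- round(a + rnorm(40, sd = 0.5), 1)
  keep <- a != b
  ref <- stats::wilcox.test(a[keep], b[keep], paired = TRUE,
                            exact = FALSE, correct = FALSE)$p.value
  expect_equal(pairedWilcoxon(a, b), ref, tolerance = 1e-10)

  expect_error(pairedWilcoxon(a, a), "zero")
  expect_error(pairedWilcoxon(1:3, c(2, 3, 4)), "fewer than 5")
})
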