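# Dice, bounding-box and positional Dice losses: worked examples,
# brute-force oracle agreement and structural properties.

test_that("dice loss reproduces hand-computed values", {
  shape <- c(8L, 8L, 8L)
  p <- lab2(cuboid_mask(shape, 1:2, 1, 1))  # 2 voxels

  # identical masks
  expect_equal(diceLoss(p, p, excludeBackground = TRUE)@total, 0)
  expect_equal(diceLoss(p, p)@total, 0)

  # q covers 1 of p's 2 voxels
  q <- lab2(cuboid_mask(shape, 1, 1, 1))
  expect_equal(diceLoss(p, q, excludeBackground = TRUE)@total, 1 / 3)

  # disjoint foregrounds
  q2 <- lab2(cuboid_mask(shape, 5, 5, 5))
  expect_equal(diceLoss(p, q2, excludeBackground = TRUE)@total, 1)

  # both empty over the summed region -> 0 by convention
  empty <- lab2(array(FALSE, shape))
  expect_equal(diceLoss(empty, empty, excludeBackground = TRUE)@total, 0)

  # shape mismatch is a contract error
  expect_error(diceLoss(p, lab2(cuboid_mask(c(4L, 4L, 4L), 1, 1, 1))),
               "share shape")
})

test_that("axis projection and union extent follow the binarised profiles", {
  shape <- c(8L, 8L, 8L)
  cube <- cuboid_mask(shape, 1:4, 1:4, 1:4)
  px <- axisProjection(cube, "x", "crisp")
  expect_equal(px, c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(axisProjection(array(FALSE, shape), "x", "crisp"),
               rep(0, 8))
  # soft mode saturates integer sums to the crisp profile
  expect_equal(axisProjection(cube, "y", "soft"),
               axisProjection(cube, "y", "crisp"))

  a <- c(1, 1, 1, 1, 0, 0, 0, 0)
  b <- c(1, 1, 0, 0, 0, 0, 0, 0)
  expect_equal(unionExtent(a, b), 4)
  expect_equal(unionExtent(rep(0, 8), rep(0, 8)), 0)
  expect_equal(unionExtent(a, a), 4)
})

test_that("bbox and positional Dice losses match the nested-cube worked example", {
  shape <- c(8L, 8L, 8L)
  p <- lab2(cuboid_mask(shape, 1:4, 1:4, 1:4))  # 64 voxels
  q <- lab2(cuboid_mask(shape, 1:2, 1:4, 1:4))  # 32, nested at the corner

  expect_equal(bboxLoss(p, p)@total, 0)
  expect_equal(bboxLoss(p, q)@total, 1 / 6)  # (2+0+0)/(4+4+4)

  # prediction empty while truth is not: numerator equals denominator
  expect_equal(bboxLoss(p, lab2(array(FALSE, shape)))@total, 1)

  pdl <- positionalDiceLoss(p, q, excludeBackground = TRUE)
  expect_equal(unname(pdl@components["dice"]), 1 / 3)  # 1 - 2*32/96
  expect_equal(unname(pdl@components["bbox"]), 1 / 6)
  expect_equal(pdl@total, 1 / 2)
  expect_equal(pdl@total, sum(pdl@components))
})

test_that("bbox loss equals the brute-force occupancy-set oracle on random pairs", {
  set.seed(11)
  for (i in 1:60) {
    nch <- sample(2:4, 1)
    parr <- random_onehot(c(8L, 8L, 8L), nch)
    qarr <- random_onehot(c(8L, 8L, 8L), nch)
    expect_equal(bboxLoss(parr, qarr)@total, bbox_oracle(parr, qarr),
                 tolerance = 1e-12)
  }
})

test_that("losses are symmetric and translation covariant on crisp masks", {
  set.seed(12)
  for (i in 1:10) {
    parr <- random_onehot(c(6L, 6L, 6L), 3L)
    qarr <- random_onehot(c(6L, 6L, 6L), 3L)
    expect_equal(diceLoss(parr, qarr, TRUE)@total,
                 diceLoss(qarr, parr, TRUE)@total)
    expect_equal(bboxLoss(parr, qarr)@total, bboxLoss(qarr, parr)@total)
  }

  # translate both masks by the same offset inside a larger grid
  shape <- c(10L, 10L, 10L)
  p1 <- lab2(cuboid_mask(shape, 1:3, 2:4, 1:2))
  q1 <- lab2(cuboid_mask(shape, 2:3, 2:5, 1:3))
  p2 <- lab2(cuboid_mask(shape, 4:6, 5:7, 6:7))
  q2 <- lab2(cuboid_mask(shape, 5:6, 5:8, 6:8))
  for (fn in list(function(p, q) diceLoss(p, q, TRUE),
                  bboxLoss,
                  function(p, q) positionalDiceLoss(p, q, TRUE)))
    expect_equal(fn(p1, q1)@total, fn(p2, q2)@total)
})

test_that("dice + cross-entropy has the closed-form uniform value", {
  shape <- c(4L, 4L, 4L)
  parr <- random_onehot(shape, 4L)
  qarr <- array(0.25, dim = c(shape, 4L))
  lv <- diceCrossEntropyLoss(parr, qarr)
  expect_equal(unname(lv@components["cross_entropy"]), log(4))
  expect_equal(lv@total, sum(lv@components))

  # near-identity: smoothed one-hot gives a near-zero loss
  qs <- parr * (1 - 3e-7) + (1 - parr) * 1e-7
  lv2 <- diceCrossEntropyLoss(parr, qs)
  expect_lt(lv2@total, 1e-5)
})

test_that("loss ranges hold on random soft predictions", {
  set.seed(13)
  for (i in 1:10) {
    parr <- random_onehot(c(6L, 6L, 6L), 4L)
    qarr <- random_soft(c(6L, 6L, 6L), 4L)
    d <- diceLoss(parr, qarr, TRUE)@total
    b <- bboxLoss(parr, qarr)@total
    expect_gte(d, 0); expect_lte(d, 1)
    expect_gte(b, 0); expect_lte(b, 1)
    expect_equal(positionalDiceLoss(parr, qarr, TRUE)@total, d + b)
  }
})
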