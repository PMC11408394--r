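# Architecture contracts: construction, forward shapes, softmax
# normalisation, bottleneck structure, mask branch and weight transfer.

spec8 <- function(name, nClasses = 4L)
  networkSpec(name, nClasses = nClasses, baseFilters = 4L)

test_that("all three architectures forward with channel-normalised output", {
  img <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  for (name in c("unet3d", "mnet", "dmnet")) {
    net <- buildNetwork(spec8(name), seed = 5)
    pred <- networkForward(net, img,
                           classVector = if (name == "unet3d") NULL else
                             c(0, 1, 1, 0))
    expect_equal(dim(pred@data), c(16L, 16L, 8L, 4L))
    expect_true(all(pred@data >= 0))
    expect_lt(max(abs(.channel_sums(pred@data) - 1)), 1e-5)
  }
})

test_that("input extents must be divisible by the downsampling factor", {
  net <- buildNetwork(spec8("unet3d"), seed = 1)
  img <- array(0, dim = c(30, 30, 15))
  expect_error(networkForward(net, img), "divisible by 8")
})

test_that("the deepest feature map is the input shrunk by 2^(levels-1)", {
  net <- buildNetwork(spec8("unet3d"), seed = 1)
  img <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  out <- networkForward(net, img, activations = TRUE)
  spatial <- vapply(out$activations, function(v) dim(v)[1], numeric(1))
  expect_equal(min(spatial), 16 / 2^(net@spec@levels - 1))
})

test_that("masked networks require and respond to the class-label input", {
  net <- buildNetwork(spec8("mnet"), seed = 6)
  img <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  expect_error(networkForward(net, img), "class-label")
  expect_error(networkForward(net, img, classVector = c(1, 0)),
               "does not match")

  # an all-zero class vector still forwards with the contracted shape
  p0 <- networkForward(net, img, classVector = c(0, 0, 0, 0))
  expect_equal(dim(p0@data), c(16L, 16L, 8L, 4L))

  # different class vectors change the output of the untrained network
  p1 <- networkForward(net, img, classVector = c(0, 1, 1, 0))
  expect_gt(max(abs(p1@data - p0@data)), 1e-8)

  # one mask injection per encoder resolution
  mask_convs <- grep("^mask[0-9]+\\.conv\\.W$", names(net@params),
                     value = TRUE)
  expect_length(mask_convs, net@spec@levels)
})

test_that("the DM-Net bottleneck is three equal-dilation, filter-descending blocks", {
  net <- buildNetwork(spec8("dmnet"), seed = 7)
  dcl <- lapply(1:3, function(i) {
    id <- which(vapply(net@nodes, function(nd)
      identical(nd$p, sprintf("bneck.dcl%d.conv", i)), logical(1)))
    net@nodes[[id]]
  })
  expect_equal(vapply(dcl, function(nd) nd$dil, numeric(1)), rep(2, 3))
  filters <- vapply(dcl, function(nd) nd$Co, numeric(1))
  expect_equal(filters, net@spec@baseFilters * c(4, 2, 1))
  expect_true(all(diff(filters) < 0))
  # followed by exactly one standard conv before the decoder
  expect_true("bneck.conv.conv.W" %in% names(net@params))
  # dilated blocks carry no dropout (leaky-ReLU path)
  dcl_act <- vapply(net@nodes, function(nd)
    nd$op == "lrelu", logical(1))
  expect_equal(sum(dcl_act), 3)
})

test_that("parameter counts order dmnet > mnet > unet3d", {
  n_unet <- countParameters(buildNetwork(spec8("unet3d"), seed = 1))
  n_mnet <- countParameters(buildNetwork(spec8("mnet"), seed = 1))
  n_dmnet <- countParameters(buildNetwork(spec8("dmnet"), seed = 1))
  expect_gt(n_mnet, n_unet)
  expect_gt(n_dmnet, n_mnet)
})

test_that("forward passes are reproducible for fixed seeds", {
  img <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  n1 <- buildNetwork(spec8("dmnet"), seed = 9)
  n2 <- buildNetwork(spec8("dmnet"), seed = 9)
  p1 <- networkForward(n1, img, classVector = c(0, 1, 0, 0))
  p2 <- networkForward(n2, img, classVector = c(0, 1, 0, 0))
  expect_identical(p1@data, p2@data)
})

test_that("weight transfer copies matching tensors and reinitialises the head", {
  # same-spec transfer: everything copies
  src <- buildNetwork(spec8("unet3d"), seed = 10)
  tw <- transferWeights(src, spec8("unet3d"), seed = 11)
  expect_true(all(tw$manifest$status == "copied"))
  expect_equal(tw$network@params, src@params)

  # 5-class source (male-pelvis task) to 4-class target: only the head
  # changes
  src5 <- buildNetwork(spec8("unet3d", nClasses = 5L), seed = 10)
  tw2 <- transferWeights(src5, spec8("unet3d", nClasses = 4L), seed = 11)
  reinit <- tw2$manifest$name[tw2$manifest$status == "reinitialized"]
  expect_setequal(reinit, c("head.W", "head.b"))

  # activations agree up to the head on a fixed input
  img <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  a_src <- networkForward(src5, img, activations = TRUE)
  a_tgt <- networkForward(tw2$network, img, activations = TRUE)
  expect_equal(a_tgt$penultimate, a_src$penultimate, tolerance = 1e-12)

  # incompatible pairing fails
  tiny <- buildNetwork(networkSpec("unet3d", nClasses = 3L,
                                   baseFilters = 3L), seed = 1)
  expect_error(transferWeights(tiny, spec8("dmnet")), "no parameter")
})

test_that("checkpoints round-trip the network", {
  net <- buildNetwork(spec8("mnet"), seed = 12)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f)
  expect_true(file.exists(paste0(f, ".manifest.json")))
  back <- loadCheckpoint(f)
  img <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  expect_identical(networkForward(net, img, classVector = c(0, 1, 0, 0))@data,
                   networkForward(back, img, classVector = c(0, 1, 0, 0))@data)
})
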