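# Synthetic phantom generation: determinism, calibrated volumes,
# population ranges and internal consistency of the class vectors.

test_that("generation is deterministic and piecewise constant without noise", {
  spec <- phantomSpec(shape = c(32L, 32L, 16L),
                      spacing = c(13.125, 13.125, 12),
                      noiseSD = 0, biasAmplitude = 0, seed = 3L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxelData(caseImage(a)), voxelData(caseImage(b)))
  expect_identical(voxelData(caseLabels(a)), voxelData(caseLabels(b)))
  # noise-free, bias-free image takes exactly the four structure means
  expect_setequal(unique(as.numeric(voxelData(caseImage(a)))),
                  c(100, 200, 140, 60))

  # different seeds give different anatomy
  c_ <- generatePhantom(phantomSpec(shape = c(32L, 32L, 16L),
                                    spacing = c(13.125, 13.125, 12),
                                    noiseSD = 0, biasAmplitude = 0,
                                    seed = 4L))
  expect_false(identical(voxelData(caseLabels(a)), voxelData(caseLabels(c_))))
})

test_that("rasterized structure volumes match the requested volumes", {
  # spherical 30 mm bladder: (4/3) pi 27 cm^3
  cs <- generatePhantom(phantomSpec(bladderVolume = 4 / 3 * pi * 27,
                                    seed = 5L))
  vv <- prod(voxelSpacing(caseLabels(cs))) / 1000
  bl <- sum(cs@componentMasks$bladder) * vv
  expect_lt(abs(bl - 4 / 3 * pi * 27) / (4 / 3 * pi * 27), 0.05)

  set.seed(61)
  for (seed in sample.int(1e6, 6)) {
    vols <- list(bladderVolume = runif(1, 40, 600),
                 gtvVolume = runif(1, 15, 500),
                 rectumVolume = runif(1, 20, 200))
    cs2 <- generatePhantom(do.call(phantomSpec,
                                   c(vols, list(seed = as.integer(seed)))))
    vv2 <- prod(voxelSpacing(caseLabels(cs2))) / 1000
    expect_lt(abs(sum(cs2@componentMasks$bladder) * vv2 -
                    vols$bladderVolume) / vols$bladderVolume, 0.05)
    expect_lt(abs(sum(cs2@componentMasks$GTV) * vv2 -
                    vols$gtvVolume) / vols$gtvVolume, 0.05)
    expect_lt(abs(sum(cs2@componentMasks$rectum) * vv2 -
                    vols$rectumVolume) / vols$rectumVolume, 0.05)
  }
})

test_that("phantom labels are one-hot with single-component structures", {
  for (seed in 1:4) {
    cs <- small_phantom(seed)
    lab <- voxelData(caseLabels(cs))
    expect_true(all(.channel_sums(lab) == 1))
    for (ch in 2:4) {
      m <- lab[, , , ch] > 0
      expect_true(any(m))
      cc <- .label_cc26(m, dim(m))
      expect_equal(max(cc), 1L)
    }
  }
})

test_that("stored class vectors match re-derivation from the component masks", {
  for (seed in c(2, 9, 14)) {
    cs <- generatePhantom(phantomSpec(gtvVolume = c(60, 500, 120)[seed %% 3 + 1],
                                      uterusVolume = 60,
                                      seed = as.integer(seed)))
    sp <- voxelSpacing(caseImage(cs))
    vec <- suppressWarnings(assignClassLabels(cs@componentMasks$bladder,
                                              cs@componentMasks$GTV,
                                              cs@componentMasks$uterus, sp))
    expect_equal(classVector(cs), unname(vec))
  }
})

test_that("population sampling spans the configured volume ranges", {
  pop <- samplePhantomPopulation(12, seed = 8, variation = "paper-range")
  vv <- prod(voxelSpacing(caseLabels(pop[[1]]))) / 1000
  bl <- vapply(pop, function(cs) sum(cs@componentMasks$bladder) * vv,
               numeric(1))
  gtv <- vapply(pop, function(cs) sum(cs@componentMasks$GTV) * vv,
                numeric(1))
  re <- vapply(pop, function(cs) sum(cs@componentMasks$rectum) * vv,
               numeric(1))
  # rasterized volumes stay within the clinical ranges (5% slack for
  # series jitter and quantisation at the extremes)
  expect_true(all(bl > 30.08 * 0.85 & bl < 721.8 * 1.15))
  expect_true(all(gtv > 11.42 * 0.85 & gtv < 712.31 * 1.15))
  expect_true(all(re > 19.3 * 0.85 & re < 213.45 * 1.15))
  expect_gt(max(bl) / min(bl), 2)   # actually spans a wide range

  # distinct patients, reproducible per seed, n = patients x series
  expect_length(unique(vapply(pop, patientId, character(1))), 12)
  pop2 <- samplePhantomPopulation(12, seed = 8, variation = "paper-range")
  expect_identical(voxelData(caseLabels(pop[[3]])),
                   voxelData(caseLabels(pop2[[3]])))
  pop3 <- samplePhantomPopulation(2, seed = 9, variation = "small",
                                  seriesPerPatient = 3)
  expect_length(pop3, 6)
  expect_false(identical(voxelData(caseLabels(pop3[[1]])),
                         voxelData(caseLabels(pop3[[2]]))))
})
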