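makeBankFixture <- function() {
  fixture("lesionBank", function() {
    ph <- makePhantom(phantomSpec(shape = c(48, 48, 48), seed = 21,
                                  lesionCount = 2,
                                  lesionRadiusRange = c(4.5, 5.5)))
    makeLesionBank(list(ph), groupIds = "g01")
  })
}

test_that("inserted lesion cores match surrounding lung statistics", {
  # larger grid and lesions here so the core has enough voxels for stable
  # mean/SD estimates
  ph <- makePhantom(phantomSpec(shape = c(64, 64, 64), seed = 22))
  donor <- makePhantom(phantomSpec(shape = c(64, 64, 64), seed = 23,
                                   lesionCount = 4,
                                   lesionRadiusRange = c(6, 7.5)))
  bank <- makeLesionBank(list(donor), groupIds = "g01")
  d <- dim(ph$ct)
  lung <- array(labelArray(ph$labels) %in% 1:5, dim = d)
  out <- insertLesion(ph$ct, lung, bank[[1]], blendSigma = 1)

  mask <- bank[[1]]$mask
  w <- array(LobeSeg:::cpp_gauss3(as.double(mask), d, 1), dim = d)
  w[!lung] <- 0
  core <- w > 0.99
  expect_gt(sum(core), 20)  # the blend must have a genuine core
  lungStats <- intensities(ph$ct)[lung & !mask]
  coreVals <- intensities(out)[core]
  expect_lt(abs(mean(coreVals) - mean(lungStats)) / mean(lungStats), 0.05)
  expect_lt(abs(sd(coreVals) - sd(lungStats)) / sd(lungStats), 0.05)

  # outside the blur support the target is bit-identical
  expect_identical(intensities(out)[w == 0], intensities(ph$ct)[w == 0])
  # all modified voxels lie inside the lung
  changed <- intensities(out) != intensities(ph$ct)
  expect_true(all(lung[changed]))
  expect_gte(min(intensities(out)), 0)
  expect_lte(max(intensities(out)), 1)
})

test_that("degenerate lesion placements are handled per contract", {
  ph <- smallPhantom()
  d <- dim(ph$ct)
  lung <- array(labelArray(ph$labels) %in% 1:5, dim = d)
  entry <- list(intensities = intensities(ph$ct),
                mask = array(FALSE, dim = d), groupId = "g01")
  entry$mask[1:3, 1:3, 1:3] <- TRUE  # corner: outside the lung
  expect_warning(out <- insertLesion(ph$ct, lung, entry), "outside the lung")
  expect_identical(intensities(out), intensities(ph$ct))
  expect_error(insertLesion(ph$ct, array(FALSE, dim = d), entry),
               "empty lung mask")
})

test_that("blendSigma -> 0 reduces to a hard paste inside the mask", {
  ph <- smallPhantom()
  bank <- makeBankFixture()
  d <- dim(ph$ct)
  lung <- array(labelArray(ph$labels) %in% 1:5, dim = d)
  out <- insertLesion(ph$ct, lung, bank[[1]], blendSigma = 0)
  mask <- bank[[1]]$mask & lung
  expect_identical(intensities(out)[!mask], intensities(ph$ct)[!mask])
})

test_that("an identity augmentation draw is bit-exact", {
  ph <- smallPhantom()
  cfg <- augmentConfig(crop = 48L, lesionProb = 0, scaleRange = c(1, 1),
                       rotateDeg = 0, mirrorProb = 0, noiseSd = 0,
                       blurProb = 0, brightness = 0, contrast = c(1, 1))
  out <- augmentSample(ph$ct, ph$labels, cfg, seed = 9)
  expect_identical(intensities(out$ct), intensities(ph$ct))
  expect_identical(labelArray(out$labels), labelArray(ph$labels))
})

test_that("mirroring is an involution and draws are seed-deterministic", {
  ph <- smallPhantom()
  cfg <- augmentConfig(crop = 48L, lesionProb = 0, scaleRange = c(1, 1),
                       rotateDeg = 0, mirrorProb = 1, noiseSd = 0,
                       blurProb = 0, brightness = 0, contrast = c(1, 1))
  once <- augmentSample(ph$ct, ph$labels, cfg, seed = 4)
  twice <- augmentSample(once$ct, once$labels, cfg, seed = 4)
  expect_identical(intensities(twice$ct), intensities(ph$ct))
  expect_identical(labelArray(twice$labels), labelArray(ph$labels))

  full <- augmentConfig(crop = 32L)
  a <- augmentSample(ph$ct, ph$labels, full, seed = 12,
                     lesionBank = makeBankFixture())
  b <- augmentSample(ph$ct, ph$labels, full, seed = 12,
                     lesionBank = makeBankFixture())
  expect_identical(intensities(a$ct), intensities(b$ct))
  expect_identical(labelArray(a$labels), labelArray(b$labels))
})

test_that("geometric augmentation never invents label classes", {
  ph <- smallPhantom()
  cfg <- augmentConfig(crop = 40L)
  present <- unique(as.integer(labelArray(ph$labels)))
  for (seed in 1:5) {
    out <- augmentSample(ph$ct, ph$labels, cfg, seed = seed)
    expect_true(all(unique(as.integer(labelArray(out$labels))) %in% present))
    expect_identical(dim(out$ct), c(40L, 40L, 40L))
  }
  expect_error(augmentSample(ph$ct, ph$labels, augmentConfig(crop = 64L)),
               "crop larger")
})

test_that("lesion insertion actually fires across seeded draws", {
  ph <- smallPhantom()
  bank <- makeBankFixture()
  cfg <- augmentConfig(crop = 48L, lesionProb = 0.5, scaleRange = c(1, 1),
                       rotateDeg = 0, mirrorProb = 0, noiseSd = 0,
                       blurProb = 0, brightness = 0, contrast = c(1, 1))
  fired <- vapply(1:30, function(seed) {
    out <- augmentSample(ph$ct, ph$labels, cfg, seed = seed,
                         lesionBank = bank)
    !identical(intensities(out$ct), intensities(ph$ct))
  }, logical(1))
  expect_gt(sum(fired), 0)
  expect_lt(sum(fired), 30)  # and it is genuinely stochastic
})
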