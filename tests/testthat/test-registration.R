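test_that("center-of-mass init recovers pure translations", {
  d <- c(48, 48, 48)
  blob <- function(cen) {
    cc <- lapply(1:3, function(a) (1:48) - cen[a])
    r2 <- outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`)
    ctVolume(array(exp(-r2 / 50), dim = d), normalized = TRUE)
  }
  fixed <- blob(c(20, 24, 24))
  moving <- blob(c(25, 24, 24))  # shifted by (5, 0, 0) voxels at 1 mm
  t <- centerOfMassInit(fixed, moving)
  expect_lt(abs(t@preAlign[1] - 5), 0.5)
  expect_lt(max(abs(t@preAlign[2:3])), 0.5)

  tId <- centerOfMassInit(fixed, fixed)
  expect_lt(max(abs(tId@preAlign)), 1e-9)

  flat <- ctVolume(array(1, dim = c(16, 16, 16)))
  expect_lt(max(abs(centerOfMassInit(flat, flat)@preAlign)), 1e-9)
  expect_error(centerOfMassInit(flat, ctVolume(array(0, dim = c(16, 16, 16)))),
               "zero total intensity")
})

test_that("identity registration yields a near-zero field", {
  ph <- makePhantom(phantomSpec(shape = c(32, 32, 32), seed = 13))
  tr <- registerDiffeomorphic(ph$ct, ph$ct, levels = c(20, 10, 5))
  mag <- sqrt(tr@forward$x^2 + tr@forward$y^2 + tr@forward$z^2)
  expect_lt(mean(mag), 0.2)
  warped <- applyTransform(tr, ph$ct, "forward")
  expect_lt(mean(abs(intensities(warped) - intensities(ph$ct))), 0.01)
})

test_that("registration requires normalized inputs and is deterministic", {
  raw <- ctVolume(array(rnorm(32^3, -500, 300), dim = c(32, 32, 32)))
  expect_error(registerDiffeomorphic(raw, raw), "normalized")
  ph <- makePhantom(phantomSpec(shape = c(32, 32, 32), seed = 13))
  co <- makeCohort(2, phantomSpec(shape = c(32, 32, 32), seed = 13),
                   variability = 1)
  a <- registerDiffeomorphic(co[[1]]$ct, co[[2]]$ct, levels = c(15, 8, 4))
  b <- registerDiffeomorphic(co[[1]]$ct, co[[2]]$ct, levels = c(15, 8, 4))
  expect_identical(a@forward, b@forward)
  expect_identical(a@inverse, b@inverse)
})

test_that("transforms move labels without inventing classes", {
  co <- makeCohort(2, phantomSpec(shape = c(48, 48, 48), seed = 17),
                   variability = 2)
  tr <- registerDiffeomorphic(co[[1]]$ct, co[[2]]$ct, levels = c(40, 20, 10))
  warped <- applyTransform(tr, co[[2]]$labels, "forward")
  expect_true(all(unique(as.integer(labelArray(warped))) %in%
                    unique(as.integer(labelArray(co[[2]]$labels)))))
  # registration improves lobe alignment over the unregistered state
  before <- LobeSeg:::.meanLobeDice(labelArray(co[[2]]$labels),
                                    labelArray(co[[1]]$labels))
  after <- LobeSeg:::.meanLobeDice(labelArray(warped),
                                   labelArray(co[[1]]$labels))
  expect_gt(after, before)

  # forward-then-inverse label round trip stays faithful
  back <- applyTransform(tr, warped, "inverse")
  rt <- mean(vapply(1:5, function(k)
    diceScore(labelArray(back) == k, labelArray(co[[2]]$labels) == k),
    numeric(1)))
  expect_gt(rt, 0.9)
})

test_that("constant images are fixed points of any transform", {
  co <- makeCohort(2, phantomSpec(shape = c(32, 32, 32), seed = 19),
                   variability = 1.5)
  tr <- registerDiffeomorphic(co[[1]]$ct, co[[2]]$ct, levels = c(15, 8, 4))
  const <- ctVolume(array(0.25, dim = c(32, 32, 32)), normalized = TRUE)
  out <- applyTransform(tr, const, "forward")
  expect_lt(max(abs(intensities(out) - 0.25)), 1e-9)
})

test_that("geometry mismatches are rejected", {
  ph <- makePhantom(phantomSpec(shape = c(32, 32, 32), seed = 13))
  tr <- registerDiffeomorphic(ph$ct, ph$ct, levels = c(5, 3, 2))
  small <- ctVolume(array(0.1, dim = c(16, 16, 16)), normalized = TRUE)
  expect_error(applyTransform(tr, small, "forward"), "geometry")
})

test_that("the transform cache round-trips bit-identically", {
  co <- makeCohort(2, phantomSpec(shape = c(32, 32, 32), seed = 23),
                   variability = 1)
  tr <- registerDiffeomorphic(co[[1]]$ct, co[[2]]$ct, levels = c(10, 5, 3))
  cacheDir <- file.path(tempdir(), "regcache")
  key <- transformCacheKey(co[[1]]$ct, co[[2]]$ct, c(10, 5, 3))
  cacheTransform(tr, key, cacheDir)
  back <- loadCachedTransform(key, cacheDir)
  expect_false(is.null(back))
  a <- applyTransform(tr, co[[2]]$labels, "forward")
  b <- applyTransform(back, co[[2]]$labels, "forward")
  expect_identical(labelArray(a), labelArray(b))

  expect_null(loadCachedTransform("deadbeef", cacheDir))
  # corrupt entry is treated as absent with a warning
  p <- LobeSeg:::.cachePaths(key, cacheDir)
  writeLines("not json", p$meta)
  expect_warning(expect_null(loadCachedTransform(key, cacheDir)), "corrupt")

  # the key depends on content and schedule
  expect_false(transformCacheKey(co[[1]]$ct, co[[2]]$ct, c(10, 5, 3)) ==
                 transformCacheKey(co[[1]]$ct, co[[2]]$ct, c(9, 5, 3)))
})
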