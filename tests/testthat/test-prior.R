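test_that("grouping by Dice forms connected components at the threshold", {
  ph <- smallPhantom()
  same <- list(ph$labels, ph$labels, ph$labels)
  ga <- groupByDice(same)
  expect_length(groups(ga), 1)
  expect_identical(sort(groups(ga)[[1]]), 1:3)
  expect_true(all(diceMatrix(ga) == 1))

  # two disjoint anatomies: swap lobes with background far away
  d <- dim(ph$labels)
  other <- array(0L, dim = d)
  other[1:4, 1:4, 1:4] <- 1L  # tiny fake lobe far from the lungs
  ga2 <- groupByDice(list(ph$labels, labelMap(other)))
  expect_length(groups(ga2), 2)

  bad <- labelMap(array(0L, dim = c(8, 8, 8)))
  expect_error(groupByDice(list(ph$labels, bad)), "same grid")
})

test_that("grouping matches a brute-force component oracle on random matrices", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    D <- matrix(runif(n * n), n)
    D <- (D + t(D)) / 2; diag(D) <- 1
    got <- lapply(groups(groupFromDiceMatrix(D, 0.8)), as.integer)
    want <- lapply(bfComponents(D >= 0.8), as.integer)
    expect_identical(got, want)
  }
})

test_that("label fusion computes exact fractions before smoothing", {
  d <- c(8, 8, 8)
  mk <- function(vals) {
    arr <- array(0L, dim = d); arr[3:6, 3:6, 3:6] <- vals; labelMap(arr)
  }
  ct <- ctVolume(array(0.5, dim = d), normalized = TRUE)
  # one member: one-hot channels
  a1 <- buildAtlas(list(list(ct = ct, labels = mk(2L))), sigma = 0)
  expect_setequal(unique(as.vector(atlasProbs(a1))), c(0, 1))
  expect_true(all(atlasProbs(a1)[3:6, 3:6, 3:6, 2] == 1))

  # two members disagreeing lobe-2 vs lobe-3: exactly 0.5 / 0.5
  a2 <- buildAtlas(list(list(ct = ct, labels = mk(2L)),
                        list(ct = ct, labels = mk(3L))), sigma = 0)
  expect_true(all(atlasProbs(a2)[3:6, 3:6, 3:6, 2] == 0.5))
  expect_true(all(atlasProbs(a2)[3:6, 3:6, 3:6, 3] == 0.5))
  expect_true(all(atlasProbs(a2)[, , , c(1, 4, 5)] == 0))

  expect_error(buildAtlas(list()), "empty")
})

test_that("smoothed atlases renormalize to unit channel sums on support", {
  atlas <- smallAtlas()
  p <- atlasProbs(atlas)
  s <- rowSums(matrix(p, ncol = 5))
  supported <- s > 1e-9
  expect_lt(max(abs(s[supported] - 1)), 1e-6)
  expect_gte(min(p), 0); expect_lte(max(p), 1 + 1e-9)
  expect_identical(nMembers(atlas), 4L)
})

test_that("atlas fusion is invariant to member order", {
  co <- smallCohort()
  members <- lapply(co, function(m) m[c("ct", "labels")])
  a <- buildAtlas(members, sigma = 1, reference = co[[1]]$ct)
  b <- buildAtlas(rev(members), sigma = 1, reference = co[[1]]$ct)
  expect_equal(atlasProbs(a), atlasProbs(b), tolerance = 1e-12)
})

test_that("composite similarity reproduces its closed form and oracle terms", {
  ph <- smallPhantom()
  a <- ph$ct
  # identical images: MSE term 1, NCC term 1, MI = self-entropy
  x <- as.double(intensities(a))
  bins <- pmin(32L, pmax(1L, as.integer(x * 32L) + 1L))
  p <- tabulate(bins, 32L) / length(bins)
  H <- -sum(p[p > 0] * log(p[p > 0]))
  expect_equal(compositeSimilarity(a, a), 2 + H, tolerance = 1e-9)

  # anticorrelated image: NCC term exactly 0
  neg <- ctVolume(1 - intensities(a), normalized = TRUE)
  mse <- mean((x - (1 - x))^2)
  mi <- mutualInformation(x, 1 - x)
  expect_equal(compositeSimilarity(a, neg), 1 / (1 + mse) + 0 + mi,
               tolerance = 1e-9)

  # independent noise images vs a per-term brute-force oracle
  set.seed(0); n1 <- array(runif(64^3), dim = c(64, 64, 64))
  set.seed(1); n2 <- array(runif(64^3), dim = c(64, 64, 64))
  va <- ctVolume(n1, normalized = TRUE); vb <- ctVolume(n2, normalized = TRUE)
  oMse <- mean((n1 - n2)^2)
  oNcc <- stats::cor(as.vector(n1), as.vector(n2))
  bi <- function(v) pmin(32L, pmax(1L, as.integer(v * 32L) + 1L))
  jo <- table(factor(bi(n1), 1:32), factor(bi(n2), 1:32)) / length(n1)
  pj <- as.vector(jo); px <- rowSums(jo); py <- colSums(jo)
  oMi <- sum(pj[pj > 0] * log(pj[pj > 0])) -
    sum(px[px > 0] * log(px[px > 0])) - sum(py[py > 0] * log(py[py > 0]))
  expect_equal(compositeSimilarity(va, vb),
               1 / (1 + oMse) + (oNcc + 1) / 2 + oMi, tolerance = 1e-6)
  expect_error(compositeSimilarity(va, ctVolume(array(0, c(8, 8, 8)),
                                                normalized = TRUE)),
               "same grid")
})

test_that("atlas selection picks the self-matching reference", {
  co <- smallCohort()
  atlasA <- buildAtlas(lapply(co[1:2], function(m) m[c("ct", "labels")]),
                       reference = co[[1]]$ct, groupId = "g01")
  coB <- makeCohort(2, phantomSpec(shape = c(48, 48, 48), seed = 99,
                                   fissureTilt = 12), variability = 1)
  atlasB <- buildAtlas(lapply(coB, function(m) m[c("ct", "labels")]),
                       reference = coB[[1]]$ct, groupId = "g02")
  sel <- selectAtlas(co[[1]]$ct, list(atlasB, atlasA),
                     levels = c(30, 15, 8))
  expect_identical(groupId(sel$atlas), "g01")
  expect_gt(sel$scores[["g01"]], sel$scores[["g02"]])

  single <- selectAtlas(co[[1]]$ct, list(atlasA), levels = c(10, 5, 3))
  expect_identical(groupId(single$atlas), "g01")
  expect_error(selectAtlas(co[[1]]$ct, list()), "empty")
})

test_that("prior fill labels every gap inside the lung", {
  ph <- smallPhantom()
  atlas <- smallAtlas()
  lab <- labelArray(ph$labels)
  d <- dim(lab)
  lung <- array(lab %in% 1:5, dim = d)

  # complete segmentation is untouched
  res0 <- fillFromAtlas(ph$labels, lung, atlas)
  expect_identical(labelArray(res0$labels), lab)

  # carve a hole inside the RLL and recover it
  rllIdx <- which(lab == 3L, arr.ind = TRUE)
  cen <- round(colMeans(rllIdx))
  hole <- lab
  sl <- lapply(1:3, function(a) max(1, cen[a] - 4):min(d[a], cen[a] + 4))
  holeRegion <- array(FALSE, dim = d)
  holeRegion[sl[[1]], sl[[2]], sl[[3]]] <- TRUE
  holeRegion <- holeRegion & lab == 3L
  hole[holeRegion] <- 0L
  res <- fillFromAtlas(labelMap(hole), lung, atlas)
  out <- labelArray(res$labels)
  expect_identical(sum(lung & out == 0L), 0L)
  expect_gte(mean(out[holeRegion] == 3L), 0.95)
  expect_true(all(res$provenance[holeRegion] %in% c(2L, 3L)))

  # argmax ties break to the lowest channel index
  tieProbs <- array(0, dim = c(d, 5))
  tieProbs[, , , 2] <- 0.5; tieProbs[, , , 3] <- 0.5
  tieAtlas <- new("ProbAtlas", probs = tieProbs, reference = ph$ct,
                  groupId = "tie", nMembers = 1L, sigma = 0)
  resTie <- fillFromAtlas(labelMap(hole), lung, tieAtlas)
  expect_true(all(labelArray(resTie$labels)[holeRegion] == 2L))

  # zero-support atlas falls back to the nearest labelled voxel
  zeroAtlas <- new("ProbAtlas", probs = array(0, dim = c(d, 5)),
                   reference = ph$ct, groupId = "z", nMembers = 1L,
                   sigma = 0)
  resZ <- fillFromAtlas(labelMap(hole), lung, zeroAtlas)
  expect_identical(sum(lung & labelArray(resZ$labels) == 0L), 0L)
  expect_true(all(resZ$provenance[holeRegion] == 3L))
})

test_that("atlas persistence round-trips through NIfTI + JSON", {
  atlas <- smallAtlas()
  dir <- file.path(tempdir(), "atlas_g1")
  saveAtlas(atlas, dir)
  back <- readAtlas(dir)
  expect_equal(atlasProbs(back), atlasProbs(atlas), tolerance = 1e-12)
  expect_identical(groupId(back), groupId(atlas))
  expect_identical(nMembers(back), nMembers(atlas))
})
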