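mkPred <- function(act) {
  new("StagePrediction", activations = act, stage = 2L,
      gridMeta = list(dim = dim(act)[1:3], spacing = c(1, 1, 1)))
}

test_that("decoder fusion applies the threshold/argmax/lung-gate rules", {
  d <- c(8, 8, 8)
  act <- array(0, dim = c(d, 7))
  act[, , , 6] <- 1  # whole lung everywhere -> lung mask = full grid

  act[1, 1, 1, 1] <- 0.9; act[1, 1, 1, 2] <- 0.2      # clear lobe-1 win
  act[2, 1, 1, 1] <- 0.6; act[2, 1, 1, 3] <- 0.8      # argmax -> lobe 3
  act[3, 1, 1, 1] <- 0.7; act[3, 1, 1, 2] <- 0.7      # tie -> lowest index
  act[4, 1, 1, 7] <- 0.95; act[4, 1, 1, 1] <- 0.6     # airway argmax
  act[5, 1, 1, 7] <- 0.6; act[5, 1, 1, 1] <- 0.9      # lobe beats airway
  # voxel (6,1,1): all activations < 0.5 -> gap
  fr <- fuseDecoders(mkPred(act))
  lab <- labelArray(fr@labels)
  expect_identical(lab[1, 1, 1], 1L)
  expect_identical(lab[2, 1, 1], 3L)
  expect_identical(lab[3, 1, 1], 1L)
  expect_identical(lab[4, 1, 1], 6L)
  expect_identical(lab[5, 1, 1], 1L)
  expect_identical(lab[6, 1, 1], 0L)
  expect_true(fr@gapMask[6, 1, 1])
  expect_false(fr@gapMask[1, 1, 1])

  # outside the lung mask, activations are disregarded
  act2 <- array(0, dim = c(d, 7))
  act2[1:4, , , 6] <- 1                    # lung only in x 1..4
  act2[6, 2, 2, 1] <- 0.9                  # strong lobe outside the lung
  fr2 <- fuseDecoders(mkPred(act2))
  expect_identical(labelArray(fr2@labels)[6, 2, 2], 0L)
  expect_false(fr2@gapMask[6, 2, 2])
})

test_that("the lung mask keeps both lungs but drops spurious islands", {
  d <- c(16, 16, 16)
  act <- array(0, dim = c(d, 7))
  act[2:6, 2:9, 2:9, 6] <- 1     # left lung blob
  act[9:14, 2:9, 2:9, 6] <- 1    # right lung blob (disjoint, comparable)
  act[15, 15, 15, 6] <- 1        # spurious island
  act[, , , 1] <- 0.9 * (act[, , , 6] > 0)
  fr <- fuseDecoders(mkPred(act))
  expect_true(all(fr@lungMask[2:6, 2:9, 2:9]))
  expect_true(all(fr@lungMask[9:14, 2:9, 2:9]))
  expect_false(fr@lungMask[15, 15, 15])
  expect_identical(labelArray(fr@labels)[15, 15, 15], 0L)
})

test_that("largestComponent keeps exactly the biggest blob", {
  d <- c(16, 16, 16)
  m <- array(FALSE, dim = d)
  m[2:6, 2:6, 2:6] <- TRUE      # 125 voxels
  m[12:13, 12:13, 12] <- TRUE   # 4 voxels
  out <- largestComponent(m)
  expect_true(all(out[2:6, 2:6, 2:6]))
  expect_false(any(out[12:13, 12:13, 12]))
  expect_identical(largestComponent(out), out)          # idempotent
  expect_false(any(largestComponent(array(FALSE, d))))  # empty in, empty out
})

test_that("largestComponent agrees with an independent graph oracle", {
  set.seed(3)
  for (trial in 1:10) {
    d <- c(20, 20, 20)
    m <- array(runif(prod(d)) < 0.2, dim = d)
    expect_identical(largestComponent(m, 26), bfLargestComponent(m, 26))
    expect_identical(largestComponent(m, 6), bfLargestComponent(m, 6))
  }
})

test_that("finalize fills carved gaps and restores the native grid", {
  ph <- smallPhantom()
  atlas <- smallAtlas()
  lab <- labelArray(ph$labels)
  d <- dim(lab)
  act <- array(0, dim = c(d, 7))
  for (k in 1:5) act[, , , k] <- (lab == k) * 0.95
  act[, , , 6] <- (lab %in% 1:5) * 0.95
  act[, , , 7] <- (lab == 6L) * 0.95
  # zero out a cube of confidence inside the RLL (synthetic consolidation)
  cen <- round(colMeans(which(lab == 3L, arr.ind = TRUE)))
  sl <- lapply(1:3, function(a) (cen[a] - 4):(cen[a] + 4))
  act[sl[[1]], sl[[2]], sl[[3]], 1:5] <- 0
  pred <- new("StagePrediction", activations = act, stage = 2L,
              gridMeta = list(dim = d, spacing = c(1, 1, 1),
                              affine = diag(4)))
  fr <- fuseDecoders(pred)
  expect_gt(sum(fr@gapMask), 0)
  seg <- finalizeSegmentation(fr, atlas, NULL, ph$ct)
  expect_identical(dim(seg), d)
  out <- labelArray(seg)
  lung <- out %in% 1:5 | lab %in% 1:5
  # no unlabeled voxels remain inside the recovered lung
  expect_identical(sum(fr@lungMask & out == 0L), 0L)
  # the carved region is dominated by the true lobe
  carved <- array(FALSE, dim = d); carved[sl[[1]], sl[[2]], sl[[3]]] <- TRUE
  carved <- carved & lab == 3L
  expect_gte(mean(out[carved] == 3L), 0.95)

  # without prior fill the carved region stays background
  seg0 <- finalizeSegmentation(fr, atlas, NULL, ph$ct, priorFill = FALSE)
  expect_gt(sum(labelArray(seg0)[carved] == 0L), 0)

  # each lobe ends as a single connected component
  for (k in 1:5) {
    mk <- out == k
    comp <- LobeSeg:::cpp_label_components(array(mk, dim = d), d, 26L)
    expect_identical(max(comp), 1L)
  }
})
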