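tinyCfg <- function(stage, attention = TRUE)
  netConfig(baseChannels = 2L, depth = 2L,
            inChannels = if (stage == 1) 1L else 13L, stage = stage,
            attention = attention)

test_that("network configuration enforces the 13-channel stage-2 contract", {
  expect_error(netConfig(inChannels = 5L, stage = 2L), "13")
  expect_error(netConfig(inChannels = 2L, stage = 1L), "1 \\(CT\\)")
  cfg <- netConfig(4, 2, 13, 2)
  expect_identical(cfg$outStructures, 7L)
})

test_that("forward passes honor the shape and activation-range contracts", {
  d <- c(16L, 16L, 16L)
  n <- prod(d)
  set.seed(1)
  for (stage in 1:2) for (att in c(TRUE, FALSE)) {
    model <- buildAttUNet(tinyCfg(stage, att), seed = 2)
    mat <- matrix(runif(n * model$cfg$inChannels), n)
    act <- LobeSeg:::.activations7(model, mat, d)
    expect_identical(dim(act), c(d, 7L))
    expect_gte(min(act), 0); expect_lte(max(act), 1)
  }
  model <- buildAttUNet(tinyCfg(1), seed = 2)
  expect_error(LobeSeg:::.forwardNet(model, matrix(0, 7^3, 1), c(7L, 7L, 7L)),
               "incompatible")
})

test_that("a zero-initialized head yields uniform activations", {
  model <- buildAttUNet(tinyCfg(1), seed = 3)
  model$params$head_soft_W[] <- 0; model$params$head_soft_b[] <- 0
  model$params$head_aux_W[] <- 0; model$params$head_aux_b[] <- 0
  d <- c(8L, 8L, 8L)
  act <- LobeSeg:::.activations7(model, matrix(0.3, prod(d), 1), d)
  expect_true(all(abs(act[, , , 1:5] - 1 / 6) < 1e-12))
  expect_true(all(abs(act[, , , 6:7] - 0.5) < 1e-12))
})

test_that("analytic gradients match finite differences in both stages", {
  set.seed(42)
  for (stage in 1:2) {
    model <- buildAttUNet(tinyCfg(stage), seed = 3)
    d <- c(8L, 8L, 8L); n <- prod(d)
    mat <- matrix(runif(n * model$cfg$inChannels), n)
    lab <- sample(0:6, n, replace = TRUE)
    fwd <- LobeSeg:::.forwardNet(model, mat, d)
    lg <- LobeSeg:::.lossGrad(model, fwd, lab)
    grads <- LobeSeg:::.backwardNet(model, fwd, lg$dHead)
    for (nm in sample(names(model$params), 10)) {
      w <- model$params[[nm]]
      idx <- sample(length(w), 1)
      eps <- 1e-6
      m2 <- model
      m2$params[[nm]][idx] <- w[idx] + eps
      l1 <- LobeSeg:::.lossGrad(m2, LobeSeg:::.forwardNet(m2, mat, d), lab,
                                wantGrad = FALSE)$loss
      m2$params[[nm]][idx] <- w[idx] - eps
      l2 <- LobeSeg:::.lossGrad(m2, LobeSeg:::.forwardNet(m2, mat, d), lab,
                                wantGrad = FALSE)$loss
      fd <- (l1 - l2) / (2 * eps)
      an <- grads[[nm]][idx]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd), abs(an)), 1e-3)
    }
  }
})

test_that("the soft Dice loss hits its endpoints", {
  n <- 100
  t <- as.double(seq_len(n) <= 40)
  expect_equal(1 - LobeSeg:::.softDice(t, t), 0, tolerance = 1e-4)
  expect_equal(1 - LobeSeg:::.softDice(1 - t, t), 1, tolerance = 1e-4)
})

test_that("training follows the exponential learning-rate schedule and
           selects the best-validation checkpoint", {
  co <- makeCohort(3, phantomSpec(shape = c(32, 32, 32), seed = 31),
                   variability = 1)
  samples <- lapply(co, function(m) list(ct = m$ct, labels = m$labels))
  model <- buildAttUNet(tinyCfg(1), seed = 1)
  hp <- list(epochs = 4L, lr = 1e-2, lrDecay = 0.985, valIdx = 3L, seed = 5)
  res <- trainStage(model, samples, hp)
  expect_equal(res$history$lr, 1e-2 * 0.985^(0:3))
  expect_identical(nrow(res$history), 4L)
  # loss trends down on this easy overfit and the best epoch is retained
  expect_lte(res$history$trainLoss[4], res$history$trainLoss[1])
  bestVal <- min(res$history$valLoss)
  s <- LobeSeg:::.sampleInput(model$cfg, samples[[3]])
  reLoss <- LobeSeg:::.lossGrad(res$model,
                                LobeSeg:::.forwardNet(res$model, s$mat, s$d),
                                s$lab, wantGrad = FALSE)$loss
  expect_equal(reLoss, bestVal, tolerance = 1e-12)

  expect_error(trainStage(model, samples[1], hp), "at least one")
})

test_that("training reruns with the same seed are bit-identical", {
  co <- makeCohort(3, phantomSpec(shape = c(32, 32, 32), seed = 31),
                   variability = 1)
  samples <- lapply(co, function(m) list(ct = m$ct, labels = m$labels))
  hp <- list(epochs = 2L, lr = 1e-2, valIdx = 3L, seed = 5, crop = 16L,
             drawsPerEpoch = 2L)
  r1 <- trainStage(buildAttUNet(tinyCfg(1), seed = 1), samples, hp)
  r2 <- trainStage(buildAttUNet(tinyCfg(1), seed = 1), samples, hp)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
})

test_that("stage-1 prediction always lands on the requested grid", {
  model <- buildAttUNet(tinyCfg(1), seed = 1)
  ph <- makePhantom(phantomSpec(shape = c(40, 48, 56), seed = 33))
  pred <- stage1Predict(model, ph$ct, targetSize = 32L)
  expect_identical(dim(activations(pred)), c(32L, 32L, 32L, 7L))
  expect_identical(pred@gridMeta$sourceDim, c(40L, 48L, 56L))
})

test_that("stage-2 stitching equals brute-force patch averaging", {
  set.seed(9)
  model <- buildAttUNet(tinyCfg(2), seed = 4)
  d <- c(24L, 24L, 24L)
  ct <- ctVolume(array(runif(prod(d)), dim = d), normalized = TRUE)
  prior <- array(runif(prod(d) * 5), dim = c(d, 5))
  coarse <- new("StagePrediction",
                activations = array(runif(prod(d) * 7), dim = c(d, 7)),
                stage = 1L, gridMeta = list(size = d))

  # overlap 0 with an exactly tiling patch: stitching is the identity
  p0 <- stage2Refine(model, ct, prior, coarse, patch = 12L, overlap = 0)
  full <- array(cbind(matrix(intensities(ct), ncol = 1),
                      matrix(prior, ncol = 5),
                      matrix(LobeSeg:::.resampleChannels(activations(coarse),
                                                         d), ncol = 7)),
                dim = c(d, 13))
  manual0 <- array(0, dim = c(d, 7))
  for (sx in c(1, 13)) for (sy in c(1, 13)) for (sz in c(1, 13)) {
    ix <- sx:(sx + 11); iy <- sy:(sy + 11); iz <- sz:(sz + 11)
    sub <- full[ix, iy, iz, , drop = FALSE]
    manual0[ix, iy, iz, ] <- LobeSeg:::.activations7(
      model, matrix(sub, ncol = 13), c(12L, 12L, 12L))
  }
  expect_equal(activations(p0), manual0, tolerance = 1e-12)

  # overlap 0.5: every stitched voxel is the mean of its contributors
  p5 <- stage2Refine(model, ct, prior, coarse, patch = 12L, overlap = 0.5)
  acc <- array(0, dim = c(d, 7)); cnt <- array(0, dim = d)
  starts <- unique(c(seq(1, 13, 6), 13))
  for (sx in starts) for (sy in starts) for (sz in starts) {
    ix <- sx:(sx + 11); iy <- sy:(sy + 11); iz <- sz:(sz + 11)
    sub <- full[ix, iy, iz, , drop = FALSE]
    acc[ix, iy, iz, ] <- acc[ix, iy, iz, ] +
      LobeSeg:::.activations7(model, matrix(sub, ncol = 13),
                              c(12L, 12L, 12L))
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  expect_gte(min(cnt[7:18, 7:18, 7:18]), 2)  # central voxels covered >= 2x
  expect_equal(activations(p5), acc / array(cnt, dim = c(d, 7)),
               tolerance = 1e-12)

  # determinism
  expect_identical(activations(stage2Refine(model, ct, prior, coarse,
                                            patch = 12L, overlap = 0.5)),
                   activations(p5))

  # an oversized patch shrinks with a warning
  expect_warning(stage2Refine(model, ct, prior, coarse, patch = 48L),
                 "shrinking")
})

test_that("stage 2 runs with the prior channels zeroed (soft guidance)", {
  model <- buildAttUNet(tinyCfg(2), seed = 4)
  d <- c(16L, 16L, 16L)
  ct <- ctVolume(array(runif(prod(d)), dim = d), normalized = TRUE)
  coarse <- new("StagePrediction",
                activations = array(runif(prod(d) * 7), dim = c(d, 7)),
                stage = 1L, gridMeta = list(size = d))
  out <- stage2Refine(model, ct, array(0, dim = c(d, 5)), coarse,
                      patch = 16L, overlap = 0)
  act <- activations(out)
  expect_true(all(is.finite(act)))
  expect_gte(min(act), 0); expect_lte(max(act), 1)
})
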