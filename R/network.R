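#' Network configuration
#'
#' Architecture hyperparameters of the 3D attention U-Net used by both
#' stages. Stage 1 takes the CT alone (1 channel) through one decoder with a
#' 6-class softmax head (background + five lobes) plus sigmoid auxiliary
#' whole-lung and airway channels; stage 2 takes 13 channels
#' (CT + 5 atlas probability channels + 7 stage-1 activation channels)
#' through a shared encoder and seven independent decoders, each ending in a
#' per-structure sigmoid.
#'
#' @param baseChannels Channels at the finest encoder level.
#' @param depth Number of encoder levels (input dims must be divisible by
#'   `2^depth`).
#' @param inChannels 1 (stage 1) or 13 (stage 2).
#' @param stage 1 or 2.
#' @param attention Enable the spatial attention gates (learned sigmoid
#'   heatmaps multiplied onto the skip features); disabling yields a plain
#'   U-Net.
#' @return A named list, validated.
#' @export
netConfig <- function(baseChannels = 16L, depth = 3L, inChannels = 1L,
                      stage = 1L, attention = TRUE) {
  stage <- as.integer(stage)
  inChannels <- as.integer(inChannels)
  if (!stage %in% c(1L, 2L)) stop("stage must be 1 or 2")
  expectedIn <- if (stage == 1L) 1L else 13L
  if (inChannels != expectedIn)
    stop("stage ", stage, " expects ", expectedIn, " input channel(s): ",
         "1 (CT) for stage 1; 1 CT + 5 prior + 7 coarse = 13 for stage 2")
  list(baseChannels = as.integer(baseChannels), depth = as.integer(depth),
       inChannels = inChannels, stage = stage,
       attention = isTRUE(attention), outStructures = 7L)
}


.heW <- function(nr, nc, fanIn) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fanIn)), nr, nc)
}

.levelChannels <- function(cfg, l) cfg$baseChannels * 2L^l

#' Build an attention U-Net model
#'
#' Allocates and He-initializes all parameters for the configured stage.
#' The returned handle is a plain list (`cfg`, `params`, `opt`) that
#' [trainStage()] updates in a functional style.
#'
#' @param cfg A [netConfig()] list.
#' @param seed Seed for weight initialization.
#' @return Model handle.
#' @export
buildAttUNet <- function(cfg, seed = 1L) {
  .withLocalSeed(seed, {
    p <- list()
    addConvBlock <- function(prefix, cin, cout) {
      p[[paste0(prefix, "_c1_W")]] <<- .heW(27 * cin, cout, 27 * cin)
      p[[paste0(prefix, "_c1_b")]] <<- numeric(cout)
      p[[paste0(prefix, "_n1_g")]] <<- rep(1, cout)
      p[[paste0(prefix, "_n1_b")]] <<- numeric(cout)
      p[[paste0(prefix, "_c2_W")]] <<- .heW(27 * cout, cout, 27 * cout)
      p[[paste0(prefix, "_c2_b")]] <<- numeric(cout)
      p[[paste0(prefix, "_n2_g")]] <<- rep(1, cout)
      p[[paste0(prefix, "_n2_b")]] <<- numeric(cout)
    }
    cin <- cfg$inChannels
    for (l in seq_len(cfg$depth) - 1L) {
      addConvBlock(paste0("enc", l), cin, .levelChannels(cfg, l))
      cin <- .levelChannels(cfg, l)
    }
    addConvBlock("bott", cin, .levelChannels(cfg, cfg$depth))
    decoders <- if (cfg$stage == 1L) 1L else 7L
    for (k in seq_len(decoders)) {
      for (l in rev(seq_len(cfg$depth) - 1L)) {
        cAbove <- .levelChannels(cfg, l + 1L)
        cSkip <- .levelChannels(cfg, l)
        pre <- sprintf("d%dl%d", k, l)
        if (cfg$attention) {
          p[[paste0(pre, "_ag1_W")]] <- .heW(cAbove + cSkip, cSkip,
                                             cAbove + cSkip)
          p[[paste0(pre, "_ag1_b")]] <- numeric(cSkip)
          p[[paste0(pre, "_ag2_W")]] <- .heW(cSkip, 1L, cSkip)
          p[[paste0(pre, "_ag2_b")]] <- numeric(1L)
        }
        addConvBlock(pre, cAbove + cSkip, cSkip)
      }
    }
    b <- cfg$baseChannels
    if (cfg$stage == 1L) {
      p[["head_soft_W"]] <- .heW(b, 6L, b)
      p[["head_soft_b"]] <- numeric(6L)
      p[["head_aux_W"]] <- .heW(b, 2L, b)
      p[["head_aux_b"]] <- numeric(2L)
    } else {
      for (k in 1:7) {
        p[[sprintf("head%d_W", k)]] <- .heW(b, 1L, b)
        p[[sprintf("head%d_b", k)]] <- numeric(1L)
      }
    }
    list(cfg = cfg, params = p, opt = NULL)
  })
}

# ---- layer primitives --------------------------------------------------
# Feature maps travel through the network as zero-halo-padded
# ((nx+2)(ny+2)(nz+2) x C) matrices; `d` is always the interior dims.
# Convolutions then reduce to 27 shifted BLAS GEMM accumulations (see
# src/conv.cpp). Inputs are padded on entry and activations unpadded at the
# heads; elementwise ops are safe on halo rows because conv/pool/upsample
# kernels re-zero halos.

.convF <- function(x, d, W, b) cpp_conv3_fwd(x, d, W, b)

.convB <- function(dy, x, d, W) {
  r <- cpp_conv3_bwd(x, d, W, dy)
  list(dx = r$dx, dW = r$dW, db = colSums(dy))
}

.sigm <- function(x) 1 / (1 + exp(-x))

# Instance normalization over the interior voxels of one feature map
# (halo rows are zero and must stay zero, so stats use raw sums and outputs
# are re-zeroed on the halo).
.IN_EPS <- 1e-5

.inormF <- function(x, d, gamma, beta) {
  nInt <- prod(d)
  mu <- colSums(x) / nInt
  v <- pmax(0, colSums(x^2) / nInt - mu^2)
  s <- sqrt(v + .IN_EPS)
  xhat <- sweep(sweep(x, 2, mu), 2, s, `/`)
  cpp_zero_halo(xhat, d)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  cpp_zero_halo(y, d)
  list(out = y, xhat = xhat, s = s)
}

.inormB <- function(dy, cache, gamma, d) {
  nInt <- prod(d)
  dxhat <- sweep(dy, 2, gamma, `*`)
  m1 <- colSums(dxhat) / nInt
  m2 <- colSums(dxhat * cache$xhat) / nInt
  dx <- sweep(dxhat, 2, m1) - sweep(cache$xhat, 2, m2, `*`)
  dx <- sweep(dx, 2, cache$s, `/`)
  cpp_zero_halo(dx, d)
  list(dx = dx, dgamma = colSums(dy * cache$xhat), dbeta = colSums(dy))
}

.convBlockF <- function(p, prefix, x, d) {
  z1 <- .convF(x, d, p[[paste0(prefix, "_c1_W")]], p[[paste0(prefix, "_c1_b")]])
  n1 <- .inormF(z1, d, p[[paste0(prefix, "_n1_g")]], p[[paste0(prefix, "_n1_b")]])
  a1 <- n1$out * (n1$out > 0)
  z2 <- .convF(a1, d, p[[paste0(prefix, "_c2_W")]], p[[paste0(prefix, "_c2_b")]])
  n2 <- .inormF(z2, d, p[[paste0(prefix, "_n2_g")]], p[[paste0(prefix, "_n2_b")]])
  a2 <- n2$out * (n2$out > 0)
  list(out = a2,
       cache = list(x = x, n1 = n1, a1 = a1, n2 = n2, d = d))
}

.convBlockB <- function(p, g, prefix, da2, cache) {
  d <- cache$d
  dn2 <- da2 * (cache$n2$out > 0)
  ib2 <- .inormB(dn2, cache$n2, p[[paste0(prefix, "_n2_g")]], d)
  g[[paste0(prefix, "_n2_g")]] <- g[[paste0(prefix, "_n2_g")]] + ib2$dgamma
  g[[paste0(prefix, "_n2_b")]] <- g[[paste0(prefix, "_n2_b")]] + ib2$dbeta
  b2 <- .convB(ib2$dx, cache$a1, d, p[[paste0(prefix, "_c2_W")]])
  g[[paste0(prefix, "_c2_W")]] <- g[[paste0(prefix, "_c2_W")]] + b2$dW
  g[[paste0(prefix, "_c2_b")]] <- g[[paste0(prefix, "_c2_b")]] + b2$db
  dn1 <- b2$dx * (cache$n1$out > 0)
  ib1 <- .inormB(dn1, cache$n1, p[[paste0(prefix, "_n1_g")]], d)
  g[[paste0(prefix, "_n1_g")]] <- g[[paste0(prefix, "_n1_g")]] + ib1$dgamma
  g[[paste0(prefix, "_n1_b")]] <- g[[paste0(prefix, "_n1_b")]] + ib1$dbeta
  b1 <- .convB(ib1$dx, cache$x, d, p[[paste0(prefix, "_c1_W")]])
  g[[paste0(prefix, "_c1_W")]] <- g[[paste0(prefix, "_c1_W")]] + b1$dW
  g[[paste0(prefix, "_c1_b")]] <- g[[paste0(prefix, "_c1_b")]] + b1$db
  list(g = g, dx = b1$dx)
}

.checkDims <- function(d, depth) {
  if (any(d %% 2L^depth != 0L) || any(d %/% 2L^depth < 2L))
    stop("input dims ", paste(d, collapse = "x"),
         " incompatible with encoder depth ", depth,
         " (each axis must be a multiple of 2^depth and not collapse)")
}

.forwardNet <- function(model, x, d) {
  p <- model$params
  cfg <- model$cfg
  .checkDims(d, cfg$depth)
  cache <- list(dIn = d)
  skips <- list()
  dims <- list()
  cur <- cpp_pad_mat(x, d); curd <- d
  for (l in seq_len(cfg$depth) - 1L) {
    cb <- .convBlockF(p, paste0("enc", l), cur, curd)
    cache[[paste0("enc", l)]] <- cb$cache
    skips[[l + 1L]] <- cb$out
    dims[[l + 1L]] <- curd
    cur <- cpp_avgpool2(cb$out, curd)
    curd <- curd %/% 2L
  }
  cb <- .convBlockF(p, "bott", cur, curd)
  cache$bott <- cb$cache
  bott <- cb$out; bottd <- curd
  cache$skipDims <- dims
  decoders <- if (cfg$stage == 1L) 1L else 7L
  decOut <- vector("list", decoders)
  for (k in seq_len(decoders)) {
    g <- bott; gd <- bottd
    for (l in rev(seq_len(cfg$depth) - 1L)) {
      pre <- sprintf("d%dl%d", k, l)
      gUp <- cpp_upsample2(g, gd)
      ld <- dims[[l + 1L]]
      skip <- skips[[l + 1L]]
      lev <- list(gd = gd, gUp = gUp, skip = skip, d = ld)
      if (cfg$attention) {
        cat1 <- cbind(gUp, skip)
        h1 <- sweep(cat1 %*% p[[paste0(pre, "_ag1_W")]], 2,
                    p[[paste0(pre, "_ag1_b")]], `+`)
        r1 <- h1 * (h1 > 0)
        h2 <- as.numeric(r1 %*% p[[paste0(pre, "_ag2_W")]]) +
          p[[paste0(pre, "_ag2_b")]]
        a <- .sigm(h2)
        skipA <- skip * a
        lev$cat1 <- cat1; lev$h1 <- h1; lev$r1 <- r1; lev$a <- a
      } else skipA <- skip
      cat2 <- cbind(gUp, skipA)
      cb <- .convBlockF(p, pre, cat2, ld)
      lev$cb <- cb$cache
      cache[[pre]] <- lev
      g <- cb$out; gd <- ld
    }
    decOut[[k]] <- g
  }
  if (cfg$stage == 1L) {
    feat <- decOut[[1L]]   # padded
    logitsSoft <- cpp_unpad_mat(
      sweep(feat %*% p$head_soft_W, 2, p$head_soft_b, `+`), d)
    logitsAux <- cpp_unpad_mat(
      sweep(feat %*% p$head_aux_W, 2, p$head_aux_b, `+`), d)
    cache$feat <- feat
    list(cache = cache, logitsSoft = logitsSoft, logitsAux = logitsAux)
  } else {
    headsPad <- vapply(1:7, function(k)
      as.numeric(decOut[[k]] %*% p[[sprintf("head%d_W", k)]]) +
        p[[sprintf("head%d_b", k)]], numeric(nrow(decOut[[1L]])))
    cache$decOut <- decOut
    list(cache = cache, logits = cpp_unpad_mat(headsPad, d))
  }
}

.zeroGrads <- function(p) lapply(p, function(w) w * 0)

.backwardDecoder <- function(model, g, k, dOut, cache) {
  p <- model$params
  cfg <- model$cfg
  dg <- dOut
  dBott <- NULL
  for (l in seq_len(cfg$depth) - 1L) {  # finest level first (reverse of fwd)
    pre <- sprintf("d%dl%d", k, l)
    lev <- cache[[pre]]
    cb <- .convBlockB(p, g, pre, dg, lev$cb)
    g <- cb$g
    dcat2 <- cb$dx
    cA <- ncol(lev$gUp)
    dgUp <- dcat2[, seq_len(cA), drop = FALSE]
    dskipA <- dcat2[, -seq_len(cA), drop = FALSE]
    if (cfg$attention) {
      dskip <- dskipA * lev$a
      da <- rowSums(dskipA * lev$skip)
      dh2 <- da * lev$a * (1 - lev$a)
      g[[paste0(pre, "_ag2_W")]] <- g[[paste0(pre, "_ag2_W")]] +
        crossprod(lev$r1, dh2)
      g[[paste0(pre, "_ag2_b")]] <- g[[paste0(pre, "_ag2_b")]] + sum(dh2)
      dr1 <- outer(dh2, as.numeric(p[[paste0(pre, "_ag2_W")]]))
      dh1 <- dr1 * (lev$h1 > 0)
      g[[paste0(pre, "_ag1_W")]] <- g[[paste0(pre, "_ag1_W")]] +
        crossprod(lev$cat1, dh1)
      g[[paste0(pre, "_ag1_b")]] <- g[[paste0(pre, "_ag1_b")]] + colSums(dh1)
      dcat1 <- dh1 %*% t(p[[paste0(pre, "_ag1_W")]])
      dgUp <- dgUp + dcat1[, seq_len(cA), drop = FALSE]
      dskip <- dskip + dcat1[, -seq_len(cA), drop = FALSE]
    } else dskip <- dskipA
    # gradient flowing into the skip connection (encoder feature)
    cache$dskipAcc[[l + 1L]] <- cache$dskipAcc[[l + 1L]] + dskip
    dg <- cpp_upsample2_bwd(dgUp, lev$gd)
  }
  list(g = g, dBott = dg, cache = cache)
}

.backwardNet <- function(model, fwd, dHead) {
  p <- model$params
  cfg <- model$cfg
  cache <- fwd$cache
  g <- .zeroGrads(p)
  dims <- cache$skipDims
  d <- cache$dIn
  cache$dskipAcc <- lapply(seq_len(cfg$depth), function(l)
    matrix(0, prod(dims[[l]] + 2L), .levelChannels(cfg, l - 1L)))
  if (cfg$stage == 1L) {
    feat <- cache$feat
    dSoft <- cpp_pad_mat(dHead$soft, d)
    dAux <- cpp_pad_mat(dHead$aux, d)
    g$head_soft_W <- crossprod(feat, dSoft)
    g$head_soft_b <- colSums(dHead$soft)
    g$head_aux_W <- crossprod(feat, dAux)
    g$head_aux_b <- colSums(dHead$aux)
    dFeat <- dSoft %*% t(p$head_soft_W) + dAux %*% t(p$head_aux_W)
    bk <- .backwardDecoder(model, g, 1L, dFeat, cache)
    g <- bk$g; cache <- bk$cache
    dBott <- bk$dBott
  } else {
    dBott <- NULL
    dHeadPad <- cpp_pad_mat(dHead, d)
    for (k in 1:7) {
      dk <- dHeadPad[, k]
      W <- p[[sprintf("head%d_W", k)]]
      g[[sprintf("head%d_W", k)]] <- crossprod(cache$decOut[[k]],
                                               matrix(dk, ncol = 1))
      g[[sprintf("head%d_b", k)]] <- sum(dk)
      dFeat <- outer(dk, as.numeric(W))
      bk <- .backwardDecoder(model, g, k, dFeat, cache)
      g <- bk$g; cache <- bk$cache
      dBott <- if (is.null(dBott)) bk$dBott else dBott + bk$dBott
    }
  }
  cb <- .convBlockB(p, g, "bott", dBott, cache$bott)
  g <- cb$g
  dcur <- cb$dx
  for (l in rev(seq_len(cfg$depth) - 1L)) {
    dUp <- cpp_avgpool2_bwd(dcur, dims[[l + 1L]]) + cache$dskipAcc[[l + 1L]]
    cb <- .convBlockB(p, g, paste0("enc", l), dUp, cache[[paste0("enc", l)]])
    g <- cb$g
    dcur <- cb$dx
  }
  g
}

# ---- soft Dice loss -------------------------------------------------------

.DICE_EPS <- 1e-5

.softDice <- function(p, t) {
  (2 * sum(p * t) + .DICE_EPS) / (sum(p) + sum(t) + .DICE_EPS)
}

.softDiceGrad <- function(p, t) {
  A <- 2 * sum(p * t) + .DICE_EPS
  B <- sum(p) + sum(t) + .DICE_EPS
  list(dice = A / B, dp = 2 * t / B - A / B^2)
}

.stage1Targets <- function(lab) {
  soft <- vapply(0:5, function(c) {
    tc <- as.double(lab == c)
    if (c == 0) tc <- as.double(lab == 0 | lab == .AIRWAY_CODE)
    tc
  }, numeric(length(lab)))
  list(soft = soft, lung = as.double(lab %in% .LOBE_CODES),
       airway = as.double(lab == .AIRWAY_CODE))
}

.stage2Targets <- function(lab) {
  vapply(1:7, function(k) {
    if (k <= 5) as.double(lab == k)
    else if (k == 6) as.double(lab %in% .LOBE_CODES)
    else as.double(lab == .AIRWAY_CODE)
  }, numeric(length(lab)))
}

.rowSoftmax <- function(logits) {
  m <- do.call(pmax, c(as.data.frame(logits), list(0)))
  e <- exp(logits - m)
  e / rowSums(e)
}

# loss + gradient wrt logits for one sample
.lossGrad <- function(model, fwd, lab, wantGrad = TRUE) {
  if (model$cfg$stage == 1L) {
    ps <- .rowSoftmax(fwd$logitsSoft)
    pa <- .sigm(fwd$logitsAux)
    tg <- .stage1Targets(lab)
    nterm <- 8
    dices <- numeric(nterm)
    dps <- matrix(0, nrow(ps), 6)
    dpa <- matrix(0, nrow(pa), 2)
    for (c in 1:6) {
      gr <- .softDiceGrad(ps[, c], tg$soft[, c])
      dices[c] <- gr$dice
      if (wantGrad) dps[, c] <- -gr$dp / nterm
    }
    gl <- .softDiceGrad(pa[, 1], tg$lung)
    ga <- .softDiceGrad(pa[, 2], tg$airway)
    dices[7] <- gl$dice; dices[8] <- ga$dice
    loss <- 1 - mean(dices)
    if (!wantGrad) return(list(loss = loss))
    dpa[, 1] <- -gl$dp / nterm
    dpa[, 2] <- -ga$dp / nterm
    dSoft <- ps * (dps - rowSums(dps * ps))
    dAux <- dpa * pa * (1 - pa)
    list(loss = loss, dHead = list(soft = dSoft, aux = dAux))
  } else {
    act <- .sigm(fwd$logits)
    tg <- .stage2Targets(lab)
    dices <- numeric(7)
    dAct <- matrix(0, nrow(act), 7)
    for (k in 1:7) {
      gr <- .softDiceGrad(act[, k], tg[, k])
      dices[k] <- gr$dice
      if (wantGrad) dAct[, k] <- -gr$dp / 7
    }
    loss <- 1 - mean(dices)
    if (!wantGrad) return(list(loss = loss))
    list(loss = loss, dHead = dAct * act * (1 - act))
  }
}

# ---- AdamW ----------------------------------------------------------------

.adamwInit <- function(p) list(m = .zeroGrads(p), v = .zeroGrads(p), t = 0L)

.adamwStep <- function(p, g, opt, lr, weightDecay, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(p)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- opt$m[[nm]] / bc1
    vh <- opt$v[[nm]] / bc2
    p[[nm]] <- p[[nm]] - lr * (mh / (sqrt(vh) + eps) + weightDecay * p[[nm]])
  }
  list(p = p, opt = opt)
}

# ---- sample assembly ------------------------------------------------------

.asArr <- function(x) {
  if (is(x, "CTVolume")) x@intensities
  else if (is(x, "LabelMap")) x@labels
  else x
}

.sampleInput <- function(cfg, s) {
  ct <- .asArr(s$ct)
  d <- dim(ct)
  lab <- as.integer(.asArr(s$labels))
  if (cfg$stage == 1L) {
    mat <- matrix(as.double(ct), ncol = 1)
  } else {
    if (is.null(s$prior) || is.null(s$coarse))
      stop("stage-2 samples need prior (5ch) and coarse (7ch) arrays")
    mat <- cbind(matrix(as.double(ct), ncol = 1),
                 matrix(s$prior, ncol = 5),
                 matrix(s$coarse, ncol = 7))
  }
  list(mat = mat, d = d, lab = lab)
}

#' Train one network stage
#'
#' Optimizes the soft Dice loss (1 minus the mean per-structure soft Dice)
#' with AdamW and an exponential learning-rate schedule
#' (`lr * lrDecay^epoch`). The checkpoint with the lowest validation loss is
#' retained. Fully seeded and deterministic.
#'
#' @param model A [buildAttUNet()] handle.
#' @param samples List of samples: `list(ct =, labels =)` for stage 1, plus
#'   `prior` (nx,ny,nz,5 array) and `coarse` (nx,ny,nz,7 array) for stage 2.
#' @param hp Hyperparameters: `epochs` (50), `lr` (1e-4), `weightDecay`
#'   (1e-5), `lrDecay` (0.985), `valIdx` (indices of validation samples;
#'   default the trailing 20 percent), `seed` (1), `crop` (optional cubic
#'   random-crop size for training steps; validation always uses the full
#'   grid), `drawsPerEpoch` (training passes over the sample list per epoch,
#'   default 1 — useful together with `crop`).
#' @return `list(model = trained handle with best-validation params,
#'   history = data.frame(epoch, lr, trainLoss, valLoss))`.
#' @export
trainStage <- function(model, samples, hp = list()) {
  hp <- utils::modifyList(list(epochs = 50L, lr = 1e-4, weightDecay = 1e-5,
                               lrDecay = 0.985, valIdx = NULL, seed = 1L,
                               crop = NULL, drawsPerEpoch = 1L), hp)
  n <- length(samples)
  if (n < 2) stop("need at least one training and one validation sample")
  valIdx <- hp$valIdx
  if (is.null(valIdx)) valIdx <- seq.int(max(2L, n - max(1L, round(0.2 * n)) + 1L), n)
  trainIdx <- setdiff(seq_len(n), valIdx)
  if (!length(trainIdx)) stop("no training samples left after split")
  prepped <- lapply(samples, function(s) .sampleInput(model$cfg, s))
  if (is.null(model$opt)) model$opt <- .adamwInit(model$params)
  history <- data.frame(epoch = integer(), lr = numeric(),
                        trainLoss = numeric(), valLoss = numeric())
  best <- list(loss = Inf, params = model$params)
  cropOf <- function(s) {
    crop <- as.integer(rep_len(hp$crop, 3L))
    if (all(crop >= s$d)) return(s)
    start <- vapply(1:3, function(a)
      if (s$d[a] <= crop[a]) 1L else sample.int(s$d[a] - crop[a] + 1L, 1L),
      integer(1))
    crop <- pmin(crop, s$d)
    ix <- start[1]:(start[1] + crop[1] - 1L)
    iy <- start[2]:(start[2] + crop[2] - 1L)
    iz <- start[3]:(start[3] + crop[3] - 1L)
    idx <- as.vector(outer(outer(ix, (iy - 1L) * s$d[1], `+`),
                           (iz - 1L) * s$d[1] * s$d[2], `+`))
    list(mat = s$mat[idx, , drop = FALSE], d = crop, lab = s$lab[idx])
  }
  .withLocalSeed(hp$seed, {
    for (epoch in seq_len(hp$epochs)) {
      lrE <- hp$lr * hp$lrDecay^(epoch - 1)
      ord <- unlist(lapply(seq_len(hp$drawsPerEpoch),
                           function(r) sample(trainIdx)))
      trLoss <- 0
      for (i in ord) {
        s <- prepped[[i]]
        if (!is.null(hp$crop)) s <- cropOf(s)
        fwd <- .forwardNet(model, s$mat, s$d)
        lg <- .lossGrad(model, fwd, s$lab)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (sample ", i, "); aborting")
        trLoss <- trLoss + lg$loss
        grads <- .backwardNet(model, fwd, lg$dHead)
        st <- .adamwStep(model$params, grads, model$opt, lrE, hp$weightDecay)
        model$params <- st$p
        model$opt <- st$opt
      }
      trLoss <- trLoss / length(ord)
      valLoss <- mean(vapply(valIdx, function(i) {
        s <- prepped[[i]]
        .lossGrad(model, .forwardNet(model, s$mat, s$d), s$lab,
                  wantGrad = FALSE)$loss
      }, numeric(1)))
      history <- rbind(history, data.frame(epoch = epoch, lr = lrE,
                                           trainLoss = trLoss,
                                           valLoss = valLoss))
      if (valLoss < best$loss) best <- list(loss = valLoss,
                                            params = model$params)
    }
  })
  model$params <- best$params
  list(model = model, history = history)
}

# 7-channel activations from a forward pass
.activations7 <- function(model, mat, d) {
  fwd <- .forwardNet(model, mat, d)
  act <- if (model$cfg$stage == 1L) {
    ps <- .rowSoftmax(fwd$logitsSoft)
    cbind(ps[, 2:6], .sigm(fwd$logitsAux))
  } else .sigm(fwd$logits)
  if (!all(is.finite(act))) stop("non-finite network activations")
  array(act, dim = c(d, 7L))
}

#' Stage-1 coarse prediction
#'
#' Resamples the CT to the low-resolution working size, runs the stage-1
#' network, and returns the 7-channel activations with the bookkeeping needed
#' to map back to the input grid.
#'
#' @param model Trained stage-1 [buildAttUNet()] handle.
#' @param ct Preprocessed (isotropic, normalized) [CTVolume-class].
#' @param targetSize Cubic processing size (default 128; tests use smaller).
#' @return A [StagePrediction-class] (stage 1) on the low-resolution grid.
#' @export
stage1Predict <- function(model, ct, targetSize = 128L) {
  d <- dim(ct)
  ts <- as.integer(rep_len(targetSize, 3L))
  sc <- d / ts
  M <- diag(4); diag(M)[1:3] <- sc; M[1:3, 4] <- (sc - 1) / 2
  small <- cpp_resample_affine(as.double(ct@intensities), d, ts, M, FALSE, 0)
  act <- .activations7(model, matrix(small, ncol = 1), ts)
  new("StagePrediction", activations = act, stage = 1L,
      gridMeta = list(sourceDim = d, sourceSpacing = ct@spacing,
                      sourceAffine = ct@affine, size = ts))
}

# trilinear upsampling of a multi-channel activation stack to a target grid
.resampleChannels <- function(arr4, targetDim) {
  d <- dim(arr4)[1:3]
  nc <- dim(arr4)[4]
  sc <- d / targetDim
  M <- diag(4); diag(M)[1:3] <- sc; M[1:3, 4] <- (sc - 1) / 2
  out <- array(0, dim = c(targetDim, nc))
  for (c in seq_len(nc))
    out[, , , c] <- cpp_resample_affine(as.double(arr4[, , , c]), d,
                                        targetDim, M, FALSE, 0)
  out
}

#' Stage-2 high-resolution refinement
#'
#' Assembles the 13-channel input (CT, 5 atlas probability channels, 7
#' stage-1 activation channels upsampled trilinearly), runs the shared
#' encoder / seven-decoder network patch-wise with a sliding window, and
#' averages overlapping predictions.
#'
#' @param model Trained stage-2 handle.
#' @param ct Working-grid normalized [CTVolume-class].
#' @param prior `(nx,ny,nz,5)` atlas probability array on the working grid.
#' @param coarse Stage-1 [StagePrediction-class] (any grid; upsampled here).
#' @param patch Patch edge length (default 128).
#' @param overlap Fractional patch overlap in \[0,1) (default 0.5).
#' @return A [StagePrediction-class] (stage 2) on the working grid.
#' @export
stage2Refine <- function(model, ct, prior, coarse, patch = 128L,
                         overlap = 0.5) {
  d <- dim(ct)
  if (!identical(dim(prior)[1:3], d))
    stop("prior must live on the working grid")
  patch <- as.integer(rep_len(patch, 3L))
  if (any(patch > d)) {
    warning("patch larger than volume; shrinking to the volume size")
    patch <- pmin(patch, d)
  }
  m <- 2L^model$cfg$depth
  if (any(patch %% m != 0L))
    patch <- pmax(m * 2L, (patch %/% m) * m)
  coarseUp <- .resampleChannels(activations(coarse), d)
  chans <- cbind(matrix(as.double(ct@intensities), ncol = 1),
                 matrix(prior, ncol = 5), matrix(coarseUp, ncol = 7))
  full <- array(chans, dim = c(d, 13L))
  starts <- lapply(1:3, function(a) {
    if (patch[a] >= d[a]) return(1L)
    stride <- max(1L, as.integer(round(patch[a] * (1 - overlap))))
    unique(c(seq.int(1L, d[a] - patch[a] + 1L, by = stride),
             d[a] - patch[a] + 1L))
  })
  accum <- array(0, dim = c(d, 7L))
  count <- array(0, dim = d)
  for (sx in starts[[1]]) for (sy in starts[[2]]) for (sz in starts[[3]]) {
    ix <- sx:(sx + patch[1] - 1L)
    iy <- sy:(sy + patch[2] - 1L)
    iz <- sz:(sz + patch[3] - 1L)
    sub <- full[ix, iy, iz, , drop = FALSE]
    act <- .activations7(model, matrix(sub, ncol = 13L), patch)
    accum[ix, iy, iz, ] <- accum[ix, iy, iz, ] + act
    count[ix, iy, iz] <- count[ix, iy, iz] + 1
  }
  act <- accum / array(count, dim = c(d, 7L))
  new("StagePrediction", activations = act, stage = 2L,
      gridMeta = list(dim = d, spacing = ct@spacing, affine = ct@affine,
                      patch = patch, overlap = overlap))
}
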