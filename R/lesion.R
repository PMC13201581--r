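#' Build a lesion bank from phantoms
#'
#' Training-time lesion insertion draws from a bank of
#' `(intensities, mask, groupId)` entries, each pre-registered to an atlas
#' space. This helper populates the bank from phantoms generated with
#' `lesionCount > 0` (the field analogue draws lesions from a fixed set of
#' representative severe CT cases).
#'
#' @param phantoms List of `makePhantom()` results with nonempty lesion masks.
#' @param groupIds Atlas-space identifier per entry (recycled).
#' @return A list of bank entries `list(intensities, mask, groupId)`.
#' @export
makeLesionBank <- function(phantoms, groupIds = "g01") {
  groupIds <- rep_len(groupIds, length(phantoms))
  entries <- lapply(seq_along(phantoms), function(i) {
    ph <- phantoms[[i]]
    if (!any(ph$lesionMask)) stop("phantom ", i, " has no lesion voxels")
    list(intensities = intensities(ph$ct),
         mask = array(as.logical(ph$lesionMask), dim = dim(ph$ct)),
         groupId = groupIds[i])
  })
  entries
}

#' Insert a bank lesion into a target volume
#'
#' The lesion intensities are rescaled to match the mean and SD of the
#' surrounding lung tissue (`x' = (x - mu_les)/sd_les * sd_lung + mu_lung`,
#' lung statistics computed over `targetLung` minus the lesion footprint,
#' airway excluded by construction of the mask), then blended with a soft
#' weight map obtained by Gaussian-blurring the binary lesion mask with SD
#' `blendSigma` voxels, clipped to \[0,1\] and zeroed outside the lung so the
#' lesion never paints outside the pulmonary area. Voxels outside the blurred
#' mask support are bit-identical to the target.
#'
#' @param target Normalized [CTVolume-class] sharing the entry's grid.
#' @param targetLung Logical array: lung voxels of the target (lobes only).
#' @param entry A bank entry from [makeLesionBank()].
#' @param blendSigma Edge blending SD in voxels (default 2).
#' @return A normalized [CTVolume-class] with the lesion blended in.
#' @export
insertLesion <- function(target, targetLung, entry, blendSigma = 2) {
  d <- dim(target)
  if (!identical(dim(entry$mask), d) || !identical(dim(targetLung), d))
    stop("target, lung mask and bank entry must share the same grid")
  if (!any(targetLung)) stop("empty lung mask")
  mask <- entry$mask
  inside <- mask & targetLung
  if (!any(inside)) {
    warning("lesion lies entirely outside the lung; target returned unchanged")
    return(target)
  }
  lungIdx <- targetLung & !mask
  muLung <- mean(target@intensities[lungIdx])
  sdLung <- stats::sd(target@intensities[lungIdx])
  les <- entry$intensities[mask]
  muLes <- mean(les)
  sdLes <- stats::sd(les)
  scaled <- if (sdLes > 0) (les - muLes) / sdLes * sdLung + muLung
            else rep(muLung, length(les))
  # the [0,1] clip would otherwise bias the delivered moments, so iterate the
  # affine match until the clipped values carry the lung mean/SD
  if (sdLes > 0) {
    for (it in 1:25) {
      cl <- pmin(1, pmax(0, scaled))
      m <- mean(cl); s <- stats::sd(cl)
      if (abs(m - muLung) < 1e-9 && abs(s - sdLung) < 1e-9) break
      scaled <- (scaled - m) / max(s, 1e-12) * sdLung + muLung
    }
  }
  lesArr <- array(muLung, dim = d)
  lesArr[mask] <- pmin(1, pmax(0, scaled))
  w <- array(pmin(1, pmax(0, cpp_gauss3(as.double(mask), d, blendSigma))),
             dim = d)
  w[!targetLung] <- 0
  out <- w * lesArr + (1 - w) * target@intensities
  out <- pmin(1, pmax(0, out))
  # outside the blur support the target must be untouched bit-exactly
  out[w == 0] <- target@intensities[w == 0]
  ctVolume(array(out, dim = d), spacing = target@spacing,
           affine = target@affine, normalized = TRUE)
}

#' Default augmentation configuration
#'
#' Parameter ranges for the training-time augmentation chain: optional lesion
#' insertion, scaling, rotation, axis mirroring, Gaussian noise, Gaussian
#' blur, brightness/contrast, and a random crop.
#'
#' @param crop Crop size (voxels, cubic). The full-scale default is 128;
#'   desk-scale runs use the phantom size.
#' @param lesionProb Probability of inserting a bank lesion.
#' @param scaleRange,rotateDeg,mirrorProb,noiseSd,blurSigma,blurProb,brightness,contrast
#'   Transform ranges; see the methods vignette for units and rationale.
#' @return A named list.
#' @export
augmentConfig <- function(crop = 128L, lesionProb = 0.5,
                          scaleRange = c(0.9, 1.1), rotateDeg = 10,
                          mirrorProb = 0.5, noiseSd = 0.02,
                          blurSigma = 0.8, blurProb = 0.2,
                          brightness = 0.1, contrast = c(0.9, 1.1)) {
  list(crop = as.integer(crop), lesionProb = lesionProb,
       scaleRange = scaleRange, rotateDeg = rotateDeg,
       mirrorProb = mirrorProb, noiseSd = noiseSd, blurSigma = blurSigma,
       blurProb = blurProb, brightness = brightness, contrast = contrast)
}

.affineAroundCenter <- function(d, scale, thetaDeg) {
  # output voxel -> input voxel: rotation about z through the grid center,
  # then inverse scaling
  th <- thetaDeg * pi / 180
  R <- diag(3)
  R[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- R / scale
  cen <- (d - 1) / 2
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- cen - A %*% cen
  M
}

#' One stochastic augmentation draw
#'
#' Applies, in order: optional lesion insertion, scaling, rotation about the
#' axial axis, per-axis mirroring, Gaussian noise, Gaussian blur,
#' brightness/contrast, and a random crop. Identical geometric transforms are
#' applied to the labels (nearest-neighbour); intensities are clipped back to
#' \[0,1\]. Fully reproducible given `seed`.
#'
#' @param ct Normalized [CTVolume-class].
#' @param labels Congruent [LabelMap-class].
#' @param cfg An [augmentConfig()] list.
#' @param seed Integer seed for this draw.
#' @param lesionBank Optional [makeLesionBank()] bank (entries on this grid).
#' @return `list(ct =, labels =)` at the crop size.
#' @export
augmentSample <- function(ct, labels, cfg = augmentConfig(), seed = 1L,
                          lesionBank = NULL) {
  .requireSameGrid(ct, labels, "ct and labels")
  d <- dim(ct)
  if (any(cfg$crop > d)) stop("crop larger than the volume")
  .withLocalSeed(seed, {
    img <- ct@intensities
    lab <- labels@labels
    if (!is.null(lesionBank) && length(lesionBank) > 0 &&
        stats::runif(1) < cfg$lesionProb) {
      entry <- lesionBank[[sample.int(length(lesionBank), 1L)]]
      lung <- array(lab %in% .LOBE_CODES, dim = d)
      img <- intensities(insertLesion(
        ctVolume(img, normalized = TRUE), lung, entry))
    }
    scale <- stats::runif(1, cfg$scaleRange[1], cfg$scaleRange[2])
    theta <- stats::runif(1, -cfg$rotateDeg, cfg$rotateDeg)
    if (abs(scale - 1) > 1e-9 || abs(theta) > 1e-9) {
      M <- .affineAroundCenter(d, scale, theta)
      img <- array(cpp_resample_affine(as.double(img), d, d, M, FALSE, 0),
                   dim = d)
      lab <- array(as.integer(
        cpp_resample_affine(as.double(lab), d, d, M, TRUE, 0)), dim = d)
    }
    for (ax in 1:3) if (stats::runif(1) < cfg$mirrorProb) {
      idx <- rev(seq_len(d[ax]))
      if (ax == 1) { img <- img[idx, , , drop = FALSE]; lab <- lab[idx, , , drop = FALSE] }
      if (ax == 2) { img <- img[, idx, , drop = FALSE]; lab <- lab[, idx, , drop = FALSE] }
      if (ax == 3) { img <- img[, , idx, drop = FALSE]; lab <- lab[, , idx, drop = FALSE] }
    }
    if (cfg$noiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, stats::runif(1) * cfg$noiseSd)
    if (stats::runif(1) < cfg$blurProb)
      img <- array(cpp_gauss3(as.double(img), d,
                              stats::runif(1, 0.3, cfg$blurSigma)), dim = d)
    bright <- stats::runif(1, -cfg$brightness, cfg$brightness)
    contr <- stats::runif(1, cfg$contrast[1], cfg$contrast[2])
    if (abs(contr - 1) > 0 || abs(bright) > 0)
      img <- (img - 0.5) * contr + 0.5 + bright
    img <- array(pmin(1, pmax(0, img)), dim = d)
    crop <- rep_len(cfg$crop, 3L)
    start <- vapply(1:3, function(a)
      if (d[a] == crop[a]) 1L
      else sample.int(d[a] - crop[a] + 1L, 1L), integer(1))
    sl <- lapply(1:3, function(a) start[a]:(start[a] + crop[a] - 1L))
    img <- img[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    lab <- lab[sl[[1]], sl[[2]], sl[[3]], drop = FALSE]
    list(ct = ctVolume(img, spacing = ct@spacing, normalized = TRUE),
         labels = labelMap(lab, spacing = labels@spacing,
                           classNames = labels@classNames))
  })
}
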