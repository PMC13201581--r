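.ENGINE_VERSION <- "demons-1"

#' Mutual information between two intensity volumes
#'
#' Joint-histogram estimator on \[0,1\] intensities: `bins` equal-width bins
#' per axis, natural logarithm.
#'
#' @param a,b Numeric arrays/vectors on the same grid, values in \[0,1\].
#' @param bins Histogram bins per axis (default 32).
#' @return Scalar MI in nats (>= 0).
#' @export
mutualInformation <- function(a, b, bins = 32L) {
  ia <- pmin(bins, pmax(1L, as.integer(a * bins) + 1L))
  ib <- pmin(bins, pmax(1L, as.integer(b * bins) + 1L))
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- joint / sum(joint)
  px <- rowSums(matrix(p, bins, bins, byrow = TRUE))
  py <- colSums(matrix(p, bins, bins, byrow = TRUE))
  nz <- p > 0
  sum(p[nz] * log(p[nz])) - sum(px[px > 0] * log(px[px > 0])) -
    sum(py[py > 0] * log(py[py > 0]))
}

.worldCentroid <- function(vol) {
  w <- as.double(vol@intensities)
  tot <- sum(w)
  if (tot <= 0) stop("volume has zero total intensity")
  d <- dim(vol)
  idx <- .normCoordsVox(d)
  cv <- c(sum(idx$x * w), sum(idx$y * w), sum(idx$z * w)) / tot
  (vol@affine %*% c(cv, 1))[1:3]
}

.normCoordsVox <- function(d) {
  list(x = array(0:(d[1] - 1), dim = d),
       y = array(rep(0:(d[2] - 1), each = d[1]), dim = d),
       z = array(rep(0:(d[3] - 1), each = d[1] * d[2]), dim = d))
}

.geomMeta <- function(vol) list(dim = dim(vol), spacing = vol@spacing,
                                affine = vol@affine)

#' Rigid pre-alignment by center-of-mass matching
#'
#' Computes the translation between the intensity-weighted centroids of the
#' two volumes in world coordinates.
#'
#' @param fixed,moving [CTVolume-class] objects with nonzero total intensity.
#' @return A rigid-only [DiffeoTransform-class] whose `preAlign` is
#'   `centroid(moving) - centroid(fixed)` in mm.
#' @export
centerOfMassInit <- function(fixed, moving) {
  t <- .worldCentroid(moving) - .worldCentroid(fixed)
  new("DiffeoTransform", preAlign = as.numeric(t), forward = list(),
      inverse = list(), fixedMeta = .geomMeta(fixed),
      movingMeta = .geomMeta(moving))
}

# world translation -> displacement in moving-grid voxel units
.preAlignVox <- function(t) {
  as.numeric(solve(t@movingMeta$affine[1:3, 1:3]) %*% t@preAlign)
}

.downsampleArr <- function(arr, d, factor) {
  if (factor == 1) return(list(arr = arr, dim = d))
  nd <- as.integer(pmax(4, .rhalf(d / factor)))
  sc <- d / nd
  M <- diag(4); diag(M)[1:3] <- sc
  M[1:3, 4] <- (sc - 1) / 2
  list(arr = array(cpp_resample_affine(as.double(arr), d, nd, M, FALSE, 0),
                   dim = nd), dim = nd)
}

# fixed-point inversion of a displacement field (voxel units)
.invertField <- function(u, d, iters = 20L) {
  v <- lapply(u, function(a) array(0, dim = d))
  for (it in seq_len(iters)) {
    v <- lapply(1:3, function(a)
      array(-cpp_warp_field(as.double(u[[a]]), d, v[[1]], v[[2]], v[[3]],
                            d, FALSE, 0), dim = d))
  }
  names(v) <- c("x", "y", "z")
  v
}

#' Multi-resolution diffeomorphic registration
#'
#' Aligns `moving` to `fixed` with center-of-mass initialization followed by a
#' multi-resolution demons-style solver: at each pyramid level the moving
#' image is warped, an intensity-difference force field is computed,
#' regularized with Gaussian smoothing (fluid on the update, elastic on the
#' accumulated field), and accumulated until the per-level iteration cap or
#' convergence. The inverse field is obtained by fixed-point iteration, so
#' forward and inverse compose to near identity on smooth deformations. The
#' solver is fully deterministic. Both volumes must be normalized to \[0,1\]
#' and live on the same grid.
#'
#' @param fixed,moving Normalized, grid-congruent [CTVolume-class] objects.
#' @param levels Per-pyramid-level iteration caps, coarse to fine. The default
#'   mirrors the full-scale protocol; convergence checks normally stop far
#'   earlier, and desk-scale runs may pass reduced schedules such as
#'   `c(100, 50, 25)`.
#' @param fluidSigma,elasticSigma Gaussian SDs (voxels) smoothing the update
#'   and the accumulated field.
#' @param tol Relative MSE improvement below which a level stops.
#' @return A [DiffeoTransform-class] with dense forward and inverse fields.
#' @export
registerDiffeomorphic <- function(fixed, moving, levels = c(10000, 1000, 100),
                                  fluidSigma = 1.0, elasticSigma = 1.5,
                                  tol = 1e-5) {
  if (!isNormalized(fixed) || !isNormalized(moving))
    stop("both volumes must be normalized to [0,1] (see normalizeHU)")
  .requireSameGrid(fixed, moving, "fixed and moving")
  init <- centerOfMassInit(fixed, moving)
  tvox <- .preAlignVox(init)
  d <- dim(fixed)
  nlev <- length(levels)
  u <- NULL
  F0 <- fixed@intensities
  M0 <- moving@intensities
  miBefore <- mutualInformation(
    F0, cpp_warp_field(as.double(M0), d,
                       array(tvox[1], d), array(tvox[2], d), array(tvox[3], d),
                       d, FALSE, 0))
  worsened <- TRUE
  for (lev in seq_len(nlev)) {
    factor <- 2^(nlev - lev)
    Fl <- .downsampleArr(F0, d, factor)
    Ml <- .downsampleArr(M0, d, factor)
    dl <- Fl$dim
    tl <- tvox * dl / d
    if (is.null(u)) {
      u <- lapply(tl, function(t0) array(t0, dim = dl))
    } else {
      prevd <- dim(u[[1]])
      sc <- dl / prevd
      M <- diag(4); diag(M)[1:3] <- 1 / sc
      u <- lapply(1:3, function(a)
        array(cpp_resample_affine(as.double(u[[a]]), prevd, dl, M, FALSE, 0) *
                sc[a], dim = dl))
      # keep the translation exact outside the previous field's support
    }
    bestU <- u
    prevMse <- Inf
    bestMse <- Inf
    stall <- 0L
    for (it in seq_len(levels[lev])) {
      w <- cpp_warp_field(as.double(Ml$arr), dl, u[[1]], u[[2]], u[[3]],
                          dl, FALSE, 0)
      diffv <- as.double(Fl$arr) - w
      mse <- mean(diffv^2)
      if (mse < bestMse) { bestMse <- mse; bestU <- u }
      if (is.finite(prevMse) && prevMse - mse < tol * max(prevMse, 1e-12)) {
        stall <- stall + 1L
        if (stall >= 3L) break
      } else stall <- 0L
      prevMse <- mse
      g <- cpp_gradient3(w, dl)
      g2 <- g$x^2 + g$y^2 + g$z^2
      denom <- g2 + diffv^2
      scale <- ifelse(denom > 1e-9, diffv / denom, 0)
      upd <- lapply(list(g$x, g$y, g$z), function(ga) {
        s <- ga * scale
        cpp_gauss3(pmin(2, pmax(-2, s)), dl, fluidSigma)
      })
      u <- lapply(1:3, function(a)
        array(cpp_gauss3(u[[a]] + upd[[a]], dl, elasticSigma) +
                tl[a] * 0, dim = dl))
    }
    u <- lapply(bestU, function(a) array(a, dim = dim(bestU[[1]])))
  }
  # bring to full resolution if the finest level was subsampled (it is not,
  # since factor = 1 at the last level)
  names(u) <- c("x", "y", "z")
  miAfter <- mutualInformation(
    F0, cpp_warp_field(as.double(M0), d, u$x, u$y, u$z, d, FALSE, 0))
  if (miAfter < miBefore)
    warning("registration did not improve mutual information; ",
            "returning best-seen transform")
  inv <- .invertField(u, d)
  new("DiffeoTransform", preAlign = init@preAlign, forward = u,
      inverse = inv, fixedMeta = .geomMeta(fixed),
      movingMeta = .geomMeta(moving))
}

#' Apply a transform to a volume or label map
#'
#' `direction = "forward"` resamples a moving-space image onto the fixed grid;
#' `"inverse"` maps a fixed-space image back to the moving grid. Intensities
#' are interpolated trilinearly, labels nearest-neighbour (warping a label map
#' never creates classes absent from the input).
#'
#' @param t A [DiffeoTransform-class].
#' @param vol A [CTVolume-class] or [LabelMap-class] whose geometry matches
#'   the transform's corresponding side.
#' @param direction `"forward"` or `"inverse"`.
#' @return Object of the same class on the target side's grid.
#' @export
applyTransform <- function(t, vol, direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  srcMeta <- if (direction == "forward") t@movingMeta else t@fixedMeta
  dstMeta <- if (direction == "forward") t@fixedMeta else t@movingMeta
  if (!identical(dim(vol), srcMeta$dim))
    stop("volume geometry does not match the transform's ", direction,
         "-direction source grid")
  d <- dstMeta$dim
  rigidOnly <- length(t@forward) == 0
  if (rigidOnly) {
    tvox <- .preAlignVox(t)
    if (direction == "inverse") tvox <- -tvox
    field <- lapply(1:3, function(a) array(tvox[a], dim = d))
  } else {
    field <- if (direction == "forward") t@forward else t@inverse
  }
  isLab <- is(vol, "LabelMap")
  src <- if (isLab) as.double(vol@labels) else as.double(vol@intensities)
  out <- cpp_warp_field(src, dim(vol), field[[1]], field[[2]], field[[3]],
                        d, isLab, 0)
  if (isLab)
    labelMap(array(as.integer(out), dim = d), spacing = dstMeta$spacing,
             affine = dstMeta$affine, classNames = vol@classNames)
  else
    ctVolume(array(if (vol@normalized) pmin(1, pmax(0, out)) else out,
                   dim = d),
             spacing = dstMeta$spacing, affine = dstMeta$affine,
             normalized = vol@normalized)
}

#' Content-hash cache key for a registration
#'
#' MD5 over the fixed and moving contents, the iteration schedule, and the
#' engine version, so a cache entry is reused only for bit-identical inputs.
#'
#' @param fixed,moving [CTVolume-class] objects.
#' @param levels Iteration schedule used.
#' @return Character MD5 hex string.
#' @export
transformCacheKey <- function(fixed, moving, levels = c(10000, 1000, 100)) {
  payload <- list(f = fixed@intensities, fa = fixed@affine,
                  m = moving@intensities, ma = moving@affine,
                  levels = as.numeric(levels), engine = .ENGINE_VERSION)
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(payload, tf, version = 2)
  unname(tools::md5sum(tf))
}

.cachePaths <- function(key, cacheDir) {
  list(fwd = file.path(cacheDir, paste0(key, "_forward.nii.gz")),
       inv = file.path(cacheDir, paste0(key, "_inverse.nii.gz")),
       meta = file.path(cacheDir, paste0(key, ".json")))
}

#' Cache a transform on disk
#'
#' Serialized as a pair of 4D NIfTI displacement fields (voxel units, x/y/z
#' stacked on the 4th axis) plus a JSON metadata sidecar.
#'
#' @param t A [DiffeoTransform-class] with dense fields.
#' @param key Cache key from [transformCacheKey()].
#' @param cacheDir Writable cache directory (created if absent).
#' @return `key`, invisibly.
#' @export
cacheTransform <- function(t, key, cacheDir = ".lobeseg_cache") {
  dir.create(cacheDir, showWarnings = FALSE, recursive = TRUE)
  p <- .cachePaths(key, cacheDir)
  d <- t@fixedMeta$dim
  stack <- function(f) array(c(f$x, f$y, f$z), dim = c(d, 3))
  RNifti::writeNifti(RNifti::asNifti(stack(t@forward), datatype = "double"),
                     p$fwd)
  RNifti::writeNifti(RNifti::asNifti(stack(t@inverse), datatype = "double"),
                     p$inv)
  meta <- list(preAlign = t@preAlign, engine = .ENGINE_VERSION,
               fixedMeta = t@fixedMeta, movingMeta = t@movingMeta)
  writeLines(jsonlite::toJSON(meta, digits = NA, auto_unbox = TRUE), p$meta)
  invisible(key)
}

#' Load a cached transform
#'
#' @inheritParams cacheTransform
#' @return The cached [DiffeoTransform-class], or `NULL` if the key is absent.
#'   A corrupt entry is treated as absent with a warning.
#' @export
loadCachedTransform <- function(key, cacheDir = ".lobeseg_cache") {
  p <- .cachePaths(key, cacheDir)
  if (!all(file.exists(p$fwd, p$inv, p$meta))) return(NULL)
  tryCatch({
    meta <- jsonlite::fromJSON(paste(readLines(p$meta), collapse = ""))
    unstack <- function(path) {
      a <- as.array(RNifti::readNifti(path))
      d <- dim(a)[1:3]
      list(x = array(a[, , , 1], dim = d), y = array(a[, , , 2], dim = d),
           z = array(a[, , , 3], dim = d))
    }
    fm <- function(m) list(dim = as.integer(m$dim),
                           spacing = as.numeric(m$spacing),
                           affine = matrix(unlist(m$affine), 4, 4))
    new("DiffeoTransform", preAlign = as.numeric(meta$preAlign),
        forward = unstack(p$fwd), inverse = unstack(p$inv),
        fixedMeta = fm(meta$fixedMeta), movingMeta = fm(meta$movingMeta))
  }, error = function(e) {
    warning("corrupt cache entry for key ", key, "; treating as absent")
    NULL
  })
}
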