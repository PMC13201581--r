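#' Specify a synthetic lung phantom
#'
#' The phantom emulates the label topology of a chest CT: two ellipsoidal
#' lungs, the right split into three lobes and the left into two by tilted
#' fissure surfaces, a three-generation branching airway, and optional bright
#' lesions. Intensities are authored in Hounsfield units (parenchyma around
#' -900 to -700 HU, background soft tissue around 0 HU, fissures as thin
#' brighter sheets, airway lumen at air density) and then passed through
#' [normalizeHU()] so the fixed preprocessing is exercised realistically.
#'
#' @param shape Voxel counts per axis (each >= 32).
#' @param seed RNG seed; the same spec and seed give a bit-identical phantom.
#' @param lungRadiusFrac Half-width of each lung along x as a fraction of the
#'   grid half-extent.
#' @param fissureTilt Angular jitter of the fissure surfaces, degrees.
#' @param lesionCount Number of spherical lesions to insert.
#' @param lesionRadiusRange Lesion radius range in voxels.
#' @param noiseSd Additive Gaussian noise SD in normalized intensity units.
#' @param deformAmplitude RMS magnitude (voxels) of a smooth random warp.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(shape = c(64, 64, 64), seed = 1L,
                        lungRadiusFrac = 0.34, fissureTilt = 5,
                        lesionCount = 0L, lesionRadiusRange = c(3, 5),
                        noiseSd = 0.01, deformAmplitude = 0) {
  new("PhantomSpec", shape = as.integer(rep_len(shape, 3L)),
      seed = as.integer(seed), lungRadiusFrac = lungRadiusFrac,
      fissureTilt = fissureTilt, lesionCount = as.integer(lesionCount),
      lesionRadiusRange = as.numeric(rep_len(lesionRadiusRange, 2L)),
      noiseSd = noiseSd, deformAmplitude = deformAmplitude)
}

.withLocalSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# normalized coordinates in [-1, 1] at voxel centers
.normCoords <- function(shape) {
  lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) /
           (shape[a] / 2))
}

# distance (normalized units) from grid points to a line segment
.segDist2 <- function(px, py, pz, a, b) {
  v <- b - a
  L2 <- sum(v^2)
  t <- ((px - a[1]) * v[1] + (py - a[2]) * v[2] + (pz - a[3]) * v[3]) / L2
  t <- pmin(1, pmax(0, t))
  (px - a[1] - t * v[1])^2 + (py - a[2] - t * v[2])^2 + (pz - a[3] - t * v[3])^2
}

.phantomHU <- c(BG = 0, lobes = c(-900, -850, -800, -750, -700),
                fissure = -300, airway = -1000, lesion = -50)

# Deterministic base phantom (no deformation, no noise), in HU.
.phantomBase <- function(spec) {
  shape <- spec@shape
  cc <- .normCoords(shape)
  X <- array(cc[[1]], dim = shape)
  Y <- array(rep(cc[[2]], each = shape[1]), dim = shape)
  Z <- array(rep(cc[[3]], each = shape[1] * shape[2]), dim = shape)

  .withLocalSeed(spec@seed, {
    f <- spec@lungRadiusFrac
    semi <- c(f, 2.1 * f, 2.6 * f)
    centers <- list(left = c(-0.45, 0, -0.05), right = c(0.45, 0, -0.05))
    jit <- function() (stats::runif(1, -spec@fissureTilt, spec@fissureTilt)) * pi / 180

    labels <- array(0L, dim = shape)
    hu <- array(.phantomHU[["BG"]], dim = shape)
    lobeHU <- .phantomHU[2:6]

    for (s in 1:2) {
      cen <- centers[[s]]
      e <- ((X - cen[1]) / semi[1])^2 + ((Y - cen[2]) / semi[2])^2 +
        ((Z - cen[3]) / semi[3])^2
      inside <- e <= 1
      zl <- (Z - cen[3]) / semi[3]
      yl <- (Y - cen[2]) / semi[2]
      if (s == 1) {  # left: oblique fissure -> LLL (1) below, LUL (2) above
        tilt <- 0.35 + jit()
        sfun <- zl + tan(tilt) * yl
        lab <- ifelse(sfun < 0.05, 1L, 2L)
        fiss <- abs(sfun - 0.05) < 0.03
      } else {       # right: two fissures -> RLL (3), RML (4), RUL (5)
        tilt1 <- 0.35 + jit(); tilt2 <- 0.10 + jit()
        s1 <- zl + tan(tilt1) * yl
        s2 <- zl + tan(tilt2) * yl
        lab <- ifelse(s1 < -0.15, 3L, ifelse(s2 > 0.40, 5L, 4L))
        fiss <- (abs(s1 + 0.15) < 0.03) | (abs(s2 - 0.40) < 0.03)
      }
      labels[inside] <- lab[inside]
      hu[inside] <- lobeHU[lab[inside]]
      hu[inside & fiss] <- .phantomHU[["fissure"]]
    }

    # airway: trachea + two bronchi + second-generation branches
    segs <- list(
      list(a = c(0, -0.05, 0.85), b = c(0, -0.05, 0.25), r = 0.055),
      list(a = c(0, -0.05, 0.25), b = centers$left + c(0, 0, 0.15), r = 0.045),
      list(a = c(0, -0.05, 0.25), b = centers$right + c(0, 0, 0.15), r = 0.045),
      list(a = centers$left + c(0, 0, 0.15),
           b = centers$left + c(-0.10, 0.45, -0.35), r = 0.035),
      list(a = centers$left + c(0, 0, 0.15),
           b = centers$left + c(-0.10, -0.45, -0.35), r = 0.035),
      list(a = centers$right + c(0, 0, 0.15),
           b = centers$right + c(0.10, 0.45, -0.35), r = 0.035),
      list(a = centers$right + c(0, 0, 0.15),
           b = centers$right + c(0.10, -0.45, -0.35), r = 0.035))
    airway <- array(FALSE, dim = shape)
    for (sg in segs)
      airway <- airway | (.segDist2(X, Y, Z, sg$a, sg$b) < sg$r^2)
    labels[airway] <- .AIRWAY_CODE
    hu[airway] <- .phantomHU[["airway"]]

    # lesions: bright blobs strictly inside the lobes, mutually separated
    lesionMask <- array(FALSE, dim = shape)
    if (spec@lesionCount > 0L) {
      voxNorm <- 2 / min(shape)  # one voxel in normalized units (isotropic grid)
      radii <- stats::runif(spec@lesionCount, spec@lesionRadiusRange[1],
                     spec@lesionRadiusRange[2])
      airIdx <- which(airway)
      axC <- X[airIdx]; ayC <- Y[airIdx]; azC <- Z[airIdx]
      centersPicked <- list()
      for (li in seq_len(spec@lesionCount)) {
        rN <- radii[li] * voxNorm
        placed <- FALSE
        for (try in 1:1000) {
          s <- sample.int(2L, 1L)
          cen <- centers[[s]]
          p <- cen + stats::runif(3, -0.7, 0.7) * semi
          # radial clearance to the ellipsoid surface must exceed the lesion
          # radius plus a safety margin
          m <- rN + 1.5 * voxNorm
          d <- p - cen
          e <- sqrt(sum((d / semi)^2))
          if (e < 1e-9 || e >= 1) next
          rdir <- sqrt(sum(d^2)) / e
          if ((1 - e) * rdir < m) next
          dAir <- min((axC - p[1])^2 + (ayC - p[2])^2 + (azC - p[3])^2)
          if (dAir < m^2) next
          ok <- TRUE
          for (q in centersPicked) {
            if (sum((p - q$p)^2) < (rN + q$r + 3 * voxNorm)^2) { ok <- FALSE; break }
          }
          if (!ok) next
          centersPicked[[length(centersPicked) + 1L]] <- list(p = p, r = rN)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place lesion ", li,
               ": lesions too large for the lung geometry")
      }
      lobeMask <- labels %in% .LOBE_CODES
      dim(lobeMask) <- shape
      for (q in centersPicked) {
        blob <- ((X - q$p[1])^2 + (Y - q$p[2])^2 + (Z - q$p[3])^2) < q$r^2
        blob <- blob & lobeMask
        lesionMask <- lesionMask | blob
        hu[blob] <- .phantomHU[["lesion"]]
      }
    }
    list(hu = hu, labels = labels, lesionMask = lesionMask)
  })
}

# smooth random displacement field with given RMS amplitude (voxels)
.smoothRandomField <- function(shape, amplitude, smoothSigma = 6) {
  u <- lapply(1:3, function(a)
    cpp_gauss3(stats::rnorm(prod(shape)), shape, smoothSigma))
  mag2 <- u[[1]]^2 + u[[2]]^2 + u[[3]]^2
  rms <- sqrt(mean(mag2))
  scale <- if (rms > 0) amplitude / rms else 0
  lapply(u, function(v) array(v * scale, dim = shape))
}

.deformAndFinish <- function(base, spec, amplitude, seed) {
  shape <- spec@shape
  .withLocalSeed(seed, {
    hu <- base$hu; labels <- base$labels; lesion <- base$lesionMask
    if (amplitude > 0) {
      u <- .smoothRandomField(shape, amplitude)
      hu <- array(cpp_warp_field(as.double(hu), shape, u[[1]], u[[2]], u[[3]],
                                 shape, FALSE, .phantomHU[["BG"]]), dim = shape)
      labels <- array(as.integer(cpp_warp_field(as.double(labels), shape,
                                                u[[1]], u[[2]], u[[3]], shape,
                                                TRUE, 0)), dim = shape)
      lesion <- array(cpp_warp_field(as.double(lesion), shape, u[[1]], u[[2]],
                                     u[[3]], shape, TRUE, 0) > 0.5, dim = shape)
    }
    if (spec@noiseSd > 0)
      hu <- hu + stats::rnorm(length(hu), 0, spec@noiseSd * (600 - (-1024)))
    ct <- normalizeHU(ctVolume(array(hu, dim = shape)))
    list(ct = ct,
         labels = labelMap(labels),
         lesionMask = lesion)
  })
}

#' Generate a synthetic lung phantom
#'
#' @param spec A [PhantomSpec-class] from [phantomSpec()].
#' @return A list with elements `ct` (normalized [CTVolume-class]), `labels`
#'   (a [LabelMap-class] over the 7-class scheme) and `lesionMask` (logical
#'   array marking lesion voxels).
#' @examples
#' ph <- makePhantom(phantomSpec(shape = c(32, 32, 32), seed = 7))
#' table(labelArray(ph$labels))
#' @export
makePhantom <- function(spec) {
  validObject(spec)
  base <- .phantomBase(spec)
  .deformAndFinish(base, spec, spec@deformAmplitude, spec@seed + 1L)
}

#' Generate a cohort of anatomically related phantoms
#'
#' All members share the base geometry of `base` (same fissure tilts, same
#' lesions) and differ by per-subject smooth random deformations whose RMS
#' magnitude in voxels is `variability`, plus independent acquisition noise.
#' `variability = 0` yields bit-identical members.
#'
#' @param n Number of members (>= 1).
#' @param base A [PhantomSpec-class] defining the shared geometry.
#' @param variability RMS deformation magnitude in voxels.
#' @return A list of `n` lists, each with `ct`, `labels`, `lesionMask`.
#' @export
makeCohort <- function(n, base, variability = 1.5) {
  if (n < 1) stop("n must be >= 1")
  validObject(base)
  baseArrays <- .phantomBase(base)
  lapply(seq_len(n), function(i)
    .deformAndFinish(baseArrays, base, variability,
                     base@seed + 7919L * i))
}
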