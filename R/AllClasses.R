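#' @useDynLib LobeSeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Class codes of the 7-class segmentation scheme
#'
#' Integer voxel codes used throughout the package: 0 background (BG),
#' 1 left lower lobe (LLL), 2 left upper lobe (LUL), 3 right lower lobe (RLL),
#' 4 right middle lobe (RML), 5 right upper lobe (RUL), 6 airway.
#'
#' @format Named integer vector of length 7.
#' @export
lobeClassCodes <- c(BG = 0L, LLL = 1L, LUL = 2L, RLL = 3L, RML = 4L,
                    RUL = 5L, airway = 6L)

.LOBE_CODES <- 1:5
.AIRWAY_CODE <- 6L
.CLASS_NAMES <- names(lobeClassCodes)

#' CTVolume: a 3D CT-like intensity volume
#'
#' Holds a 3D scalar grid (Hounsfield units before normalization,
#' dimensionless in \[0,1\] after), per-axis voxel spacing in mm, a 4x4
#' voxel-to-world affine (NIfTI convention, 0-based voxel indices), and a flag
#' recording whether intensities have been clipped/normalized.
#'
#' @slot intensities 3D numeric array.
#' @slot spacing Numeric length-3, voxel size in mm, strictly positive.
#' @slot affine 4x4 numeric voxel-to-world matrix.
#' @slot normalized Logical flag: intensities mapped to \[0,1\].
#' @export
setClass("CTVolume", representation(
  intensities = "array", spacing = "numeric", affine = "matrix",
  normalized = "logical"
))

setValidity("CTVolume", function(object) {
  msg <- character()
  if (length(dim(object@intensities)) != 3L)
    msg <- c(msg, "intensities must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (isTRUE(object@normalized)) {
    rng <- range(object@intensities)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      msg <- c(msg, "normalized volume has intensities outside [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' LabelMap: integer voxel labels over the 7-class scheme
#'
#' @slot labels 3D integer array with values among the class codes.
#' @slot classNames Ordered class names (see [lobeClassCodes]).
#' @slot spacing,affine Geometry, as in [CTVolume-class].
#' @export
setClass("LabelMap", representation(
  labels = "array", classNames = "character", spacing = "numeric",
  affine = "matrix"
))

setValidity("LabelMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  codes <- seq_along(object@classNames) - 1L
  if (!all(object@labels %in% codes))
    msg <- c(msg, "labels contain values outside the class code range")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (length(msg)) msg else TRUE
})

#' ProbAtlas: probabilistic lobe atlas for one anatomical group
#'
#' A 5-channel per-voxel lobe-probability field built by label fusion over
#' co-registered members, together with the group's reference volume.
#'
#' @slot probs 4D array (nx, ny, nz, 5); each channel in \[0,1\] and channel
#'   sums equal to 1 (within 1e-6) wherever any lobe has support.
#' @slot reference The group reference [CTVolume-class] (registration target).
#' @slot groupId Character group identifier.
#' @slot nMembers Number of fused members (>= 1).
#' @slot sigma Gaussian smoothing SD (voxels) used at build time.
#' @export
setClass("ProbAtlas", representation(
  probs = "array", reference = "CTVolume", groupId = "character",
  nMembers = "integer", sigma = "numeric"
))

setValidity("ProbAtlas", function(object) {
  msg <- character()
  d <- dim(object@probs)
  if (length(d) != 4L || d[4] != 5L)
    msg <- c(msg, "probs must be a 4D array with 5 channels")
  if (object@nMembers < 1L) msg <- c(msg, "nMembers must be >= 1")
  rng <- range(object@probs)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-6)
    msg <- c(msg, "probabilities outside [0,1]")
  s <- .channelSum(object@probs)
  supported <- s > 1e-9
  if (any(supported) && max(abs(s[supported] - 1)) > 1e-6)
    msg <- c(msg, "channel sums differ from 1 on supported voxels")
  if (length(msg)) msg else TRUE
})

.channelSum <- function(p4) {
  d <- dim(p4)
  rowSums(matrix(p4, ncol = d[4]))
}

#' GroupAssignment: partition of a cohort into anatomical groups
#'
#' @slot groups List of integer vectors partitioning member indices.
#' @slot threshold Pairwise mean-over-lobes Dice cut used for grouping.
#' @slot diceMatrix Symmetric matrix of pairwise lobe-averaged Dice values.
#' @export
setClass("GroupAssignment", representation(
  groups = "list", threshold = "numeric", diceMatrix = "matrix"
))

setValidity("GroupAssignment", function(object) {
  members <- sort(unlist(object@groups))
  n <- nrow(object@diceMatrix)
  if (!identical(members, seq_len(n)))
    return("groups must partition 1..n exactly once")
  TRUE
})

#' DiffeoTransform: invertible spatial mapping between two grids
#'
#' Rigid (translation) pre-alignment from center-of-mass matching plus dense
#' forward/inverse displacement fields (voxel units) from diffeomorphic
#' registration. The forward field resamples a moving-space image onto the
#' fixed grid; the inverse field maps fixed-space images back.
#'
#' @slot preAlign Length-3 translation in mm (world), moving relative to fixed.
#' @slot forward,inverse Either `NULL`-free empty lists (rigid-only) or lists
#'   with elements `x`,`y`,`z`: 3D arrays of displacements in voxels.
#' @slot fixedMeta,movingMeta Geometry records: `list(dim, spacing, affine)`.
#' @export
setClass("DiffeoTransform", representation(
  preAlign = "numeric", forward = "list", inverse = "list",
  fixedMeta = "list", movingMeta = "list"
))

#' StagePrediction: per-structure network activations
#'
#' @slot activations 4D array (nx, ny, nz, 7), values in \[0,1\]; channels are
#'   LLL, LUL, RLL, RML, RUL, whole lung, airway.
#' @slot stage Integer 1 or 2.
#' @slot gridMeta Geometry of the prediction grid plus bookkeeping needed to
#'   map back (source grid of stage 1, crop offsets of stage 2).
#' @export
setClass("StagePrediction", representation(
  activations = "array", stage = "integer", gridMeta = "list"
))

setValidity("StagePrediction", function(object) {
  d <- dim(object@activations)
  if (length(d) != 4L || d[4] != 7L)
    return("activations must be (nx, ny, nz, 7)")
  rng <- range(object@activations)
  if (!all(is.finite(rng))) return("non-finite activations")
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    return("activations outside [0,1]")
  if (!object@stage %in% c(1L, 2L)) return("stage must be 1 or 2")
  TRUE
})

#' FusionResult: fused decoder output before/after prior filling
#'
#' @slot labels A [LabelMap-class] on the working grid.
#' @slot lungMask Logical 3D array: the dominant connected components of the
#'   whole-lung decoder's binarized output (both lungs; spurious islands
#'   removed).
#' @slot gapMask Logical 3D array: lung voxels initially unassigned.
#' @slot provenance Integer array: 0 background, 1 network, 2 prior fill,
#'   3 nearest-label fallback.
#' @export
setClass("FusionResult", representation(
  labels = "LabelMap", lungMask = "array", gapMask = "array",
  provenance = "array"
))

#' PhantomSpec: parameters of the synthetic lung phantom
#'
#' @slot shape Integer length-3 voxel counts (each >= 32).
#' @slot seed RNG seed; the same spec + seed is bit-reproducible.
#' @slot lungRadiusFrac Fraction of the grid half-extent occupied by each lung.
#' @slot fissureTilt Angular jitter (degrees) of the lobar dividing surfaces.
#' @slot lesionCount Number of inserted lesions (>= 0).
#' @slot lesionRadiusRange Voxel radius range of lesions.
#' @slot noiseSd Additive Gaussian noise SD in normalized intensity units.
#' @slot deformAmplitude Smooth random warp magnitude in voxels.
#' @export
setClass("PhantomSpec", representation(
  shape = "integer", seed = "integer", lungRadiusFrac = "numeric",
  fissureTilt = "numeric", lesionCount = "integer",
  lesionRadiusRange = "numeric", noiseSd = "numeric",
  deformAmplitude = "numeric"
))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (any(object@shape < 32L)) msg <- c(msg, "each axis must be >= 32 voxels")
  if (object@lesionCount < 0L) msg <- c(msg, "lesionCount must be >= 0")
  if (any(object@lesionRadiusRange <= 0))
    msg <- c(msg, "lesion radii must be positive")
  rmax <- object@lungRadiusFrac * min(object@shape) / 2
  if (max(object@lesionRadiusRange) >= rmax)
    msg <- c(msg, "lesions must be smaller than the lung radius")
  if (length(msg)) msg else TRUE
})
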