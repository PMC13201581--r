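#' Construct a CTVolume in memory
#'
#' @param intensities 3D numeric array (HU, or \[0,1\] if `normalized`).
#' @param spacing Voxel size in mm (length 3, or scalar recycled).
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal affine built
#'   from `spacing` with the origin at voxel (0,0,0).
#' @param normalized Whether intensities are already normalized to \[0,1\].
#' @return A [CTVolume-class].
#' @export
ctVolume <- function(intensities, spacing = c(1, 1, 1), affine = NULL,
                     normalized = FALSE) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  new("CTVolume", intensities = intensities, spacing = spacing,
      affine = affine, normalized = normalized)
}

#' Construct a LabelMap in memory
#'
#' @param labels 3D integer array of class codes (see [lobeClassCodes]).
#' @param spacing,affine Geometry, as in [ctVolume()].
#' @param classNames Ordered class names; defaults to the 7-class scheme.
#' @return A [LabelMap-class].
#' @export
labelMap <- function(labels, spacing = c(1, 1, 1), affine = NULL,
                     classNames = names(lobeClassCodes)) {
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  storage.mode(labels) <- "integer"
  new("LabelMap", labels = labels, classNames = classNames,
      spacing = spacing, affine = affine)
}

.spacingFromAffine <- function(affine) {
  vapply(1:3, function(j) sqrt(sum(affine[1:3, j]^2)), numeric(1))
}

#' Read a 3D volume from a NIfTI file
#'
#' Spacing and affine are taken from the header; no resampling is performed.
#' Gzipped files (.nii.gz) are handled transparently.
#'
#' @param path Path to a .nii or .nii.gz file.
#' @param normalized Whether the stored intensities are already in \[0,1\].
#' @return A [CTVolume-class].
#' @export
readVolume <- function(path, normalized = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D scalar image, got ", length(dim(arr)), " dimensions")
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  ctVolume(array(as.double(arr), dim = dim(arr)),
           spacing = .spacingFromAffine(aff), affine = aff,
           normalized = normalized)
}

#' Read a label map from a NIfTI file
#'
#' @inheritParams readVolume
#' @return A [LabelMap-class].
#' @export
readLabelMap <- function(path) {
  vol <- readVolume(path)
  labelMap(array(as.integer(round(vol@intensities)), dim = dim(vol)),
           spacing = vol@spacing, affine = vol@affine)
}

.asNiftiWithAffine <- function(arr, affine) {
  sp <- .spacingFromAffine(affine)
  RNifti::asNifti(arr, reference = list(
    pixdim = c(-1, sp, 0, 0, 0, 0),
    sform_code = 2L, qform_code = 0L,
    srow_x = affine[1, ], srow_y = affine[2, ], srow_z = affine[3, ]),
    datatype = "double")
}

#' Write a volume or label map to NIfTI
#'
#' Intensities are stored as float64 so a write/read round trip is bit exact;
#' the affine survives within float32 header precision.
#'
#' @param x A [CTVolume-class] or [LabelMap-class].
#' @param path Output path ending in .nii or .nii.gz.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(x, path) {
  arr <- if (is(x, "LabelMap")) array(as.double(x@labels), dim = dim(x))
         else x@intensities
  RNifti::writeNifti(.asNiftiWithAffine(arr, x@affine), path)
  invisible(path)
}

# round half away from zero (R's round() is banker's)
.rhalf <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Resample a volume to isotropic voxel spacing
#'
#' Intensities are interpolated trilinearly; label maps use nearest-neighbour
#' assignment. The output shape per axis is the physical extent divided by the
#' target spacing, rounded half away from zero.
#'
#' @param vol A [CTVolume-class] or [LabelMap-class].
#' @param targetMm Target isotropic spacing in mm (default 1, the working
#'   resolution of the pipeline).
#' @return Object of the same class at spacing `(targetMm, targetMm, targetMm)`.
#' @export
setGeneric("resampleIsotropic", function(vol, targetMm = 1.0)
  standardGeneric("resampleIsotropic"))

.isoGeometry <- function(d, sp, affine, targetMm) {
  newDim <- as.integer(pmax(1, .rhalf(d * sp / targetMm)))
  scale <- targetMm / sp
  list(dim = newDim, M = diag(c(scale, 1)),
       affine = affine %*% diag(c(scale, 1)))
}

#' @rdname resampleIsotropic
#' @export
setMethod("resampleIsotropic", "CTVolume", function(vol, targetMm = 1.0) {
  if (!is.finite(targetMm) || targetMm <= 0) stop("targetMm must be positive")
  g <- .isoGeometry(dim(vol), vol@spacing, vol@affine, targetMm)
  out <- cpp_resample_affine(as.double(vol@intensities), dim(vol), g$dim,
                             g$M, FALSE, 0)
  if (vol@normalized) out <- pmin(1, pmax(0, out))
  ctVolume(array(out, dim = g$dim), spacing = rep(targetMm, 3L),
           affine = g$affine, normalized = vol@normalized)
})

#' @rdname resampleIsotropic
#' @export
setMethod("resampleIsotropic", "LabelMap", function(vol, targetMm = 1.0) {
  if (!is.finite(targetMm) || targetMm <= 0) stop("targetMm must be positive")
  g <- .isoGeometry(dim(vol), vol@spacing, vol@affine, targetMm)
  out <- cpp_resample_affine(as.double(vol@labels), dim(vol), g$dim,
                             g$M, TRUE, 0)
  labelMap(array(as.integer(out), dim = g$dim), spacing = rep(targetMm, 3L),
           affine = g$affine, classNames = vol@classNames)
})

#' Clip and normalize Hounsfield units to \[0,1\]
#'
#' Applies `(clip(x, lo, hi) - lo) / (hi - lo)`. The default window
#' \[-1024, 600\] HU preserves lung parenchyma and fissure contrast.
#'
#' @param vol A [CTVolume-class] in HU.
#' @param lo,hi Clipping bounds in HU, `lo < hi`.
#' @return A normalized [CTVolume-class] (flag set).
#' @export
normalizeHU <- function(vol, lo = -1024, hi = 600) {
  if (lo >= hi) stop("lo must be strictly less than hi")
  x <- (pmin(pmax(vol@intensities, lo), hi) - lo) / (hi - lo)
  ctVolume(array(x, dim = dim(vol)), spacing = vol@spacing,
           affine = vol@affine, normalized = TRUE)
}

#' Resample a label map onto a reference grid
#'
#' Nearest-neighbour assignment onto the grid of `ref`; the output is
#' geometrically congruent with `ref` and never contains class indices absent
#' from the input.
#'
#' @param ref A [CTVolume-class] providing the target geometry.
#' @param labels A [LabelMap-class] to resample.
#' @return A [LabelMap-class] congruent with `ref`.
#' @export
resampleLabelsTo <- function(ref, labels) {
  if (abs(det(labels@affine)) < 1e-12) stop("degenerate label affine")
  if (sameGrid(ref, labels)) return(labels)
  M <- solve(labels@affine) %*% ref@affine
  out <- cpp_resample_affine(as.double(labels@labels), dim(labels),
                             dim(ref), M, TRUE, 0)
  labelMap(array(as.integer(out), dim = dim(ref)), spacing = ref@spacing,
           affine = ref@affine, classNames = labels@classNames)
}

#' Test geometric congruence of two volumes
#'
#' @param a,b CTVolume or LabelMap objects.
#' @param tol Tolerance on affine entries.
#' @return TRUE if shapes match and affines agree within `tol`.
#' @export
sameGrid <- function(a, b, tol = 1e-4) {
  identical(dim(a), dim(b)) && max(abs(a@affine - b@affine)) <= tol
}

.requireSameGrid <- function(a, b, what = "inputs") {
  if (!sameGrid(a, b)) stop(what, " must share the same grid (shape + affine)")
}
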