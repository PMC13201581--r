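#' Dice overlap coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)`. Two empty masks score 1.0 by convention.
#'
#' @param pred,ref Congruent logical/0-1 arrays.
#' @return Scalar in \[0,1\].
#' @export
diceScore <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("grids differ")
  a <- sum(pred); b <- sum(ref)
  if (a + b == 0) return(1.0)
  2 * sum(pred & ref) / (a + b)
}

#' Average Hausdorff distance between two masks (mm)
#'
#' Symmetric mean of the directed average surface distances:
#' `(mean_a d(a, ∂B) + mean_b d(b, ∂A)) / 2`, where boundaries are mask voxels
#' with at least one 6-neighbour outside the mask and distances are Euclidean
#' between boundary voxel centers scaled by `spacing`.
#'
#' @param pred,ref Congruent nonempty logical arrays.
#' @param spacing Voxel size in mm (length 3 or scalar).
#' @return Scalar distance in mm (>= 0; 0 for identical masks).
#' @export
averageHausdorff <- function(pred, ref, spacing = c(1, 1, 1)) {
  if (!identical(dim(pred), dim(ref))) stop("grids differ")
  if (sum(pred) == 0 || sum(ref) == 0)
    stop("average Hausdorff distance is undefined for an empty mask")
  spacing <- rep_len(as.numeric(spacing), 3L)
  d <- dim(pred)
  coordsMm <- function(mask) {
    idx <- which(as.logical(cpp_boundary6(as.logical(mask), d)))
    ijk <- arrayInd(idx, d) - 1L
    sweep(ijk, 2, spacing, `*`)
  }
  A <- coordsMm(pred); B <- coordsMm(ref)
  (cpp_directed_avg_dist(A, B) + cpp_directed_avg_dist(B, A)) / 2
}

#' Absolute volume similarity
#'
#' `max(0, 1 - ||A| - |B|| / |B|)`: 1 for identical volumes, decreasing with
#' volume mismatch, clipped at 0.
#'
#' @param pred Predicted mask (logical array).
#' @param ref Reference mask, nonempty.
#' @return Scalar in \[0,1\].
#' @export
absVolumeSimilarity <- function(pred, ref) {
  if (!identical(dim(pred), dim(ref))) stop("grids differ")
  vb <- sum(ref)
  if (vb == 0) stop("reference mask is empty")
  max(0, 1 - abs(sum(pred) - vb) / vb)
}

#' Default severity buckets from the lesion volume fraction
#' @keywords internal
.severityBucket <- function(lesionFraction,
                            thresholds = c(mild = 0.05, moderate = 0.15)) {
  if (is.null(lesionFraction)) return(NA_character_)
  if (lesionFraction <= 0) "none"
  else if (lesionFraction <= thresholds[["mild"]]) "mild"
  else if (lesionFraction <= thresholds[["moderate"]]) "moderate"
  else "severe"
}

#' Evaluate a predicted label map against a reference
#'
#' Computes Dice, average Hausdorff distance (mm), and absolute volume
#' similarity per structure at the native resolution of the inputs, plus the
#' arithmetic mean over the five lobes. Structures missing from the reference
#' are reported as `NA` and excluded from the means with a warning.
#'
#' @param pred,ref Congruent [LabelMap-class] objects.
#' @param lesionFraction Optional known lesion volume fraction (lesion voxels
#'   over lung voxels) used to tag a severity bucket.
#' @param structures Integer class codes to evaluate (default: the five lobes
#'   plus airway when present in the reference).
#' @return A list with `perStructure` (data.frame with dice/ahd/avs rows),
#'   `meanOverLobes` (named numeric triple) and `severityBucket`.
#' @export
evaluateSegmentation <- function(pred, ref, lesionFraction = NULL,
                                 structures = NULL) {
  .requireSameGrid(pred, ref, "pred and ref")
  refArr <- ref@labels; predArr <- pred@labels
  if (is.null(structures)) {
    structures <- .LOBE_CODES
    if (any(refArr == .AIRWAY_CODE)) structures <- c(structures, .AIRWAY_CODE)
  }
  rows <- lapply(structures, function(k) {
    rmask <- refArr == k
    if (!any(rmask)) {
      warning("structure ", .CLASS_NAMES[k + 1L],
              " absent from reference; excluded from means")
      return(data.frame(structure = .CLASS_NAMES[k + 1L], code = k,
                        dice = NA_real_, ahd = NA_real_, avs = NA_real_))
    }
    pmask <- predArr == k
    ahd <- if (any(pmask)) averageHausdorff(pmask, rmask, ref@spacing)
           else NA_real_
    data.frame(structure = .CLASS_NAMES[k + 1L], code = k,
               dice = diceScore(pmask, rmask), ahd = ahd,
               avs = absVolumeSimilarity(pmask, rmask))
  })
  perStructure <- do.call(rbind, rows)
  lobeRows <- perStructure[perStructure$code %in% .LOBE_CODES, ]
  meanOverLobes <- c(dice = mean(lobeRows$dice, na.rm = TRUE),
                     ahd = mean(lobeRows$ahd, na.rm = TRUE),
                     avs = mean(lobeRows$avs, na.rm = TRUE))
  list(perStructure = perStructure, meanOverLobes = meanOverLobes,
       severityBucket = .severityBucket(lesionFraction))
}

# mean-over-lobes Dice between two label maps (grouping + cohort diagnostics)
.meanLobeDice <- function(a, b, codes = .LOBE_CODES) {
  mean(vapply(codes, function(k) diceScore(a == k, b == k), numeric(1)))
}
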