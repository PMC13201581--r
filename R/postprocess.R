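#' Largest connected component of a binary mask
#'
#' @param mask Logical 3D array.
#' @param connectivity 26 (default) or 6.
#' @return Logical array keeping only the largest component (empty input
#'   gives an empty output).
#' @export
largestComponent <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), d, as.integer(connectivity))
  if (max(lab) == 0L) return(array(FALSE, dim = d))
  sizes <- tabulate(lab)
  array(lab == which.max(sizes), dim = d)
}

# Whole-lung cleanup: the left and right lungs are anatomically disjoint, so
# a single largest component would delete one lung. Keep every component
# whose size is at least `frac` of the largest (spurious islands fall far
# below that).
.lungComponents <- function(mask, frac = 0.2, connectivity = 26L) {
  d <- dim(mask)
  lab <- cpp_label_components(as.logical(mask), d, as.integer(connectivity))
  if (max(lab) == 0L) return(array(FALSE, dim = d))
  sizes <- tabulate(lab)
  keep <- which(sizes >= frac * max(sizes))
  array(lab %in% keep, dim = d)
}

#' Fuse the seven decoder activations into a label map
#'
#' Implements the decoder fusion rules: each decoder output is binarized at
#' 0.5; the whole-lung decoder's dominant connected components (both lungs;
#' small spurious islands are dropped) define the lung mask, which acts as a
#' background indicator — activations outside it are disregarded, so
#' those voxels stay background. Inside the lung, a voxel is assigned the
#' candidate structure (activation > 0.5) with the highest activation, ties
#' to the lowest channel index; airway wins only where it is the argmax.
#' Lung voxels with no candidate become the gap mask, to be filled from the
#' prior.
#'
#' @param pred A stage-2 [StagePrediction-class].
#' @return A [FusionResult-class] (pre-fill).
#' @export
fuseDecoders <- function(pred) {
  act <- activations(pred)
  if (!all(is.finite(act)) || min(act) < 0 || max(act) > 1)
    stop("activations must be finite and within [0,1]")
  d <- dim(act)[1:3]
  n <- prod(d)
  lungMask <- .lungComponents(array(act[, , , 6] > 0.5, dim = d))
  cand <- matrix(act[, , , c(1:5, 7)], ncol = 6)  # lobes + airway
  cand[cand <= 0.5] <- -1
  best <- max.col(cand, ties.method = "first")
  hasCand <- cand[cbind(seq_len(n), best)] > 0.5
  lab <- integer(n)
  lab[hasCand] <- ifelse(best[hasCand] == 6L, .AIRWAY_CODE, best[hasCand])
  lab[!lungMask] <- 0L
  gap <- array(lungMask & lab == 0L, dim = d)
  prov <- array(0L, dim = d)
  prov[lab != 0L] <- 1L
  meta <- pred@gridMeta
  labels <- labelMap(array(lab, dim = d),
                     spacing = if (!is.null(meta$spacing)) meta$spacing else c(1, 1, 1),
                     affine = meta$affine)
  new("FusionResult", labels = labels, lungMask = lungMask, gapMask = gap,
      provenance = prov)
}

#' Finalize a fused segmentation in native space
#'
#' Applies largest-component cleanup per structure (voxels dropped from minor
#' components rejoin the gap set), fills all lung gaps from the warped atlas
#' with [fillFromAtlas()], maps the result back to the native grid with the
#' transform's inverse field (nearest-neighbour), and resamples onto the
#' native volume's grid so the output is congruent with the original input.
#'
#' @param fr A [FusionResult-class] on the working grid.
#' @param atlas A [ProbAtlas-class] warped to the working grid.
#' @param t The [DiffeoTransform-class] whose fixed side is the working grid
#'   and moving side the native-space input, or `NULL` for identity.
#' @param native The native-space [CTVolume-class] (geometry target).
#' @param priorFill Fill lung gaps from the atlas (default). With `FALSE`
#'   gaps stay background — the ablation arm of the prior-guided fill.
#' @return A [LabelMap-class] congruent with `native`.
#' @export
finalizeSegmentation <- function(fr, atlas, t, native, priorFill = TRUE) {
  lab <- fr@labels@labels
  d <- dim(lab)
  # largest component per structure; minor components become gaps
  for (k in c(.LOBE_CODES, .AIRWAY_CODE)) {
    mk <- lab == k
    if (!any(mk)) next
    keep <- largestComponent(array(mk, dim = d))
    lab[mk & !keep] <- 0L
  }
  gaps <- array(fr@lungMask & lab == 0L, dim = d)
  working <- labelMap(array(lab, dim = d), spacing = fr@labels@spacing,
                      affine = fr@labels@affine,
                      classNames = fr@labels@classNames)
  out <- if (priorFill) fillFromAtlas(working, fr@lungMask, atlas)$labels
         else working
  if (!is.null(t)) out <- applyTransform(t, out, "inverse")
  resampleLabelsTo(native, out)
}
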