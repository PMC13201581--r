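#' @name accessors
#' @title Accessors for LobeSeg data classes
#' @description Slot access for the package's S4 containers goes through these
#'   generics; user code should never reach into slots directly.
#' @param object,x An object of the relevant class.
#' @param value Replacement value.
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("voxelAffine", function(object) standardGeneric("voxelAffine"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("classNames", function(object) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setGeneric("atlasProbs", function(object) standardGeneric("atlasProbs"))
#' @rdname accessors
#' @export
setGeneric("atlasReference", function(object) standardGeneric("atlasReference"))
#' @rdname accessors
#' @export
setGeneric("groupId", function(object) standardGeneric("groupId"))
#' @rdname accessors
#' @export
setGeneric("nMembers", function(object) standardGeneric("nMembers"))
#' @rdname accessors
#' @export
setGeneric("groups", function(object) standardGeneric("groups"))
#' @rdname accessors
#' @export
setGeneric("diceMatrix", function(object) standardGeneric("diceMatrix"))
#' @rdname accessors
#' @export
setGeneric("activations", function(object) standardGeneric("activations"))

#' @rdname accessors
#' @export
setMethod("intensities", "CTVolume", function(object) object@intensities)
#' @rdname accessors
#' @export
setMethod("spacing", "CTVolume", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "LabelMap", function(object) object@spacing)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "CTVolume", function(object) object@affine)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "LabelMap", function(object) object@affine)
#' @rdname accessors
#' @export
setMethod("isNormalized", "CTVolume", function(object) object@normalized)
#' @rdname accessors
#' @export
setMethod("labelArray", "LabelMap", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("classNames", "LabelMap", function(object) object@classNames)
#' @rdname accessors
#' @export
setMethod("atlasProbs", "ProbAtlas", function(object) object@probs)
#' @rdname accessors
#' @export
setMethod("atlasReference", "ProbAtlas", function(object) object@reference)
#' @rdname accessors
#' @export
setMethod("groupId", "ProbAtlas", function(object) object@groupId)
#' @rdname accessors
#' @export
setMethod("nMembers", "ProbAtlas", function(object) object@nMembers)
#' @rdname accessors
#' @export
setMethod("groups", "GroupAssignment", function(object) object@groups)
#' @rdname accessors
#' @export
setMethod("diceMatrix", "GroupAssignment", function(object) object@diceMatrix)
#' @rdname accessors
#' @export
setMethod("activations", "StagePrediction", function(object) object@activations)

#' @rdname accessors
#' @export
setMethod("dim", "CTVolume", function(x) dim(x@intensities))
#' @rdname accessors
#' @export
setMethod("dim", "LabelMap", function(x) dim(x@labels))

setMethod("show", "CTVolume", function(object) {
  d <- dim(object)
  cat(sprintf("CTVolume %dx%dx%d | spacing %.3g x %.3g x %.3g mm | %s\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3],
              if (object@normalized) "normalized [0,1]" else "Hounsfield units"))
  rng <- range(object@intensities)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", rng[1], rng[2]))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object)
  present <- sort(unique(as.integer(object@labels)))
  cat(sprintf("LabelMap %dx%dx%d | classes present: %s\n", d[1], d[2], d[3],
              paste(object@classNames[present + 1L], collapse = ", ")))
})

setMethod("show", "ProbAtlas", function(object) {
  d <- dim(object@probs)
  cat(sprintf("ProbAtlas '%s' | grid %dx%dx%d | %d member(s) | sigma %.2f voxels\n",
              object@groupId, d[1], d[2], d[3], object@nMembers, object@sigma))
})

setMethod("show", "GroupAssignment", function(object) {
  sizes <- vapply(object@groups, length, integer(1))
  cat(sprintf("GroupAssignment: %d member(s) in %d group(s) (sizes %s) at Dice >= %.2f\n",
              sum(sizes), length(sizes), paste(sizes, collapse = ","),
              object@threshold))
})

setMethod("show", "DiffeoTransform", function(object) {
  dense <- length(object@forward) > 0
  cat(sprintf("DiffeoTransform | pre-align (%.2f, %.2f, %.2f) mm | %s\n",
              object@preAlign[1], object@preAlign[2], object@preAlign[3],
              if (dense) "dense forward/inverse fields" else "rigid only"))
})

setMethod("show", "StagePrediction", function(object) {
  d <- dim(object@activations)
  cat(sprintf("StagePrediction (stage %d) | grid %dx%dx%d | 7 channels\n",
              object@stage, d[1], d[2], d[3]))
})
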