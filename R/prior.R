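#' Group co-registered label maps by pairwise Dice
#'
#' Pairwise mean-over-five-lobes Dice is computed between all mutually aligned
#' label maps; the partition is the set of connected components of the graph
#' whose edges join pairs with Dice at or above `threshold`. Deterministic in
#' the input order.
#'
#' @param labels List of grid-congruent [LabelMap-class] objects.
#' @param threshold Dice cut (default 0.80).
#' @return A [GroupAssignment-class].
#' @export
groupByDice <- function(labels, threshold = 0.80) {
  n <- length(labels)
  if (n < 1) stop("need at least one label map")
  for (i in seq_len(n - 1))
    .requireSameGrid(labels[[i]], labels[[i + 1]], "label maps")
  arrs <- lapply(labels, labelArray)
  D <- diag(1, n)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      D[i, j] <- D[j, i] <- .meanLobeDice(arrs[[i]], arrs[[j]])
  groupFromDiceMatrix(D, threshold)
}

#' Partition members from a precomputed Dice matrix
#'
#' The grouping rule of [groupByDice()] factored out: connected components of
#' the thresholded similarity graph.
#'
#' @param D Symmetric matrix of pairwise similarity values.
#' @param threshold Edge cut: pairs with `D >= threshold` are linked.
#' @return A [GroupAssignment-class].
#' @export
groupFromDiceMatrix <- function(D, threshold = 0.80) {
  groups <- .connectedGroups(D >= threshold)
  new("GroupAssignment", groups = groups, threshold = threshold,
      diceMatrix = D)
}

# connected components of an adjacency matrix by union-find;
# groups ordered by their smallest member
.connectedGroups <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (adj[i, j]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(sort(unique(roots)), function(r) which(roots == r)))
}

#' Build a probabilistic lobe atlas by label fusion
#'
#' For each lobe k, the pre-smoothing probability at a voxel is the fraction
#' of members labelling it k. Each channel is then convolved with an isotropic
#' 3D Gaussian of SD `sigma` (voxels), and channels are renormalized to sum to
#' 1 wherever the pre-smoothing channel sum is positive (elsewhere all
#' channels stay 0).
#'
#' @param members List of `list(ct =, labels =)` pairs co-registered to the
#'   group reference grid; the first member's CT is used as the reference
#'   unless `reference` is given.
#' @param sigma Gaussian smoothing SD in voxels (1 mm at the working
#'   resolution); default 1.0.
#' @param reference Optional [CTVolume-class] registration target.
#' @param groupId Atlas identifier.
#' @return A [ProbAtlas-class].
#' @export
buildAtlas <- function(members, sigma = 1.0, reference = NULL,
                       groupId = "g1") {
  if (length(members) == 0) stop("empty member list")
  labs <- lapply(members, function(m) labelArray(m$labels))
  d <- dim(labs[[1]])
  n <- length(labs)
  pre <- array(0, dim = c(d, 5))
  for (k in .LOBE_CODES) {
    acc <- array(0, dim = d)
    for (L in labs) acc <- acc + (L == k)
    pre[, , , k] <- acc / n
  }
  preSum <- array(.channelSum(pre), dim = d)
  post <- pre
  for (k in .LOBE_CODES)
    post[, , , k] <- cpp_gauss3(pre[, , , k], d, sigma)
  s <- array(.channelSum(post), dim = d)
  support <- preSum > 0 & s > 0
  for (k in .LOBE_CODES) {
    ch <- post[, , , k]
    ch[support] <- ch[support] / s[support]
    ch[!support] <- 0
    post[, , , k] <- ch
  }
  if (is.null(reference)) reference <- members[[1]]$ct
  new("ProbAtlas", probs = post, reference = reference,
      groupId = as.character(groupId), nMembers = as.integer(n),
      sigma = sigma)
}

#' Composite registration-quality score
#'
#' `w_mse / (1 + MSE) + w_ncc * (NCC + 1) / 2 + w_mi * MI`, where MSE is the
#' mean squared intensity difference, NCC the global normalized
#' cross-correlation in \[-1, 1\], and MI the joint-histogram mutual
#' information (see [mutualInformation()]). All weights default to 1.
#'
#' @param fixed,warpedMoving Grid-congruent normalized [CTVolume-class]
#'   objects.
#' @param wMse,wNcc,wMi Term weights.
#' @param bins MI histogram bins per axis.
#' @return Scalar score (higher = more similar).
#' @export
compositeSimilarity <- function(fixed, warpedMoving, wMse = 1, wNcc = 1,
                                wMi = 1, bins = 32L) {
  .requireSameGrid(fixed, warpedMoving, "fixed and warpedMoving")
  a <- as.double(fixed@intensities)
  b <- as.double(warpedMoving@intensities)
  mse <- mean((a - b)^2)
  ncc <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
         else stats::cor(a, b)
  mi <- mutualInformation(a, b, bins)
  wMse / (1 + mse) + wNcc * (ncc + 1) / 2 + wMi * mi
}

#' Select the best-matching atlas for an input scan
#'
#' Registers the (preprocessed) input to each atlas reference, scores each
#' registration with [compositeSimilarity()], and returns the argmax atlas
#' with its transform. Ties break to the lowest group id.
#'
#' @param inputCt Normalized isotropic [CTVolume-class].
#' @param atlases Nonempty list of [ProbAtlas-class] objects.
#' @param levels Registration iteration schedule.
#' @param cacheDir Optional transform cache directory.
#' @param verbose Log scores to stderr.
#' @return `list(atlas =, transform =, scores =)`; the transform's fixed side
#'   is the selected atlas reference grid.
#' @export
selectAtlas <- function(inputCt, atlases, levels = c(100, 50, 25),
                        cacheDir = NULL, verbose = FALSE) {
  if (length(atlases) == 0) stop("empty atlas list")
  ord <- order(vapply(atlases, groupId, character(1)))
  scores <- numeric(length(atlases))
  transforms <- vector("list", length(atlases))
  for (i in ord) {
    ref <- atlasReference(atlases[[i]])
    tr <- NULL
    if (!is.null(cacheDir)) {
      key <- transformCacheKey(ref, inputCt, levels)
      tr <- loadCachedTransform(key, cacheDir)
      if (!is.null(tr))
        message("registration cache hit for group ", groupId(atlases[[i]]))
    }
    if (is.null(tr)) {
      tr <- registerDiffeomorphic(ref, inputCt, levels = levels)
      if (!is.null(cacheDir)) cacheTransform(tr, key, cacheDir)
    }
    warped <- applyTransform(tr, inputCt, "forward")
    scores[i] <- compositeSimilarity(ref, warped)
    transforms[[i]] <- tr
    if (verbose)
      message(sprintf("atlas %s: score %.4f", groupId(atlases[[i]]),
                      scores[i]))
  }
  best <- ord[which.max(scores[ord])]
  list(atlas = atlases[[best]], transform = transforms[[best]],
       scores = stats::setNames(scores, vapply(atlases, groupId,
                                               character(1))))
}

#' Fill unlabeled lung voxels from a probabilistic atlas
#'
#' Every voxel inside `lungMask` carrying no lobe label receives the argmax
#' lobe of the atlas (ties to the lowest channel index); voxels where all
#' atlas channels are zero fall back to the label of the nearest labelled
#' voxel. Voxels outside the lung and airway voxels are untouched.
#'
#' @param seg A [LabelMap-class] on the working grid.
#' @param lungMask Logical array on the same grid.
#' @param atlas A [ProbAtlas-class] already warped to the working grid.
#' @return A list: `labels` (filled [LabelMap-class]) and `provenance`
#'   (integer array: 1 network, 2 prior fill, 3 fallback, 0 background).
#' @export
fillFromAtlas <- function(seg, lungMask, atlas) {
  d <- dim(seg)
  if (!identical(dim(atlasProbs(atlas))[1:3], d) ||
      !identical(dim(lungMask), d))
    stop("seg, lungMask and atlas must share the same grid")
  lab <- seg@labels
  prov <- array(0L, dim = d)
  prov[lab != 0L] <- 1L
  gaps <- lungMask & lab == 0L
  if (any(gaps)) {
    p <- matrix(atlasProbs(atlas), ncol = 5)
    gi <- which(gaps)
    pg <- p[gi, , drop = FALSE]
    hasSupport <- rowSums(pg) > 0
    amax <- max.col(pg, ties.method = "first")
    lab[gi[hasSupport]] <- amax[hasSupport]
    prov[gi[hasSupport]] <- 2L
    if (any(!hasSupport)) {
      # fall back to nearest labelled voxel (lobes only as sources)
      src <- lab
      src[!(src %in% .LOBE_CODES)] <- 0L
      need <- array(FALSE, dim = d)
      need[gi[!hasSupport]] <- TRUE
      filled <- cpp_nearest_label_fill(src, d, need)
      lab[need] <- filled[which(need)]
      prov[need] <- 3L
    }
  }
  list(labels = labelMap(array(lab, dim = d), spacing = seg@spacing,
                         affine = seg@affine, classNames = seg@classNames),
       provenance = prov)
}

#' Persist a probabilistic atlas as a directory
#'
#' One NIfTI per lobe channel plus the reference image and a JSON metadata
#' sidecar, so an atlas can be rebuilt without any binary serialization.
#'
#' @param atlas A [ProbAtlas-class].
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
saveAtlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(atlasProbs(atlas))[1:3]
  aff <- atlasReference(atlas)@affine
  for (k in .LOBE_CODES)
    RNifti::writeNifti(.asNiftiWithAffine(atlasProbs(atlas)[, , , k], aff),
                       file.path(dir, sprintf("prob_lobe%d.nii.gz", k)))
  writeVolume(atlasReference(atlas), file.path(dir, "reference.nii.gz"))
  meta <- list(groupId = groupId(atlas), nMembers = nMembers(atlas),
               sigma = atlas@sigma,
               normalized = isNormalized(atlasReference(atlas)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
             file.path(dir, "atlas.json"))
  invisible(dir)
}

#' Read a persisted atlas directory
#'
#' @param dir Directory written by [saveAtlas()].
#' @return A [ProbAtlas-class].
#' @export
readAtlas <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "atlas.json"))
  ref <- readVolume(file.path(dir, "reference.nii.gz"),
                    normalized = isTRUE(meta$normalized))
  d <- dim(ref)
  probs <- array(0, dim = c(d, 5))
  for (k in .LOBE_CODES)
    probs[, , , k] <- intensities(readVolume(
      file.path(dir, sprintf("prob_lobe%d.nii.gz", k))))
  new("ProbAtlas", probs = probs, reference = ref,
      groupId = as.character(meta$groupId),
      nMembers = as.integer(meta$nMembers), sigma = as.numeric(meta$sigma))
}

#' Build per-group atlases from a cohort
#'
#' End-to-end atlas construction: the cohort's label maps (already on one
#' grid) are grouped with [groupByDice()]; within each group the medoid
#' member (highest mean Dice to the others) becomes the registration target,
#' every other member is registered to it, and the warped labels are fused
#' with [buildAtlas()].
#'
#' @param cohort List of `list(ct =, labels =)` pairs on a common grid.
#' @param threshold Grouping Dice cut.
#' @param sigma Atlas smoothing SD (voxels).
#' @param levels Registration schedule for member-to-medoid alignment.
#' @return `list(atlases = list of ProbAtlas, assignment = GroupAssignment)`.
#' @export
buildGroupAtlases <- function(cohort, threshold = 0.80, sigma = 1.0,
                              levels = c(100, 50, 25)) {
  ga <- groupByDice(lapply(cohort, `[[`, "labels"), threshold = threshold)
  atlases <- lapply(seq_along(groups(ga)), function(gidx) {
    idx <- groups(ga)[[gidx]]
    D <- diceMatrix(ga)[idx, idx, drop = FALSE]
    medoid <- idx[which.max(rowMeans(D))]
    ref <- cohort[[medoid]]$ct
    members <- lapply(idx, function(i) {
      if (i == medoid) return(cohort[[i]])
      tr <- registerDiffeomorphic(ref, cohort[[i]]$ct, levels = levels)
      list(ct = applyTransform(tr, cohort[[i]]$ct, "forward"),
           labels = applyTransform(tr, cohort[[i]]$labels, "forward"))
    })
    buildAtlas(members, sigma = sigma, reference = ref,
               groupId = sprintf("g%02d", gidx))
  })
  list(atlases = atlases, assignment = ga)
}
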