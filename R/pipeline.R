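#' Pipeline configuration
#'
#' All tunables of the inference and training workflows in one validated
#' list that round-trips through YAML unchanged. The full-scale defaults
#' mirror the method's working protocol (1 mm isotropic working space, HU
#' window \[-1024, 600\], stage sizes 128, patch overlap 0.5, registration
#' pyramid caps \[10000, 1000, 100\]); desk-scale runs override the sizes.
#'
#' @param targetMm Isotropic working resolution in mm.
#' @param huLo,huHi HU clipping window.
#' @param stage1Size Stage-1 processing size (cubic voxels).
#' @param patch Stage-2 patch size.
#' @param overlap Stage-2 patch overlap fraction.
#' @param regLevels Registration iteration caps, coarse to fine.
#' @param diceThreshold Atlas grouping cut.
#' @param atlasSigma Atlas smoothing SD (voxels).
#' @param bboxDilate Dilation (voxels) of the stage-1 lung bounding box that
#'   restricts stage-2 processing.
#' @param baseChannels,depth Network size.
#' @param seed Master seed; all stochastic steps derive their streams from it.
#' @param cacheDir Transform cache directory or `NULL` to disable caching.
#' @param outputDir Where outputs are written.
#' @param hp1,hp2 Stage-wise training hyperparameter overrides (see
#'   [trainStage()]).
#' @return A named list of class `lobeSegConfig`.
#' @export
pipelineConfig <- function(targetMm = 1.0, huLo = -1024, huHi = 600,
                           stage1Size = 128L, patch = 128L, overlap = 0.5,
                           regLevels = c(10000, 1000, 100),
                           diceThreshold = 0.80, atlasSigma = 1.0,
                           bboxDilate = 8L, baseChannels = 16L, depth = 3L,
                           seed = 1L, cacheDir = NULL, outputDir = ".",
                           hp1 = list(), hp2 = list()) {
  cfg <- list(targetMm = targetMm, huLo = huLo, huHi = huHi,
              stage1Size = as.integer(stage1Size), patch = as.integer(patch),
              overlap = overlap, regLevels = as.numeric(regLevels),
              diceThreshold = diceThreshold, atlasSigma = atlasSigma,
              bboxDilate = as.integer(bboxDilate),
              baseChannels = as.integer(baseChannels),
              depth = as.integer(depth), seed = as.integer(seed),
              cacheDir = cacheDir, outputDir = outputDir,
              hp1 = hp1, hp2 = hp2)
  if (cfg$targetMm <= 0) stop("targetMm must be positive")
  if (cfg$huLo >= cfg$huHi) stop("huLo must be below huHi")
  if (cfg$overlap < 0 || cfg$overlap >= 1) stop("overlap must be in [0,1)")
  class(cfg) <- "lobeSegConfig"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param cfg A [pipelineConfig()] object.
#' @param path YAML file path.
#' @return `path` / the configuration.
#' @export
writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

.preprocess <- function(ct, cfg) {
  vol <- if (is.character(ct)) readVolume(ct) else ct
  vol <- resampleIsotropic(vol, cfg$targetMm)
  if (!isNormalized(vol)) vol <- normalizeHU(vol, cfg$huLo, cfg$huHi)
  vol
}

# lung bounding box (dilated, aligned to the network's downsampling factor)
.lungBBox <- function(lungMask, dilate, mult) {
  d <- dim(lungMask)
  idx <- which(lungMask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  lo <- pmax(1L, apply(idx, 2, min) - dilate)
  hi <- pmin(d, apply(idx, 2, max) + dilate)
  len <- hi - lo + 1L
  len <- pmin(d, as.integer(ceiling(len / mult) * mult))
  # re-center the rounded box inside the volume
  lo <- pmax(1L, pmin(d - len + 1L, lo - (len - (hi - lo + 1L)) %/% 2L))
  list(lo = lo, hi = lo + len - 1L)
}

#' Run the full three-stage inference pipeline
#'
#' Preprocess (isotropic resampling + HU normalization), select and register
#' to the best-matching probabilistic atlas, run the stage-1 coarse network,
#' restrict to the dilated lung bounding box, refine with the stage-2
#' multi-decoder network (prior channels included), fuse and clean decoder
#' outputs, fill lung gaps from the atlas, and map back to native space.
#'
#' @param ct Input CT: a file path or a [CTVolume-class].
#' @param cfg A [pipelineConfig()].
#' @param model1,model2 Trained stage handles (from [runTraining()] or
#'   [trainStage()]).
#' @param atlases List of [ProbAtlas-class] objects.
#' @param outPath Optional output NIfTI path; when given, the segmentation
#'   and a JSON sidecar documenting the label codes are written there.
#' @param verbose Log per-stage timings to stderr.
#' @return The native-space [LabelMap-class] (invisibly if `outPath` given).
#' @export
runInference <- function(ct, cfg, model1, model2, atlases, outPath = NULL,
                         verbose = TRUE) {
  stamp <- function(msg, t0) if (verbose)
    message(sprintf("[lobeseg] %s (%.1fs)", msg,
                    as.numeric(Sys.time() - t0, units = "secs")))
  t0 <- Sys.time()
  native <- if (is.character(ct)) readVolume(ct) else ct
  vol <- .preprocess(native, cfg)
  stamp("preprocessing", t0)

  t0 <- Sys.time()
  sel <- selectAtlas(vol, atlases, levels = cfg$regLevels,
                     cacheDir = cfg$cacheDir)
  atlas <- sel$atlas
  working <- applyTransform(sel$transform, vol, "forward")
  stamp(sprintf("atlas selection (chose %s)", groupId(atlas)), t0)

  t0 <- Sys.time()
  coarse <- stage1Predict(model1, working, targetSize = cfg$stage1Size)
  stamp("stage 1 (coarse)", t0)

  d <- dim(working)
  coarseUp <- .resampleChannels(activations(coarse), d)
  lungCoarse <- array(coarseUp[, , , 6] > 0.5, dim = d)
  if (!any(lungCoarse)) {
    warning("no lung-like content detected; returning an all-background map")
    out <- labelMap(array(0L, dim = dim(native)), spacing = native@spacing,
                    affine = native@affine)
    if (!is.null(outPath)) return(invisible(.writeSeg(out, outPath)))
    return(out)
  }
  mult <- 2L^model2$cfg$depth
  bb <- .lungBBox(lungCoarse, cfg$bboxDilate, mult)
  sl <- lapply(1:3, function(a) bb$lo[a]:bb$hi[a])

  t0 <- Sys.time()
  ctCrop <- ctVolume(working@intensities[sl[[1]], sl[[2]], sl[[3]],
                                         drop = FALSE],
                     spacing = working@spacing, normalized = TRUE)
  priorCrop <- atlasProbs(atlas)[sl[[1]], sl[[2]], sl[[3]], , drop = FALSE]
  coarseCrop <- new("StagePrediction",
                    activations = coarseUp[sl[[1]], sl[[2]], sl[[3]], ,
                                           drop = FALSE],
                    stage = 1L, gridMeta = list(size = dim(ctCrop)))
  refined <- stage2Refine(model2, ctCrop, priorCrop, coarseCrop,
                          patch = cfg$patch, overlap = cfg$overlap)
  actFull <- array(0, dim = c(d, 7L))
  actFull[sl[[1]], sl[[2]], sl[[3]], ] <- activations(refined)
  pred <- new("StagePrediction", activations = actFull, stage = 2L,
              gridMeta = list(dim = d, spacing = working@spacing,
                              affine = working@affine))
  stamp("stage 2 (refinement)", t0)

  t0 <- Sys.time()
  fr <- fuseDecoders(pred)
  seg <- finalizeSegmentation(fr, atlas, sel$transform, native)
  stamp("stage 3 (post-processing)", t0)
  if (!is.null(outPath)) return(invisible(.writeSeg(seg, outPath)))
  seg
}

.writeSeg <- function(seg, outPath) {
  writeVolume(seg, outPath)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", outPath)
  writeLines(jsonlite::toJSON(as.list(lobeClassCodes), auto_unbox = TRUE),
             sidecar)
  outPath
}

#' Train both network stages from a manifest
#'
#' Builds (or reuses) per-group probabilistic atlases from the training
#' cohort, registers every case into its group's reference space, trains the
#' stage-1 coarse network on low-resolution volumes, generates frozen
#' stage-1 predictions, and trains the stage-2 refinement network on
#' 13-channel inputs. The train/validation split is at case level
#' (mutually exclusive IDs, 80/20 by default).
#'
#' @param manifest List of cases: `list(ct =, labels =)` with file paths or
#'   in-memory objects.
#' @param cfg A [pipelineConfig()].
#' @param atlases Optional pre-built atlases + assignment (as returned by
#'   [buildGroupAtlases()]); built from the manifest when `NULL`.
#' @param checkpointDir Optional directory for stage checkpoints (RDS) and
#'   the history JSON.
#' @param verbose Log progress.
#' @return `list(model1, model2, atlases, assignment, history1, history2,
#'   valIdx)`.
#' @export
runTraining <- function(manifest, cfg, atlases = NULL, checkpointDir = NULL,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message("[lobeseg] ", ...)
  cohort <- lapply(manifest, function(s) {
    ct <- .preprocess(s$ct, cfg)
    lab <- if (is.character(s$labels)) readLabelMap(s$labels) else s$labels
    list(ct = ct, labels = resampleLabelsTo(ct, lab))
  })
  if (is.null(atlases)) {
    say("building group atlases")
    atlases <- buildGroupAtlases(cohort, threshold = cfg$diceThreshold,
                                 sigma = cfg$atlasSigma,
                                 levels = cfg$regLevels)
  }
  ga <- atlases$assignment
  groupOf <- integer(length(cohort))
  for (gi in seq_along(groups(ga))) groupOf[groups(ga)[[gi]]] <- gi

  say("registering cases into group reference spaces")
  working <- lapply(seq_along(cohort), function(i) {
    atl <- atlases$atlases[[groupOf[i]]]
    ref <- atlasReference(atl)
    if (sameGrid(ref, cohort[[i]]$ct) &&
        isTRUE(all.equal(ref@intensities, cohort[[i]]$ct@intensities))) {
      ct <- cohort[[i]]$ct; lab <- cohort[[i]]$labels
    } else {
      tr <- registerDiffeomorphic(ref, cohort[[i]]$ct,
                                  levels = cfg$regLevels)
      ct <- applyTransform(tr, cohort[[i]]$ct, "forward")
      lab <- applyTransform(tr, cohort[[i]]$labels, "forward")
    }
    list(ct = ct, labels = lab, atlas = atlases$atlases[[groupOf[i]]])
  })

  n <- length(working)
  nVal <- max(1L, round(0.2 * n))
  valIdx <- seq.int(n - nVal + 1L, n)

  say("training stage 1")
  s1 <- .stage1Geometry(working, cfg)
  model1 <- buildAttUNet(netConfig(cfg$baseChannels, cfg$depth, 1L, 1L),
                         seed = cfg$seed)
  hp1 <- utils::modifyList(list(valIdx = valIdx, seed = cfg$seed + 1L),
                           cfg$hp1)
  r1 <- trainStage(model1, s1, hp1)

  say("generating stage-1 predictions / training stage 2")
  s2 <- lapply(working, function(w) {
    coarse <- stage1Predict(r1$model, w$ct, targetSize = cfg$stage1Size)
    d <- dim(w$ct)
    list(ct = w$ct, labels = w$labels,
         prior = atlasProbs(w$atlas),
         coarse = .resampleChannels(activations(coarse), d))
  })
  model2 <- buildAttUNet(netConfig(cfg$baseChannels, cfg$depth, 13L, 2L),
                         seed = cfg$seed + 2L)
  hp2 <- utils::modifyList(list(valIdx = valIdx, seed = cfg$seed + 3L),
                           cfg$hp2)
  r2 <- trainStage(model2, s2, hp2)

  out <- list(model1 = r1$model, model2 = r2$model, atlases = atlases$atlases,
              assignment = ga, history1 = r1$history, history2 = r2$history,
              valIdx = valIdx)
  if (!is.null(checkpointDir)) {
    dir.create(checkpointDir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(r1$model, file.path(checkpointDir, "stage1.rds"))
    saveRDS(r2$model, file.path(checkpointDir, "stage2.rds"))
    writeLines(jsonlite::toJSON(list(stage1 = r1$history,
                                     stage2 = r2$history),
                                dataframe = "columns", digits = NA),
               file.path(checkpointDir, "history.json"))
  }
  out
}

# resample working volumes/labels to the stage-1 grid
.stage1Geometry <- function(working, cfg) {
  lapply(working, function(w) {
    d <- dim(w$ct)
    ts <- as.integer(rep_len(cfg$stage1Size, 3L))
    sc <- d / ts
    M <- diag(4); diag(M)[1:3] <- sc; M[1:3, 4] <- (sc - 1) / 2
    ctArr <- array(cpp_resample_affine(as.double(w$ct@intensities), d, ts,
                                       M, FALSE, 0), dim = ts)
    labArr <- array(as.integer(
      cpp_resample_affine(as.double(w$labels@labels), d, ts, M, TRUE, 0)),
      dim = ts)
    list(ct = array(pmin(1, pmax(0, ctArr)), dim = ts), labels = labArr)
  })
}
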