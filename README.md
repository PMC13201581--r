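# LobeSeg

Prior-guided segmentation of the five pulmonary lobes on 3D chest CT.

Lobar fissures — the thin boundaries between the lobes — are routinely
incomplete or invisible on CT, and severe abnormalities (COVID-19
consolidations, tumours, collapse) can erase them entirely. Purely
appearance-driven networks then leave holes and mislabelled regions inside
the lung precisely where measurements are needed. LobeSeg implements a
multi-stage pipeline that couples deep segmentation with probabilistic
anatomical priors:

1. **Probabilistic atlases by label fusion.** Co-registered training label
   maps are grouped by anatomical similarity (connected components of the
   pairwise mean-lobe-Dice graph at a 0.80 cut). Per group *g*, the prior for
   lobe *k* is the voxel-wise label fraction
   P̃⁽ᵍ⁾ₖ(v) = (1/N_g) Σᵢ 𝕀(Yᵢ(v) = k), smoothed with a 3D Gaussian
   (σ = 1 voxel) and renormalized to Σₖ Pₖ(v) = 1 on supported voxels.
2. **Atlas selection by composite similarity.** A new scan is registered
   (center-of-mass init + multi-resolution diffeomorphic registration) to
   every group reference and scored with
   w·1/(1+MSE) + w·(NCC+1)/2 + w·MI (all w = 1); the argmax reference wins.
3. **Two-stage attention U-Net.** Stage 1 segments the whole volume coarsely
   at low resolution (lobes, whole lung, airway). Stage 2 refines with a
   shared encoder and seven per-structure decoders over a 13-channel input
   (CT + 5 prior channels + 7 stage-1 activations), sliding 128³ patches
   with overlap averaging. Trained with soft Dice loss and AdamW
   (lr 1e-4, weight decay 1e-5, decay 0.985), with synthetic lesion
   insertion as augmentation.
4. **Prior-guided post-processing.** Decoder outputs are fused
   (binarize at 0.5, argmax among candidates, whole-lung mask as background
   gate), cleaned by connected-component analysis, unlabeled lung voxels are
   filled with the atlas argmax lobe, and the result is mapped back to
   native space.

Everything — including a synthetic 3D lung phantom generator (five lobes,
fissures, branching airway, optional lesions), the registration engine, the
network with its own BLAS-backed forward/backward kernels, and
Dice / average-Hausdorff / volume-similarity metrics — is self-contained,
so the whole pipeline trains and runs at desk scale with no external data.
The intended users are medical-imaging researchers who need a transparent,
fully testable reference implementation of prior-guided lobe segmentation.

## Worked example

Build an atlas from a small synthetic cohort, damage one member's right
lower lobe, and repair it from the prior:

```r
library(LobeSeg)
cohort <- makeCohort(4, phantomSpec(shape = c(48, 48, 48), seed = 7),
                     variability = 1.5)
atlas <- buildAtlas(lapply(cohort, function(m) m[c("ct", "labels")]),
                    sigma = 1.0)
atlas
#> ProbAtlas 'g1' | grid 48x48x48 | 4 member(s) | sigma 1.00 voxels

lab <- labelArray(cohort[[1]]$labels)
cen <- round(colMeans(which(lab == 3, arr.ind = TRUE)))   # inside the RLL
hole <- lab
hole[(cen[1]-4):(cen[1]+4), (cen[2]-4):(cen[2]+4), (cen[3]-4):(cen[3]+4)] <- 0L
lung <- array(lab %in% 1:5, dim = dim(lab))
repaired <- fillFromAtlas(labelMap(hole), lung, atlas)$labels

rbind(unrepaired = evaluateSegmentation(labelMap(hole), cohort[[1]]$labels)$meanOverLobes,
      repaired   = evaluateSegmentation(repaired,       cohort[[1]]$labels)$meanOverLobes)
#>              dice    ahd    avs
#> unrepaired 0.9833 0.0477 0.9691
#> repaired   1.0000 0.0000 1.0000
```

The three numbers are the mean over the five lobes of the Dice overlap
(1 = perfect), the average Hausdorff surface distance in mm (0 = perfect),
and the absolute volume similarity (1 = identical volumes): carving a 9³
hole out of the right lower lobe costs 1.7 Dice points; the atlas fill
restores the segmentation exactly.

Full training and inference go through `runTraining()` / `runInference()`
(see the methods vignette in `vignettes/lobeseg-methods.Rmd`), or the thin
CLI at `inst/scripts/lobeseg` with subcommands
`phantom | build-atlas | train | predict | evaluate`.

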