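---
title: "Prior-guided lung lobe segmentation: models, parameters, and design notes"
author: "LobeSeg authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior-guided lung lobe segmentation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pulmonary lobes are separated by thin fissures that are frequently incomplete
or invisible on CT, and severe abnormalities (consolidations, nodules,
collapse) can obscure them entirely. A network trained only on appearance
then produces holes and mislabelled regions exactly where clinical users
need reliable output. LobeSeg couples a two-stage 3D attention U-Net with
probabilistic anatomical priors built by label fusion, so that low-confidence
regions inside the lung can be resolved from expected lobar position rather
than left unlabeled.

## The probabilistic prior

Given a set of co-registered label maps, members are grouped by anatomical
similarity: pairwise mean-over-five-lobes Dice is computed and the partition
is the set of connected components of the graph linking pairs with Dice at or
above 0.80. The supplementary clustering rule of the original description is
not public; connected components at the stated cut is the simplest rule
consistent with it, and the threshold is a configurable argument. Whether
the pairwise score should be lobe-averaged or whole-lung is likewise not
stated; we use the lobe-averaged form because grouping exists to capture
*lobar* geometry, and whole-lung Dice is insensitive to fissure position.

For each group \(g\) with \(N_g\) members, the pre-smoothing probability of
lobe \(k\) at voxel \(v\) is the label fraction

\[\tilde P^{(g)}_k(v) = \frac{1}{N_g}\sum_{i=1}^{N_g}
\mathbb I\!\left(Y_i(v)=k\right),\]

each channel is convolved with an isotropic 3D Gaussian (\(\sigma = 1.0\)
voxel, i.e. 1 mm in the 1 mm isotropic working space; the source states the
value without units), and channels are renormalized to satisfy
\(\sum_k P^{(g)}_k(v) = 1\) wherever the pre-smoothing channel sum is
positive. Outside any lobe support all channels stay zero rather than being
renormalized — renormalizing a zero vector is undefined, and a uniform
1/5 prior far outside the lungs would actively mislead the fill step.

Each group's registration target is its **medoid** (the member with the
highest mean Dice to the rest). The source never names the per-group
reference; the medoid is the canonical choice that minimizes expected
registration distance.

At inference the input is registered to every group reference and scored with

\[w_{\mathrm{MSE}}\frac{1}{1+\mathrm{MSE}}
 + w_{\mathrm{NCC}}\frac{\mathrm{NCC}+1}{2}
 + w_{\mathrm{MI}}\,\mathrm{MI},\qquad w_\cdot = 1,\]

where MI uses a 32-bin joint histogram with natural logarithms (the estimator
is not specified in the source; 32 bins on [0,1] intensities is the common
default and is configurable). The highest-scoring reference wins; ties break
to the lowest group id.

## Registration

Alignment is center-of-mass initialization followed by a multi-resolution
diffeomorphic solver. The original pipeline calls an external symmetric
diffeomorphic (SyN) implementation; no equivalent exists in this package's
dependency set, so LobeSeg ships its own demons-style solver: at each pyramid
level the moving image is warped, an intensity-difference force with the
classic demons normalization \(\delta = (F - M\circ\varphi)\,\nabla
/(|\nabla|^2 + (F - M\circ\varphi)^2)\) is computed, smoothed with a fluid
Gaussian (SD 1.0 voxel), accumulated, and the accumulated field smoothed with
an elastic Gaussian (SD 1.5 voxels). The registration contract — not the
solver brand — is what downstream stages rely on: improvement of mutual
information over the rigid initialization (asserted at run time), label
warping without class invention, and forward/inverse composition within a
voxel. The inverse field comes from fixed-point iteration (20 sweeps), which
on smooth fields leaves a mean composition residual far below one voxel.

The per-level iteration caps default to [10000, 1000, 100] coarse-to-fine,
matching the full-scale protocol; a relative-MSE convergence test (tolerance
1e-5, three stalled iterations) stops levels early, and desk-scale runs pass
reduced schedules such as [100, 50, 25]. Registration is fully deterministic:
there is no stochastic sampling anywhere in the solver.

Computed transforms can be cached on disk keyed by an MD5 hash of both image
contents, the schedule, and the engine version, so repeated runs on the same
input skip registration entirely; a corrupt cache entry is treated as a miss.

## The two-stage network

**Stage 1** processes the whole working volume at low resolution (128³ at
full scale) through an attention U-Net and produces coarse masks for the
five lobes, the whole lung, and the airway. The source describes a softmax
head over outputs that include both the lobes and the whole lung — which
cannot share one softmax, since the lung is a superset of the lobes. LobeSeg
therefore uses a 6-class softmax (background + 5 lobes) plus two independent
sigmoid auxiliary channels (whole lung, airway); this is flagged as an open
interpretation rather than a faithful copy.

**Stage 2** refines at high resolution with a shared encoder and seven
independent decoders (one per structure), each ending in its own sigmoid.
Its input has 13 channels: the CT, the 5 atlas probability channels (soft
guidance, not a hard constraint — inference with the prior channels zeroed
still runs and produces valid activations), and the 7 stage-1 activations,
passed as continuous maps and upsampled trilinearly (binarization would
discard calibrated confidence). Processing is patch-based (128³ patches at
full scale) with a sliding window; overlapping patch predictions are
averaged (overlap 0.5 by default — unstated in the source; mean stitching
is the field's default). The stage-2 working grid is restricted to the
stage-1 lung bounding box dilated by 8 voxels and rounded up to the
network's downsampling multiple.

Blocks are 3×3×3 convolution → instance normalization → ReLU, twice per
level, with 2× average pooling, nearest-neighbour upsampling, and a spatial
attention gate per decoder level (a learned sigmoid heatmap from a 1×1×1
bottleneck on the concatenated gating and skip features, multiplied onto the
skip). Instance normalization is not mentioned in the source's architecture
sketch but is standard in 3D medical U-Nets; without it, convergence within
a desk-scale step budget is unattainable, and with it the optimizer is
stable across two orders of magnitude of learning rate. The whole network
(forward, backward, AdamW) is implemented in the package with BLAS-backed
convolution kernels; gradients are verified against finite differences in
the test suite.

Training minimizes the soft Dice loss \(1 - \frac{1}{S}\sum_s
\mathrm{Dice}_s\) (smooth term \(\varepsilon = 10^{-5}\)); stage 1 averages
over the 6 softmax classes plus the two auxiliary channels, stage 2 over the
seven decoders. The full-scale defaults follow the published protocol:
AdamW, initial learning rate 1e-4, weight decay 1e-5, exponential decay
0.985 per epoch, best-validation-loss checkpointing, 80/20 train/validation
split at case level.

## Lesion insertion and augmentation

Training-time augmentation inserts lesions from a bank of pre-registered
`(intensities, mask)` entries into the pulmonary area of a target image:
lesion intensities are rescaled to the mean/SD of the surrounding lung
tissue (computed over the lung minus the lesion footprint; airway excluded),
then blended through a Gaussian-blurred soft mask (SD 2 voxels — the source
says only "soft edges") that is zeroed outside the lung, so no voxel outside
the blur support changes and nothing is painted outside the lung. Because
inserted values must stay in [0, 1], a plain affine moment match followed by
clipping would systematically shrink the delivered spread whenever the
matched distribution's tail crosses zero; the implementation therefore
iterates the affine so that the *clipped* values carry the target mean and
SD (clip-aware moment matching), which is what "normalized to match the
surrounding lung tissue" is for. The
insertion probability per draw is 0.5 (unstated in the source). The full
augmentation chain per draw is: lesion insertion, scaling (0.9–1.1),
rotation about the axial axis (±10°), per-axis mirroring, Gaussian noise
(SD ≤ 0.02), Gaussian blur, brightness/contrast (±0.1 / 0.9–1.1), random
crop. The source names these transform families and the crop size but no
ranges; the defaults above are conventional magnitudes that keep labels
valid, and lesion insertion runs first so lesions undergo the same
geometric transforms as the anatomy.

## Post-processing

Each decoder output is binarized at 0.5. For the whole-lung decoder, a
single largest connected component would delete one lung wherever the left
and right lungs are disjoint (which is the normal case), so the lung mask
keeps every 26-connected component whose size is at least 20% of the
largest — both lungs survive, spurious islands do not. The lung mask acts
as a background indicator: activations outside it are disregarded.
Connectivity is 26-neighbourhood throughout (unstated in the source; the
most permissive standard choice). Inside the lung, each
voxel takes the candidate structure with the highest activation (ties to the
lowest channel index — deterministic). After per-structure largest-component
cleanup, lung voxels with no label form the gap set and are filled with the
atlas argmax lobe; voxels where the atlas has no support fall back to the
nearest labelled voxel by breadth-first search. The prior has no airway
channel, so airway is never prior-filled — gaps become lobes only. Finally
the working-space result is mapped back through the inverse displacement
field (nearest-neighbour) and resampled onto the native grid.

## The phantom generator

Every test and the acceptance script run on synthetic lung phantoms: two
ellipsoidal lungs (the right split into three lobes, the left into two, by
tilted planar fissure surfaces with seeded angular jitter), a
three-generation branching airway tube, thin brighter fissure sheets, and
optional spherical lesions placed strictly inside the lobes with separation
constraints so the requested lesion count equals the connected-component
count. Intensities are authored in Hounsfield units — parenchyma at
−900…−700 HU with a distinct base value per lobe, fissures at −300 HU,
airway lumen at −1000 HU, lesions at −50 HU, background soft tissue at
0 HU — plus Gaussian acquisition noise (SD 0.01 in normalized units), and
passed through the package's own HU window ([−1024, 600] → [0, 1]), so the
fixed preprocessing path is exercised realistically. Cohorts share one base
geometry and differ by smooth Gaussian-filtered random displacement fields
(RMS 1.5 voxels by default, which yields pairwise lobe Dice ≈ 0.85–0.9,
comfortably above the 0.8 grouping cut, emulating an anatomically coherent
group).

What the phantom does *not* emulate: vessel trees, incomplete or absent
fissures, real lesion texture, respiratory deformation patterns, scanner
artifacts, or anisotropic acquisition. Passing tests therefore demonstrate
that the pipeline's machinery — registration, fusion arithmetic, network
optimization, gap filling, geometry bookkeeping — is correct, not that the
trained desk-scale model transfers to clinical CT.

## Desk-scale study conditions

The self-contained end-to-end experiment used by the tests and the
acceptance script trains a tiny two-stage model (base 4 channels, depth 2)
on 8 phantoms of 48³ voxels with 2 held out, 20 epochs with two passes per
epoch, learning rate 1e-2 with the 0.985 decay, stage-2 training on random
32³ crops, and registration schedules of [80, 40, 20]. The learning rate is
deliberately larger than the full-scale 1e-4 default: a four-channel network
taking a few hundred optimizer steps sits in a different regime from a
full-scale model taking tens of thousands, and 1e-4 does not leave the
initialization basin within the step budget. Problem sizes (48³, 32³
patches, tiny channel counts) were chosen as the smallest configuration in
which every pipeline stage still does nontrivial work: downsampling depth 2
keeps a 12³ bottleneck, and 48³ keeps the five lobes several voxels thick
after deformation.

## Numerical choices and degenerate inputs

- Intensity interpolation is trilinear everywhere; labels are always
  nearest-neighbour. Resampled shapes are physical-extent/target rounded
  half away from zero, so geometry tests are exact.
- Voxel indices are 0-based against NIfTI world affines. Internal arrays
  keep the native NIfTI (i, j, k) order end to end; one convention
  everywhere removes a whole class of axis bugs, and geometry travels in
  affines rather than axis permutations.
- Empty-vs-empty Dice is 1.0 by convention; average Hausdorff distance on an
  empty mask is an error (undefined, not zero). Boundary voxels for AHD are
  mask voxels with a 6-neighbour outside the mask; distances are between
  voxel centers in mm. Volume similarity is clipped at zero so it stays in
  [0, 1].
- Volumes with no lung-like content complete the pipeline and return an
  all-background map with a warning rather than failing.
- A lesion bank entry that lands entirely outside the target lung returns
  the target unchanged with a warning.

## Known limitations

- The demons-style solver is not symmetric in the fixed/moving roles and is
  validated on smooth phantom deformations; severely sliding or large
  rotational misalignments would need the full SyN machinery.
- The network implementation is CPU-only and double-precision; it is built
  for correctness and desk-scale problems, not for training at clinical
  resolution.
- Severity stratification uses the phantom's known lesion fraction; no
  automatic involvement estimation is included.
- Airway segmentation is carried as an auxiliary task and is not evaluated
  as an output of interest.
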