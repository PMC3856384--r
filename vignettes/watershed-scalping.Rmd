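---
title: "Brain extraction with the watershed transform from markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain extraction with the watershed transform from markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wscalp)
```

## The segmentation model

Skull stripping in `wscalp` is cast as a two-region flooding problem.  A
*control surface* -- a scalar image whose ridges should coincide with the
wanted boundary -- is flooded simultaneously from two labelled seed
regions, a *brain marker* (label 1) and a *background marker* (label 2).
Flooding is greedy: a global queue ordered by control value (ties broken
first-in-first-out) grows each region voxel by voxel until every voxel is
claimed, and each final region is guaranteed to contain its marker.  This
is the watershed transform from markers.  It has no stopping conditions,
data-dependent thresholds or iteration counts; all of the anatomical
knowledge lives in how the markers and the control surface are built.

Two passes are made.  **Stage 1** uses the inverted T1 (`max(R0) - R0`) as
the control: the dark bone and CSF between brain and scalp become a bright
ridge separating the two floods.  The stage-1 mask is deliberately
conservative -- it should contain every brain voxel at the cost of
including CSF, some bone and, when present, bright cancellous bone
(marrow).  **Stage 2** re-floods a second control surface built from the
intensity-clipped image and its smoothed morphological gradient, using
refined markers placed within a thin border zone of the stage-1 boundary:
a core brain marker (bright voxels at least 10 mm inside the boundary),
dark markers (voxels under 60 % of the masked local mean brightness, the
CSF/dura signature) and bright markers (marrow candidates above 1.25 x the
core median, in the superior vault).  The final mask is the stage-2 brain
region, re-dilated 1 mm to undo the grayscale erosion used during marker
construction, with bright-marker voxels removed.

The marker-correctness requirement is asymmetric and strict: the brain
marker must lie entirely inside the brain and the background marker
entirely outside.  Everything between the markers is negotiated by the
flood, so a marker on the wrong side of the boundary is the one failure
mode the pipeline cannot recover from.  The aggressive large-kernel
morphology (10-30 mm spheres and boxes) exists to buy that safety margin.

## Watershed semantics and numerical choices

* **Flavour.** The flood produces touching regions with no watershed-line
  voxels.  A one-voxel separating line would pierce the brain mask, which
  downstream consumers treat as a solid object, so the no-line variant is
  the only sensible choice here even though both variants are classical.
* **Connectivity and ties.** 6-connectivity (faces) everywhere --
  components, flooding, gradients.  Queue priority is the voxel's own
  control value; within equal priority the queue is FIFO, which makes
  plateau splitting deterministic and repeated runs bit-identical.
  Because every push of a voxel carries the same priority, the first push
  always wins the tie; the implementation exploits this to queue each
  voxel exactly once.
* **Minima imposition.** `impose_minima()` implements the classical
  topology transformation (marker voxels forced below the global minimum,
  then reconstruction by conditional erosion).  It exists as a reference:
  the test-suite checks that flooding the imposed surface reproduces
  `watershed_markers()` exactly on continuous random controls.  On
  plateaued controls the two routes may legitimately split plateaus
  differently, so the cross-check draws continuous values where ties have
  probability zero.
* **Binary morphology** uses metric balls realised by thresholding the
  exact Euclidean distance transform, so a "10 mm erosion" means 10 mm on
  anisotropic grids too.  Boundary handling is the adjoint pair (outside
  counts as background for dilation, foreground for erosion), which makes
  the duality `dilate(m) == !erode(!m)` exact and openings/closings
  idempotent -- without the adjoint convention the stage-1 smoothing
  compositions would not be filters and repeated smoothing would keep
  shrinking masks at the image border.
* **Otsu thresholds** use 128 bins over the region's value range.  The bin
  count is a reproducibility decision, not a sensitivity: the threshold is
  affine-covariant up to one bin, which in turn bounds how far a global
  intensity rescaling can move any pipeline mask.
* **Quantiles** are nearest-rank (the `ceil(qn)`-th order statistic), so a
  "median" is always an observed value, never an interpolation.
* **Component volume filters** drop a component exactly when
  `voxels x voxel volume < cutoff`.
* **Stage-2 border image.** The border term of the control is clipped at
  zero after the median subtraction: only the bright excess over the
  typical boundary intensity should raise the control, dark boundary
  voxels are already handled by the gradient term.
* **The masked gradient** computes unit dilation/erosion treating
  out-of-mask voxels as absent, so the stage-1 mask border itself does not
  masquerade as an edge.

## Parameters

All sizes are physical (mm / mm^3) and independent of voxel spacing;
lengths convert to voxels by rounding half up with a one-voxel floor.  The
defaults of `human_params()` are the design values of the method: the
40 mm seed box placed 50 mm below the crown anchor `COM_top`, the
`[median, 1.25 x median]` brain-marker band, 10/30 mm background
morphology, 5/6 mm erosion/dilation (the 6 mm dilation intentionally
overshoots so the background marker overlaps the scalp), the 10 mm border
zone, 60 % dark fraction, 3.3 mm bright border zone, 90 mm superior-zone
offset, 10 mm^3 marker-component cutoff and 5/6.5 mm smoothing radii.
`macaque_params()` swaps filter-scale knowledge for geometry: an 80 mm
neck crop, a 70 x 90 x 65 mm blanked box and a 10 x 10 x 15 mm seed box
around a point 35 mm below `COM_top`, 1 %/25 % quantile thresholds on an
8 mm-closed image for dark structures (eyes), a 100 mm^3 component cutoff
with 3 mm dilation, and a 5 mm stage-2 erosion.  Two knobs deserve
comment because they are operational rather than anatomical:
`bg_dilate_mm` should be reduced for open-skull (intra-surgical) scans so
the background marker cannot reach exposed brain, and `crop_extent_mm`
can be reduced for paediatric cohorts.

Bias correction is optional for humans and recommended for macaques.  It
divides by a low-spatial-frequency field estimated as a 30 mm-radius box
mean.  The field is estimated over a rough Otsu head mask with
out-of-mask voxels ignored, and the output is rescaled by the in-mask
field mean: estimating the field from the whole image would drag it
toward zero in air and amplify background noise to tissue level right
where the neck-crop threshold needs contrast.  Voxels whose window sees
no head tissue are left unchanged.  This is deliberately crude -- a
smoothness prior, not a tissue model -- and is not a replacement for
model-based correction when quantitative intensities matter.

## The synthetic phantom: what it does and does not show

No public manual ground truth ships with the package, so the test bed is a
parametric head phantom with voxel-exact truth.  The human default is a
1 mm isotropic 150 x 170 x 200 grid: nested ellipsoidal shells (scalp 8 mm,
cortical bone 6 mm, CSF gap 3 mm) around a brain with a gray rim, a white
core, a thalamus-like deep-gray block, a ventricular CSF inclusion, a
brain-stem extension through the skull base, and a neck long enough
(head span > 180 mm) that the neck-crop path genuinely blanks slices.
Tissue intensities follow T1 ordering (marrow/fat brightest, then white,
scalp, deep gray, gray, muscle, CSF, bone, air); noise is additive
Gaussian at 2 % of white matter.  Three anatomical choices matter for the
tests and were made once, on anatomical grounds:

* the deep-gray block makes the seed-box median fall between gray and
  white, as it does in real heads -- with a pure-white box the
  `[median, 1.25 median]` band would bisect the white-matter noise
  distribution and the opened marker would vanish;
* the brain stem extends the mask inferiorly, so the 90 mm superior-zone
  reference (the inferior face of the eroded stage-1 bounding box) lands
  mid-head as in real anatomy;
* marrow patches open through the *inner* skull table (adjacent to CSF)
  while keeping an outer cortical shell, the configuration in which thick
  cancellous bone really is swallowed by stage 1 -- patches bridging the
  full skull would instead be claimed early by the background flood
  through the scalp.

The macaque phantom (0.8 mm grid) adds temporal-muscle bulk, a shoulder
block, a face block carrying two 10 mm-radius eye globes darker than the
air-noise floor, and supports a strong multiplicative bias field (the
acceptance condition uses amplitude 0.5, i.e. the field spans 0.5-1.5).
The eye intensity sits below air because the 25 % dark quantile of the
closed image lies inside the air distribution whenever air dominates the
field of view; darker-than-air eyes are detected through the
below-background branch robustly.

Passing the phantom suite therefore demonstrates the geometric and
morphological logic of the pipeline -- marker safety, conservativeness of
stage 1, boundary refinement by stage 2, marrow removal, bias robustness
-- under controlled conditions.  It does not demonstrate performance on
real tissue: the phantom has no cortical folding, no partial-volume
mixture at boundaries, no dura, Gaussian rather than Rician noise, and
piecewise-constant classes.  Quantities like a phantom Dice of 0.97 are
internal regression anchors, not claims about clinical data.

## Problem sizes and expected scores

The regression conditions are fixed: ten human phantom seeds at the
default spec and five macaque seeds at bias amplitude 0.5 with correction
enabled.  On these, stage 1 keeps sensitivity at or above 0.99 (it is
designed never to clip brain), the smoothed stage-2 mask reaches Dice at
or above 0.95 against truth (typically ~0.976; the residual error is a
~1 voxel under-segmentation of the outermost gray rim plus the smoothing
round-off), and the macaque stage-2 Dice stays at or above 0.93 (typically
0.96-0.998).  At the default 2 % noise the human output mask is in fact
voxel-identical across noise realisations -- the flood's boundary margins
dwarf the noise -- so the seeds exercise noise robustness plus whatever
the seed drives geometrically (marrow placement, the random bias field);
they are not independent accuracy samples.  On the bright-marrow variant the stage-2 false-positive
volume must undercut stage 1's -- that comparison, not the absolute Dice,
is what the bright-marker machinery exists for.  A full human run on the
default grid takes roughly half a minute on one core; the suite sizes
were chosen so the complete check runs comfortably on a laptop.

## Known limitations

* The mask intentionally includes the brain stem and internal CSF;
  applications needing a stem cut or CSF exclusion must post-process.
* Marker generation assumes a closed skull; for open-skull scans reduce
  `bg_dilate_mm` and expect extra non-brain tissue in the result.
* Very severe bias (field far outside 0.5-1.5x) can defeat the rough
  correction, and stage-1 inferior boundaries degrade first.
* The phantom suite is a necessary, not sufficient, validation -- see
  above.

## Session info

```{r}
sessionInfo()
```
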