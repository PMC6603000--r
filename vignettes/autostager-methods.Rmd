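---
title: "Staging autophagy from dual-channel reporter stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging autophagy from dual-channel reporter stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(autostager)
```

## The measurement problem

Tandem pH-sensor reporters fuse a pH-stable red fluorophore (DsRed) to a
pH-quenchable green one (pHluorin). A vesicle carrying the reporter is bright
in both channels while it is non-acidic (phagophore, autophagosome) and loses
its green signal as it fuses with lysosomes and acidifies (autolysosome).
Imaged at high content — 3D confocal fields of dense cultures, two channels,
five z-planes at 400 nm spacing, 0.2152 µm/pixel — this color logic lets an
automated pipeline count vesicles per maturation stage without segmenting
single cells. `autostager` implements that pipeline end to end: vesicle
segmentation in both channels, hollow-vesicle (autophagosome) detection by
ring topology and circle Hough transforms, a progressive-exclusion decision
tree into four stages, a mitochondrial workflow for mitophagy events, a
lysotracker workflow for lysosome sizing, and a synthetic-field simulator
that provides voxel-level ground truth for all of it.

## Pipeline overview

Each field is flatfield-corrected (optional), then each channel is restored by
Richardson–Lucy deconvolution (10 iterations) with a parametric
Gaussian-approximation PSF (lateral FWHM $0.51\lambda/\mathrm{NA}$, axial FWHM
$1.77\,n\lambda/\mathrm{NA}^2$; emission 520/600/690 nm for
green/red/lysotracker, NA 1.2, water immersion). The PSF is only an initial
estimate for a threshold-based pipeline, which is why a scalar model suffices;
an optional blind mode alternates PSF updates but the fixed-PSF path is the
tested default because blind updates are not bit-reproducible across BLAS
builds.

All convolution and morphology filters operate plane-by-plane with square
kernels (the stacks are thin and strongly anisotropic: 5–11 planes at 400 nm
versus 0.2152 µm laterally); connected components and volume statistics are
3D with 26-connectivity (8-connectivity in 2D). Graytones are on the 16-bit
camera scale and all printed thresholds are interpreted on that scale.

Red-channel vesicles: a difference of Gaussians (kernels 20 px with sd 1 and
7) thresholded at 400 catches small vesicles; a top-hat (disc radius 25)
thresholded at 1200 adds larger ones, with large top-hat components (> 500
voxels, > 10% overlap) replaced by their DoG intersection to preserve splits.
Their union is re-split by growing its component labels outward
(Euclidean-style watershed with ridge exclusion) and confirmed against a
second DoG (11/1 vs 25/6, threshold 1000, size 200–2000); the final red mask
is the union of the seed mask and the confirmed stencil. Green-channel
vesicles combine a large-vesicle DoG (100/1 vs 100/5, threshold 1000) with
Laplacian-of-Gaussian edges (size 20, sd 1, below −2000), dropping components
under 10 voxels. A ratio image (green/red, both blurred with a 5/2 Gaussian,
denominator clamped at 1 graytone) complements and top-hat filters into an
autolysosome rescue mask: ratio-dark vesicles larger than 100 voxels whose
green neighbourhood (disc-7 dilation ring) is at least 50% brighter than the
vesicle.

Autophagosomes are hollow: their rings are isolated by a per-plane Butterworth
high-pass ($H(D) = 1/(1+(D_0/D)^{2n})$, $D_0 = 10$, $n = 5$, exact zero at DC
and gain 1/2 at the cutoff) of the green DoG, thresholded at 150,
max-projected, cleaned, and filtered by 2D Euler number: a connected component
with Euler number 0 contains exactly one hole. A proportion filter
(filled/area > 1.01 and filled − area > 20 px) rejects spurious rings, holes
are recovered from the mask inverse (components under 10,000 px),
reconstructed into filled bodies, opened (disc 5), and restored to 3D on the
planes where the thresholded volume saw them. A gradient-voting circle Hough
transform (radii 3–30 px) on the raw green channel recovers remaining rings,
validated per circle by interior texture (median absolute deviation > 20) and
red darkness (0.9-quantile < 300). Candidates must measure 50–10,000 voxels
with two sphericity indices above 1 and 1.5.

All detections are pooled (26-connected), excluding the autophagosome-mask
perimeter so ring splits survive; components with mean raw red ≤ 300 or
touching the lateral field border are dropped. The decision tree then assigns
exactly one stage per vesicle, in order: autophagosome (overlaps the
autophagosome mask, not the >0.9-eccentricity mask), phagophore (three
alternative cases: dual-mask overlap ≥ 25% with median ratio > 2 and no
rescue-mask overlap; green/red third quartiles above 7500/4000; green center
≥ 1.25× its surface), late autolysosome (red overlap ≥ 25% with green overlap
< 10% or median ratio ≤ 2; or green center below surface), early autolysosome
(red overlap ≥ 25% with green overlap ≤ 25%, or any rescue-mask overlap).
Vesicles failing every rule are kept as `unclassified` rather than silently
dropped. Per field, the autophagic-vacuole count is the sum of autophagosomes
and both autolysosome classes, and the autophagy rate-constant is
phagophores / autophagic vacuoles — read from the phrase order "ratio between
phagophores and autophagic-vacuoles"; the orientation is an interpretive
choice and is flagged here.

The mitochondrial workflow segments the network with a narrow DoG (50/1 vs
50/2, threshold 12), seeds mitophagy events from 26-connected mask components
with mean ratio below 0.6, and refines them by binary reconstruction within a
red DoG limit (50/1 vs 50/5, above 50). The lysotracker workflow mirrors the
green segmentation (DoG 100/1 vs 100/5 above 2000, LoG 20/1 below −2000,
10-voxel minimum) and reports each projected component's major axis from the
normalized-second-central-moments ellipse.

## Parameters that matter

All stage parameters live in one nested list, `pipeline_config()`, frozen in
`inst/extdata/paper_defaults.yaml` (a test fails on any drift) and
overridable per run. The most consequential:

* **Filter kernels and thresholds** (per stage, graytone units as above) —
  these define the published workflow and are not meant to be tuned per
  dataset.
* `ratio$eps` (1 graytone) — clamps the ratio denominator in empty
  background.
* `autophagosome$hough$sensitivity` (0.25) — accepted fraction of a circle's
  circumference that must vote; the only free parameter of the Hough stage.
* `classification$mean_red_min` (300) and the pooled 10-voxel minimum —
  gates on what counts as a vesicle at all.
* PSF wavelengths/NA and deconvolution iterations (10).

## Interpretation choices on ambiguous points

Several printed rules admit more than one reading; the package fixes them as
follows (each isolated behind one function so it can be revised):

* *Proportion filter orientation*: "ratio between area and filled area larger
  than 1.01" is computed as filled/area — the only orientation that can
  exceed 1.01, since filled ≥ area.
* *Late-autolysosome case 1*: parsed as red overlap ≥ 25% AND (green overlap
  < 10% OR median ratio ≤ 2), keeping late autolysosomes red-positive.
* *Sphericity indices*: the published formulas are not available in the
  source text. Index 1 is a projected circularity, $1.2 \cdot 4\pi A / P^2$
  (scaled so an ideal rendered sphere scores ≈ 1.2): with 5-plane anisotropic
  stacks, a 3D surface-to-volume measure is unstable for spheres truncated by
  the stack, which is why the projection is used. Index 2 is the mean
  deconvolved green inside the component over its 1-voxel outer shell — a
  border-to-surroundings contrast. Both live in `sphericity_indices()`.
* *"26 connected components"* in the mitophagy text is read as 26-connectivity
  labelling, extended to all 3D labelling for consistency.
* *Center vs surface*: center is the component eroded by the radius-1 3D
  ball, surface is the eroded-away shell; both fall back to the whole
  component when the erosion is empty, making the comparisons neutral for
  1–2-plane components.
* *Quantiles*: "3rd quantile" is the 75th percentile of raw voxel
  intensities; "median ratio" is the median ratio-image voxel within the
  vesicle; MAD is the unscaled median absolute deviation.
* *Perimeter exclusion at pooling*: carved as the boundary plus a 1-pixel
  outer margin; a single-voxel cut leaks under 26-connectivity through
  diagonal hops and fragments detection fringes into spurious speck
  vesicles. Pooled components under 10 voxels are dropped, mirroring the
  minimum-component rule the green mask already applies.
* *Watershed stencil*: region labels are grown geodesically within the
  confirmative DoG2 mask (the only place they are consumed); an unseeded
  DoG2 component is therefore not rescued into the final red mask.
* *Borders*: convolution uses reflective padding; thresholds printed as
  ">v" are strict; size windows are inclusive; components touching the
  border survive until the single border exclusion at pooling.

## The synthetic test bed

No imaging data is deposited with the workflow, so the package ships a
generator (`render_scene()`, `render_suite()`) that emulates the
acquisitions: 256×256 fields, 5 planes (cytosolic reporter) or 11 planes
(mitochondrial reporter and lysotracker), 0.2152 µm/pixel, 400 nm z-steps,
16-bit graytones, channel-specific PSF blur, quadratic vignetting, Poisson
shot noise and Gaussian read noise (sd 10). Objects are placed by rejection
sampling (touching allowed after repeated failures, with both ground-truth
labels kept). Class signatures follow the reporter logic:

* phagophores — solid spheres (r 2.5–4 px), green 9000 / red 4000 over a
  100-graytone background;
* autophagosomes — hollow shells (r 6.9–8.5 px, rim 1.6 px) with the same
  rim intensities, imaged at their equator so the 2 µm stack cuts the caps
  (as with any vesicle larger than the stack). Shells below r ≈ 6.6 px close
  their projected lumen under the PSF and fail the ring filter's own
  hole-size rule — the generator renders the size regime the topology route
  is designed for, and that size selectivity is a property of the method,
  not of the simulator;
* late autolysosomes — solid red-only bodies (red 6000, green at
  background);
* early autolysosomes — the transient class. They are rendered as the
  acidifying intermediate the rescue mask targets: a ratio-dark vesicle
  sitting in a locally quenched pocket of green cytoplasm, with mild
  residual luminal green (center ≈ 1.1–1.2× its shell — partial quenching)
  and a soft, diffuse red mound that passes the 300-graytone red gate
  without forming a red-mask vesicle. This is the signature that the
  published tree routes to "early": any vesicle with strong red-mask overlap
  and quenched green is, by the printed predicates, a late autolysosome;
* diffuse cytoplasm patches give the rescue mask its bright-green
  neighbourhoods;
* mitochondria — dual-positive random-walk tubules; mitophagy events —
  red-retaining, green-quenched detached bodies. Mitochondrial fields use a
  dim-intensity regime (background 12, tubules 200, events 300 graytones):
  the published mitochondrial DoG threshold of 12 graytones presumes low
  signal levels, and at vesicle-field intensities shot noise floods that
  narrow band.

The basal battery renders 20 phagophores, 5 autophagosomes, 5 early and 39
late autolysosomes per field — phagophore- and late-dominated with transient
intermediates at low frequency, and a phagophore:vacuole ratio of ≈ 0.41,
matching the described basal state. "Chloroquine-like" fields shift mass to
phagophores and autophagosomes (40/14/6/12); "CCCP-like" fields are
mitochondrial (22 tubules, 8 events vs 3 at basal).

What passing on this test bed does and does not show: the simulator has no
cell boundaries, no organelle texture, no photobleaching, no chromatic
misregistration, and its intensity classes are cleanly separated. Recovering
the rendered class counts therefore validates the *logic and numerics* of
the pipeline — filters, topology, decision tree, summaries — under realistic
optics and shot noise, not the biological discriminability of stages in any
particular cell line.

## Numerical choices

Even kernel sizes are rounded up to the next odd integer so kernels have a
center; convolution pads reflectively; FFT work (Butterworth, deconvolution)
pads to 5-smooth lengths for speed. Richardson–Lucy runs on the reflectively
padded volume, conserving interior flux to within a few percent. Grayscale
morphology is routed through an affine rescale to [0, 1] (EBImage clamps
outside that range; min/max morphology commutes with affine maps). The
radius-1 "disc" is the 5-pixel cross, and the radius-1 3D ball is the
6-neighbourhood, in line with the usual disk-structuring-element convention.
Labelling wraps per-plane 4-connected labelling with a union-find merge to
the declared 8/26-connectivity. Ties: "at least 50% brighter" counts
equality as brighter; size windows are inclusive; the empty-vacuole field
reports rate 0 with a defined-ness flag. Problem sizes in the validation
suite (10 fields of 256×256×5 or ×11 per battery, 6+3+8+2 fields in the
acceptance script) were chosen as the smallest batteries in which all four
classes appear at meaningful frequencies.

## Known limitations

The Hough route rarely contributes on the synthetic battery: its red-darkness
validation (0.9-quantile < 300) targets red-negative rings, which the
red-gate at pooling then mostly removes; ring detection is carried by the
Euler route. Tubule splitting by the narrow mitochondrial DoG band is
expected behaviour (component counts are therefore validated as recall of
rendered components, not raw counts). The watershed split is a
chessboard-metric approximation of the Euclidean transform. Sphericity
formulas are package interpretations, as stated above. The generator
renders early autolysosomes by one specific optical model of partial
quenching; real intermediates are certainly more heterogeneous.
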