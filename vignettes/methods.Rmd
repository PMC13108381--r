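---
title: "Models and methods in SpliceVasc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in SpliceVasc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpliceVasc)
```

SpliceVasc quantifies cell-type-specific alternative splicing of the
latrophilin adhesion-GPCR family and the cerebrovascular readouts that
depend on it. This vignette explains the models behind each stage, the
tunable parameters and their defaults, what the synthetic generators
emulate (and what they deliberately do not), and the numerical choices
and limitations a careful user should know about.

## The junction-read model behind EIP

A transcript that includes a cassette exon carries **two** splice
junctions flanking the exon; a transcript that skips it carries
**one** exclusion junction. If a fraction $\psi$ of transcripts
include the exon, a junction-spanning read is an inclusion read with
probability $2\psi/(1+\psi)$. The exon inclusion proportion

$$\mathrm{EIP} = \frac{I}{I + 2E}$$

doubles $E$ precisely to undo this 2:1 junction multiplicity, which
makes the estimator unbiased for $\psi$ by construction:
substituting $\hat p = I/(I+E)$ gives
$\mathrm{EIP} = \hat p/(2-\hat p)$, whose expectation is $\psi$ under
the read model. `simulateJunctionReads()` implements exactly this
generative inverse, so estimator recovery can be tested against an
analytic truth: the delta-method standard error of the pooled
estimator is
$\mathrm{SE} = \frac{2}{(2-\hat p)^2}\sqrt{\hat p(1-\hat p)/N}$
(`pooledEIPSE()`), and recovery suites assert agreement within three
SEs.

For mutually exclusive splice-site variants $a$ and $b$ of one exon
(events like "23a"/"23b" that share the exclusion junction),
$\mathrm{EIP}_a = I_a/(I_a+I_b+E)$, which structurally enforces
$\mathrm{EIP}_a + \mathrm{EIP}_b \le 1$, with equality when no
exclusion reads are seen.

**Aggregation.** Per-cell EIPs are averaged within a subclass by
default (`mode = "mean"`), matching an analysis that computes EIP for
each cell. A pooled mode sums gated reads first and applies the
formula once; it weights cells by depth, has the clean read-count SE
above, and is the mode used in recovery tests. Nothing in the
per-subclass summaries forces one choice, so both are exposed.

**Gates.** A (cell, event) pair is analyzable when inclusion *or*
exclusion reads exceed $1$ on the $\log_2(\mathrm{CPM}+1)$ scale
(strict inequality: a read level landing exactly at 1 fails), with CPM
computed against the cell's total mapped reads. The CPM denominator
for junction reads is configurable because junction-level CPM is not
uniquely defined; total mapped reads is the default. Subclasses enter
summaries only above 100 cells (again strict).

## Tau

For per-gene mean expression $x_i$ over $n$ subclasses,
$y_i = x_i/\max_i x_i$ and $\tau = \sum_i(1-y_i)/(n-1)$. Tau is
scale-free (invariant to multiplying a profile by any positive
constant) and bounded in $[0,1]$; both properties are fuzz-tested.
All-zero profiles leave $\tau$ undefined and are flagged rather than
forced to 0, since the formula divides by the profile maximum. Tau is
computed on plain subclass means by default; a 25–75% trimmed-mean
variant is available via `subclassMeans(..., trimmed = TRUE)` for
robustness to outlier cells, since either convention is defensible.

## Cell quality control

Two per-cell metrics — genes detected (≥ 1 read) and total mapped
reads — are screened by an **unscaled** median absolute deviation: no
1.4826 normality factor, because the rule is a plain "k MADs below the
median" cut, not a normal-theory z-score. With a degenerate MAD of 0
the threshold equals the median and only strictly-below cells are
rejected; the multiplier `k` (default 3) is exposed. Rejection is
monotone in `k` by construction.

## Expression simulation and its calibration

`simulateExpressionMatrix()` draws negative-binomial counts
(variance $\mu + \phi\mu^2$, $\phi = 0$ giving Poisson) against
log-normal library sizes (median 5×10⁵ reads, CV 0.2 — Smart-seq
scale). Because $\log_2(\mathrm{CPM}+1)$ is concave, naively inverting
the target mean would bias the realized mean log-expression downward;
the generator applies an iterated second-order delta correction so the
per-subclass mean log expression recovers the requested profile within
sampling error. The simulated matrix contains only the genes of
interest, and the library size is attached as the per-cell total (the
CPM denominator), the same convention as quantifying a gene panel
against aligner-reported totals.

What the generator does **not** emulate: dropout beyond NB sampling,
batch effects, gene–gene correlation, ambient RNA. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated model, not robustness to every artifact of real single-cell
data.

## Vessel morphometry

The 2D pipeline follows the classic enhancement–segmentation–skeleton
sequence:

1. **Preprocess** — median filter (radius 2 px) then CLAHE (clip 3,
   8×8 tiles), rescaled to [0,1]. Constant images pass through
   unchanged.
2. **Frangi vesselness** — scale-normalized Hessian eigenvalues at
   scales {1, 1.5, 2, 3} µm (σ in image units), blobness β = 0.5,
   structure constant c = half the maximum Hessian norm per scale,
   responses maximized over scales. The scale set should span half the
   expected vessel widths; defaults cover 2–8 µm vessels.
3. **Adaptive Gaussian threshold** — pixel is vessel when it exceeds
   the Gaussian-weighted local mean (σ = block/6, block 65 px) by more
   than `offset`. Offset is a strictness: a blank image yields an
   empty mask for any positive offset.
4. **Width refinement** — components whose maximum inscribed width
   (2 × the largest distance-transform value) is below 2 µm are
   removed. A width criterion, not an area one, so thin debris goes
   while genuine capillaries stay; monotone in the threshold.
5. **Skeleton metrics** — Zhang–Suen thinning; length as 8-connected
   chain length (diagonal steps √2, diagonals short-cut by an
   orthogonal bridge not double-counted); branch pixels are skeleton
   pixels with ≥ 3 neighbours, consolidated by repeated single-linkage
   merging at 10 µm with centroid replacement, processed in
   lexicographic order so results are independent of input ordering.

**Why the pipeline thresholds twice.** The Frangi ridge of a tube is
systematically wider than the tube, so thresholding the vesselness map
alone overestimates vessel area by ~25% on clean renders.
`vesselPipeline()` therefore uses the vesselness threshold only to
*detect* vessels and the same adaptive threshold on the preprocessed
intensity to *delineate* them, keeping intensity components touched by
a detection (morphological reconstruction). On noiseless renders this
recovers VAF within ~2% relative and mean diameter within ~0.1 µm; the
isolated operations remain available and individually tested.

Mean diameter is the standard skeleton-EDT estimator (2 × Euclidean
distance transform sampled on skeleton pixels): unbiased on straight
tubes, slightly low near free tube ends. ROI polygons clip the mask
before VAF and the skeleton before length/branch metrics, with
centre-in-polygon rasterization.

## 3D puncta and surfaces

Spot detection smooths with an anisotropic Gaussian matched to the
expected diameters (σ = diameter/2.355, i.e. FWHM = diameter; defaults
0.6/0.6/1.2 µm), estimates background with a 3× wider Gaussian,
subtracts, and keeps local maxima above a **required** quality
threshold (there is no sensible universal default; it depends on
signal amplitude and noise). Sub-voxel centres come from per-axis
quadratic interpolation; ties between equal maxima break
lexicographically, so plateaus produce exactly one spot.

Proximity uses an exact anisotropic Euclidean distance transform
(separable lower-envelope algorithm), sampled at the punctum's voxel;
puncta inside the surface have distance 0. Classification against the
1 µm cutoff is guaranteed exact only for puncta whose true distance
differs from the cutoff by more than one voxel diagonal — the
discretization limit of any voxel-domain distance.

Surface area counts exposed voxel faces weighted by their physical
dimensions: exact for axis-aligned shapes (a 10 µm cube reports
600 µm² exactly), but a staircase overestimate for smooth curved
surfaces — up to 4/π (~27%) on a cylinder's lateral surface. This bias
is deterministic and cancels in the coverage ratio, which divides two
face-counted areas; absolute densities per µm² inherit it and should
be compared only against like-computed values. A mesh-based estimator
would remove the bias at the cost of determinism and simplicity and is
out of scope.

Coverage operationalizes "colocalized surface area" as the area of
surface A within a contact radius (default: one voxel diagonal) of
surface B — a necessary stand-in for proprietary surface–surface
colocalization tolerances, and configurable for sensitivity analysis.

## Fluorometry

Unweighted ordinary least squares for the standard curve (readings
are homoskedastic at plate-reader scale), inversion with extrapolation
flags outside the fitted concentration range, and mass normalization
as concentration × total extract volume ÷ tissue mass — the
normalization order is explicit because protocols describe volumes
without a worked formula. The brain/blood permeability ratio is
invariant to rescaling all readings (with refit), which is tested.

## Synthetic geometry generators

`renderVesselImage()` rasterizes tube segments with a one-pixel
anti-aliased edge at 0.5 µm/px by default (20× confocal sampling),
optional additive Gaussian noise and a low-frequency illumination
gradient; the returned truth (length, length-weighted mean width,
hub coordinates where ≥ 3 segment endpoints meet, mask area fraction)
is derived analytically from the segments. `renderContactVolume()`
builds a cylinder along x (radius 4 µm default) in a
0.25/0.25/0.5 µm voxel grid (confocal-like z anisotropy) and places
Gaussian puncta at requested signed distances from the tube surface,
spread in azimuth to stay separated. One global seed drives every
generator through independent derived streams, so each stage can be
regenerated in isolation and all outputs are bit-reproducible.

Problem sizes used throughout the test and acceptance suites — 200
cells per subclass at mean junction depth 50, 400×400 px images,
96×64×48 voxel volumes — are chosen to keep estimator standard errors
well inside the stated tolerances while each suite runs in seconds.

## Known limitations

- Junction counting uses unique reads only; multi-mapping junction
  reads are ignored.
- The EIP read model assumes junction reads sample transcripts
  uniformly; length or positional biases are not modeled.
- Skeleton length slightly undershoots true centreline length at free
  tube ends (thinning erodes roughly half a width per free end).
- Voxel-domain proximity cannot resolve distances finer than the voxel
  diagonal; choose voxel sizes accordingly.
- PCA requires a complete subclass × event matrix; gate or subset
  events first. Component signs are fixed by forcing each component's
  largest-magnitude loading positive.
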