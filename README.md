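# SpliceVasc

Quantitative toolkit for studying how brain cell types use alternative
splicing to specialize shared genes — built around the latrophilin
family of adhesion GPCRs (*Adgrl1-3*), whose *Adgrl2* member is
expressed both by neurons and by brain endothelial cells, as different
splice isoforms — and for quantifying the cerebrovascular phenotypes
that follow from manipulating that program: vessel morphology,
synaptic-puncta contacts onto vessels, and blood–brain-barrier tracer
permeability.

The package is aimed at labs analyzing Smart-seq-style single-cell
RNA-seq (splice-junction counts from STAR alongside gene counts) and
confocal imaging of the vasculature, and at anyone who wants a fully
synthetic, ground-truth-driven testbed for these analyses.

## What it computes

**Exon inclusion proportion (EIP).** For a cassette exon with
inclusion-junction reads $I$ and exclusion-junction reads $E$ in one
cell,

$$\mathrm{EIP} = \frac{I}{I + 2E},$$

the factor 2 balancing the two inclusion junctions contributed by each
including transcript against the single skipping junction. For
mutually exclusive splice-site variants $a,b$ of one exon,
$\mathrm{EIP}_a = I_a/(I_a + I_b + E)$, so variant EIPs can never sum
above 1. Cells pass a detection gate of $>1\ \log_2(\mathrm{CPM}+1)$
on inclusion or exclusion reads, and subclasses contribute only above
100 cells.

**Tau specificity index.** For a gene with mean $\log_2(\mathrm{CPM}+1)$
expression $x_i$ over $n$ cell subclasses and $y_i = x_i/\max_i x_i$,

$$\tau = \frac{\sum_i (1 - y_i)}{n - 1},$$

0 for uniform expression, 1 for expression confined to one subclass.

**Cell QC.** Cells more than $k$ (default 3) unscaled median absolute
deviations below the median in genes detected or mapped reads are
rejected.

**Vessel morphometry.** Median filter + CLAHE preprocessing, multiscale
Frangi vesselness, local adaptive Gaussian thresholding, removal of
components thinner than 2 µm, Zhang–Suen skeletonization, branch-point
consolidation at 10 µm, then vessel area fraction (VAF, %), mean
diameter (2 × distance transform on the skeleton) and branch density
per 100 µm of vessel.

**3D contact scoring.** Gaussian-matched spot detection
(0.6/0.6/1.2 µm expected diameters), proximity classification within
1 µm of a surface (anisotropic exact distance transform),
exposed-face surface area, and surface–surface coverage
(% of one surface within a contact radius of another).

**Fluorometry.** Linear sodium-fluorescein standard curves, reading
inversion with extrapolation flags, and mass-normalized brain-to-blood
permeability ratios.

Every analysis stage has a synthetic-data generator with known ground
truth (`simulateJunctionReads`, `simulateExpressionMatrix`,
`renderVesselImage`, `renderContactVolume`,
`generateStandardCurveData`), so the whole pipeline is testable
without any external download.

## Worked example

```r
library(SpliceVasc)

## tau on a hand profile: (4,2,2) across three subclasses
computeTau(c(4, 2, 2))$tau
#> [1] 0.5

## simulate junction reads at psi = 0.5 and recover it
truth <- SplicingTruth(matrix(0.5, 1, 1), cellsPerSubclass = 200,
                       meanDepth = 50, seed = 11)
sim <- simulateJunctionReads(truth)
ag  <- aggregateBySubclass(sim$junctions, minCells = 100, mode = "pooled")
eipValues(ag)
#>                   sub1
#> gene1.event1 0.5026667

## coding impact of the packaged Adgrl2 mini-exon
exonCodingImpact(adgrlExonSequences())["Adgrl2_exon9", ]
#>               length divisibleBy3 aminoAcids
#> Adgrl2_exon9      12         TRUE          4

## vessel morphometry on a rendered 4 um x 100 um tube
r <- renderVesselImage(VesselGroundTruth(
  data.frame(x0 = 50, y0 = 100, x1 = 150, y1 = 100, width = 4),
  imageSize = c(200, 200), pixelSize = 0.5))
vesselPipeline(r$image)$metrics
#> VesselMetrics: VAF 1.03%, mean diameter 4.00 um, 0 branches / 100 um (length 97.5 um)
```

The EIP lands within three standard errors of the simulated inclusion
probability; the tube's VAF matches the analytic 1.03% of the frame
and its diameter the 4 µm ground truth.

## Layout

- `R/` — S4 classes (`CellCounts`, `JunctionCounts`, `EIPMatrix`,
  `VesselImage`/`VesselMask`/`VesselSkeleton`, `Volume3D`, `SpotSet`,
  `SurfaceMask3D`, `StandardCurve`) and the analysis functions.
- `inst/extdata/adgrl_exons.fa` — alternatively spliced latrophilin
  exon sequences used by the coding-impact arithmetic.
- `vignettes/methods.Rmd` — models, parameter choices and limitations.
- `tests/testthat/` — unit, property and end-to-end recovery suites.
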