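---
title: "Quantifying hemocyte immune assays: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hemocyte immune assays: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoquant)
```

## Background

When a parasitoid wasp oviposits into a host insect, venom proteins injected
alongside the egg suppress the host's cellular immunity. The standard
laboratory readouts of that suppression are all quantitative:

* **bead encapsulation** — chromatography beads incubated with hemolymph are
  wrapped by hemocyte capsules; the extent of wrapping is graded and
  summarized as an *encapsulation index*;
* **hemocyte spreading** — the fraction of plasmatocytes and granulocytes
  that attach and extend lamellipodia or filopodia;
* **phagocytosis** — the fraction of hemocytes that have engulfed at least
  one labelled bacterium;
* **F-actin content** — bound-phalloidin fluorescence of the hemocyte
  cytoskeleton relative to a blank;
* **docking post-processing** — candidate venom-protein ligands ranked by
  best-pose binding energy and the derived inhibition constant.

`hemoquant` implements these measurements as a reusable, testable pipeline,
together with seeded synthetic-data generators that render beads and
hemocyte fields with exact ground truth. Every downstream stage is
therefore validated end to end without any external data.

## The encapsulation index

For each bead, two quantities are measured:

* the **coverage fraction** $A = \theta/360$, where $\theta$ is the total
  number of degrees of the bead circumference covered by capsule material;
* the **thickness ratio** $T = (\sqrt{\mathrm{Area}/\pi} - R)/R$, where
  $\mathrm{Area}$ is the total bead-plus-capsule footprint and $R$ the bead
  radius, i.e. the excess of the footprint's equivalent-circle radius over
  the bead radius, in bead radii.

$A$ is binned into five grades (0–4, bin width 0.25) and $T$ into seven
grades (0–6: width 0.2 up to 1.0, then a single 1.0–2.0 bin). The index of
a cohort is

$$\mathrm{index} = \sum_g P_T(g)\, g + \sum_g P_A(g)\, g,$$

with $P$ the fraction of beads at each grade, so the index lies in
$[0, 10]$ and equals the per-bead mean of (area grade + thickness grade) —
an identity the test suite checks on a thousand random grade tables. The
*encapsulation rate* is reported as the fraction of beads with any capsule
(area grade $\ge 1$); this quantity is often referred to alongside the
index but rarely given a formula, so the definition here is an explicit,
documented interpretation.

Three conventions required a decision, each taken once and fixed:

* **Bin edges.** The published grade boundaries share endpoints
  (0–0.25, 0.25–0.5, ...). We reserve grade 0 for exactly zero (no
  capsule) and make the remaining bins lower-exclusive/upper-inclusive, so
  $A = 0.25$ is grade 1 and $A = 0.26$ is grade 2. This keeps "no
  encapsulation" a separate category and removes all ambiguity at shared
  endpoints.
* **Area in the $T$ formula.** $\mathrm{Area}$ is taken as the *total*
  bead-plus-capsule footprint: if it were capsule-only, a bare bead would
  give $T = -1$ rather than 0. $T$ is additionally floored at 0 so
  segmentation jitter cannot produce negative thickness.
* **Clamping.** $T > 2$ (beyond the last published bin) clamps to grade 6,
  preserving the index bound of 10.

## Image measurement

Images are numeric matrices with intensities in $[0,1]$, indexed
(row, col) with 1-based pixel-centre coordinates; angles are degrees
counter-clockwise from +x. The synthetic renderer places each structure in
its own intensity band (background 0.05, capsule 0.45, cell body 0.70,
bead/nucleus 0.90, bacteria 1.00), and the default thresholds in
`assay_config()` sit between bands. On real micrographs the same
thresholds apply after rescaling, but they are configuration, not
constants.

* `segment_bead()` thresholds at the bead band, keeps the largest
  connected component and fits the equivalent circle. Because the bead
  band is brighter than the capsule band, a full annulus does not inflate
  the fitted radius.
* `measure_coverage_angle()` scans the circle at 1° resolution: a degree
  is covered when capsule-band pixels lie beyond the bead radius in that
  sector, with sector membership decided by pixel-centre angle. Two
  numerical details matter: isolated capsule-classified pixels (no
  8-neighbour) are discarded first, so a lone noise pixel cannot mark a
  stray degree; and single-degree gaps flanked by covered degrees are
  closed, because next to the image axes a thin annulus can skip one
  1-degree sector purely through pixel quantization. Capsules thinner than
  about 3 px still undercount coverage by a few degrees — at the default
  40 px bead radius that corresponds to thickness ratios below about 0.08,
  thinner than a single hemocyte layer.
* `measure_total_area()` counts pixels above the capsule band's lower
  threshold times the pixel area. With 5% Gaussian noise the expected
  number of misclassified background pixels per image is ~1, negligible
  against the $\ge 5000$-pixel footprints.
* Cell segmentation (`extract_cell_features()`) uses nuclei as seeds and
  partitions the cell-body mask among them (Voronoi-style propagation from
  EBImage), so touching cells with distinct nuclei are split. Circularity
  is $4\pi A / P^2$ with the perimeter taken from the smoothed object
  contour plus a $\pi$ offset correction (the boundary runs half a pixel
  outside boundary-pixel centres; a closed curve offset by $h$ gains
  $2\pi h$). This keeps disk circularity within $1 \pm 0.05$ for radii
  $\ge 8$ px, where a raw pixel-edge perimeter would bias it above 1.3.
* Spreading classification: a cell is spread when circularity
  $< c_0 = 0.6$ or when it shows at least $d_0 = 3$ pseudopod arms
  (contiguous contour runs beyond 1.15× the median centroid distance).
  The historical literature criteria for spreading are morphological
  descriptions, not formulas, so these thresholds are explicit
  configuration (`assay_config(circularity_max =, defects_min =)`),
  calibrated once against the synthetic renderer: rendered disks score
  circularity 1.00–1.05 with 0 arms, rendered stars 0.2–0.45 with 4–6
  arms, so the defaults sit far from both populations.
* Engulfment: bright spots in the bacteria channel are connected
  components above `spot_threshold`; each spot is assigned to the cell
  whose mask contains its centroid (2D containment — the counting rule of
  fluorescence microscopy, with no internalization test).

## The synthetic generators

The generators emulate the study conditions of the assays: cohorts of 10
beads per replicate with 5 replicates per treatment; fields of several
hundred hemocytes (500 per treatment for spreading, 400–600 for
phagocytosis); four biological replicates of fluorometer readings; ten
docking conformers per ligand. Their defaults encode those designs, and
the acceptance checks run at exactly these sizes.

Choices a real assay does not pin down, fixed here once: beads default to
a 40 px radius (an 80 μm bead at 1 μm/px — mid-range for <150 μm beads);
capsules are concentric annular arcs (real capsules are irregular; keeping
them analytic keeps the area oracles exact); round cells are disks of
radius 8–12 px and spread cells are 4–6-armed stars of base radius
10–14 px with arm amplitude 0.55; engulfed counts per phagocytic cell are
$1 + \mathrm{Poisson}(\mu - 1)$, so every phagocytic cell carries at least
one bacterium; noise is additive Gaussian, clipped to $[0,1]$. Bacteria
spots are placed fully inside the silhouette and ≥4 px apart; on the rare
occasion a drawn count cannot be placed without merging, the record
reports the rendered count, keeping ground truth exact. All generators are
pure functions of (parameters, seed): the RNG state is scoped to the call.

What the generators do *not* emulate — point-spread blur, uneven
illumination, overlapping or partially detached cells, capsule boundary
irregularity, melanization — bounds what the validation shows: passing
tests demonstrate the measurement logic is correct, not that segmentation
is robust to every real-world artefact.

## Docking post-processing

Per ligand the lowest-energy conformer is selected (ties to the lowest
conformer id) and converted to an inhibition constant with the Boltzmann
relation used by standard docking engines,

$$K_i = \exp\!\left(\frac{\Delta G}{RT}\right),\qquad
R = 1.98720\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}},\ T = 298.15\ \mathrm{K},$$

and ligands are ranked by ascending $\Delta G$ (equivalently ascending
$K_i$). On the seven-fatty-acid screen shipped in
`inst/extdata/fatty_acid_docking_energies.csv`, this relation reproduces
the published inhibition constants from the published energies: exactly at
printed precision for palmitic acid (0.43 μM) and within 1% for five of
the remaining six ligands. Linolenic acid deviates by 5.2% against the
printed value directly; the printed energies are rounded to two decimals,
and across that rounding interval the implied $K_i$ band comes within
4.4% of the printed value, which is the check the test suite applies for
that one ligand. (Back-solving the printed 0.72 μM gives
$\Delta G \approx -8.38$, so the original constant was evidently computed
from an unrounded energy.)

## Statistics

`one_way_anova()` is the classical between/within sum-of-squares
decomposition with the p-value from the F distribution and all pairwise
contrasts assessed by Tukey's HSD via studentized-range quantiles
(Tukey–Kramer standard errors for unequal $n$). Levene's statistic
(mean-centred) is reported alongside as a homogeneity check but never
gates the ANOVA — reporting, not silent branching. `chi_square_2x2()` is
the Pearson statistic without continuity correction by default: the assay
comparisons involve thousands of cells, where Yates' correction is
negligible; a flag enables it. Degenerate inputs (zero within-group
variance with unequal means) are flagged explicitly and reported with a
below-machine-minimum p-value rather than an error.

The tests verify both implementations against brute-force oracles to
1e-10, against R's `aov()`, `TukeyHSD()` and `chisq.test()` as independent
references, and against a 2000-replicate null simulation holding the
type-I error rate in [0.04, 0.06] at $\alpha = 0.05$. One published df
structure is worth noting: a 3×5 design gives df (2, 12), which the
package reproduces; published 24 h comparisons show df (2, 21), implying
eight replicates per group there — the package always takes df from the
data it is given.

## Problem sizes and validation scope

The validation suite runs cohorts of 10 beads × 5 replicates at 5% noise
(index recovered within 0.5 of truth; coverage within 2° and thickness
within 0.05 per bead on noiseless renders), 500-cell fields at spread
fractions 0.60 and 0.30 (recovered percentages within the 99% binomial
confidence half-width of truth), and a 400-cell field at phagocytic
fraction 0.5. These sizes match the published assay designs. Published
*index values* (for example 6.4 vs 4.1 between control and venom-treated
cohorts) are not reproducible from first principles because the underlying
micrographs are not public; the suite instead verifies that synthetic
cohorts with weak and strong encapsulation bracket that range through the
full image pipeline.

## Known limitations

* Cell typing (plasmatocyte vs granulocyte) on synthetic data comes from
  ground truth; on real images the distinction is genuinely hard (treated
  cells round up and lose distinguishing morphology), and no high-
  confidence classifier is attempted.
* Engulfment is scored by 2D containment; a bacterium adhered on top of a
  cell is indistinguishable from an internalized one.
* Coverage measurement saturates at the 1° resolution of the grading
  scheme; sub-degree capsule gaps are invisible.
* The renderer's intensity bands make thresholding nearly trivial;
  threshold sensitivity on real micrographs must be assessed per dataset
  via `assay_config()`.
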