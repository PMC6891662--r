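# hemoquant

Quantification of the cellular immune assays used to study parasitoid
venom immunosuppression in insect hosts. When venom proteins disable host
hemocytes, the effect is read out through a handful of standard
measurements: how completely hemocytes encapsulate test beads, what
fraction of them spread on glass, what fraction engulf labelled bacteria,
how much polymerized F-actin they retain, and — on the venom side — which
ligands a candidate venom protein binds most tightly in a docking screen.
`hemoquant` implements these measurements as a tested R pipeline, with
seeded synthetic-data generators that render beads and hemocyte fields
with exact ground truth so every stage is validated end to end.

## The core quantities

**Encapsulation.** Per bead, the capsule's angular coverage fraction
*A* = θ/360 (five grades 0–4) and thickness ratio
*T* = (√(Area/π) − R)/R (seven grades 0–6), where Area is the total
bead-plus-capsule footprint and R the bead radius. Per cohort,

    index = Σ_g P_T(g)·g + Σ_g P_A(g)·g   ∈ [0, 10]

with *P* the fraction of beads at each grade, plus an encapsulation rate
(fraction of beads with any capsule).

**Cell assays.** Spreading percentage = 100 × spread plasmatocytes and
granulocytes / all plasmatocytes and granulocytes; phagocytosis
percentage = 100 × cells with ≥ 1 engulfed bacterium / all cells;
relative F-actin fluorescence = sample intensity / blank intensity.

**Docking.** Best conformer per ligand (lowest binding energy ΔG), then
K_i = exp(ΔG/RT) at T = 298.15 K, with ligands ranked by ascending ΔG.

**Statistics.** One-way ANOVA with Tukey HSD and Pearson chi-square on
2×2 counts, implemented from the sum-of-squares / observed–expected
decompositions and verified against brute-force oracles and base R.

## Worked example

Score a synthetic bead cohort with known ground truth:

```r
library(hemoquant)

coh <- generate_bead_cohort(10,
  coverage_dist  = list(dist = "uniform", min = 120, max = 360),
  thickness_dist = list(dist = "uniform", min = 0.3, max = 1.2),
  seed = 42, noise_sd = 0.05)
res <- analyze_bead_cohort(coh)
res$summary
#> Bead cohort summary (10 beads)
#>   encapsulation index: 7.4 (0-10)
#>   encapsulation rate:  1
#>   P(area grade 0-4):   0 0 0.1 0.2 0.7
#>   P(thick grade 0-6):  0 0.1 0 0.3 0.3 0.2 0.1
```

The index 7.4 is the mean per-bead sum of area grade and thickness grade;
here it equals the ground-truth index computed analytically from the
generator parameters (`bead_truth_measurement()`), so the image pipeline
recovered every grade. A spreading assay on a 200-cell field:

```r
f <- generate_hemocyte_field(field_truth(n_cells = 200,
                                         spread_fraction = 0.6,
                                         noise_sd = 0.05, seed = 7))
feat <- extract_cell_features(f$dic_channel, f$nuclei_channel)
cl <- classify_spread(feat$records)
spreading_percentage(cl)
#> [1] 56
# realized ground-truth spread fraction in this field: 56.0%
```

and the treatment comparison a spreading assay feeds into:

```r
chi_square_2x2(matrix(c(312, 188, 152, 348), 2))
#> Pearson chi-square: chi2(1) = 102.9, p = 3.466e-24
```

Ranking a docking screen from a pose table:

```r
poses <- read_assay_table(system.file("extdata",
  "fatty_acid_docking_energies.csv", package = "hemoquant"), "poses")
rank_ligands(poses)[, c("ligand", "best_energy", "ki_uM", "rank")]
#>             ligand best_energy      ki_uM rank
#> 1    Palmitic acid       -8.69  0.4267486    1
#> 2   Linolenic acid       -8.35  0.7575205    2
#> 3 Arachidonic acid       -8.06  1.2358516    3
#> 4     Ferulic acid       -6.47 18.0903482    4
#> 5      p-Coumarate       -6.41 20.0183061    5
#> 6     Caffeic acid       -6.40 20.3590445    6
#> 7    Linoleic acid       -6.37 21.4164553    7
```

Smaller K_i means tighter binding: palmitic and linolenic acid are the
top-affinity ligands of this screen.

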