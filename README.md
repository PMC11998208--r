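# airwayclust

Morphology-based clustering of monopodial airway trees, and per-compartment
two-group morphometry.

## The problem

The lungs of most laboratory species (mice, rats, rabbits) branch
**monopodially**: one long central airway per lobe with small lateral
daughters, unlike the near-dichotomous human tree. On such trees the usual
branching-based labels fail to delimit morphologically homogeneous
compartments — a *generation* mixes the huge trunk with tiny laterals and its
count explodes with trunk length; *orders* behave similarly; *Strahler
orders* compress the tree but still lump the tapering trunk with small
airways. Yet a two-group disease study (for example a hyperoxia model of
bronchopulmonary dysplasia vs normoxic controls) needs exactly such
compartments, because pathology often hits large and small airways
differently and a single global comparison averages those differences away.

`airwayclust` clusters airway segments **by morphology instead of by
branching position**: a Gaussian mixture model on each segment's lumen
diameter and wall thickness (µm), fit once on the pooled segments of all
animals, with the number of clusters $k$ and the covariance family chosen by
the Bayesian information criterion

$$\mathrm{BIC} = 2\log L - m\,\ln n \quad (\text{higher is better}),$$

scanned over $k = 1,\dots,9$ and five families up to fully free component
covariances ("ellipsoids of variable volume, shape and orientation").
Clusters are relabeled CL1…CLk by descending mean lumen diameter, so CL1 is
always the large central airway cluster. The mixture partition is
benchmarked against generations, orders and Strahler orders with the
Davies–Bouldin and Dunn cluster-validity indices, and treatment groups are
compared globally and per cluster with the Mann–Whitney U test, the
rank-based effect size $r = |Z|/\sqrt{N}$ and Cohen's benchmarks.

Because per-segment airway datasets of this kind are not publicly deposited,
the package includes a seeded generator of synthetic monopodial cohorts with
known cluster archetypes and known treatment effects, used by the entire
validation suite. It is intended for morphometrists and image-analysis
methodologists working on rodent/lagomorph airway (or vessel) trees.

## Worked example

```r
library(airwayclust)

gen <- generate_cohort(synthetic_config(seed = 1))   # 2 NOX + 2 HYX trees
gen$cohort
#> Airway cohort: 4 trees, 1484 segments
#>   group NOX: 2 trees, 778 segments
#>   group HYX: 2 trees, 706 segments

fit <- airway_gmm(gen$cohort, seed = 1)              # BIC scan, k = 1..9 x 5 families
summary(fit)
#> Gaussian mixture over 1484 airway segments
#> Selected by BIC: k = 5, family 'full-free' (BIC = -21938.60, logLik = -10863.41)
#>
#>   cluster  weight mean_lumen mean_wall sd_lumen sd_wall n_segments
#> 1     CL1 0.06862     445.96    26.691  128.088  6.4071         98
#> 2     CL2 0.08573     219.31    15.162   59.508  3.5079        130
#> 3     CL3 0.18066     118.32     6.552   16.199  0.9136        268
#> 4     CL4 0.16375      80.79     8.881    9.273  0.9738        244
#> 5     CL5 0.50124      37.67     8.486    6.296  2.7154        744
```

Five compartments, from the large central airways (CL1, mean lumen ≈ 446 µm)
down to the smallest distal segments (CL5, ≈ 38 µm, half of all segments).
How do the branching-based schemes compare on the same features?

```r
evaluate_groupings(gen$cohort, fit)
#> Grouping-scheme benchmark (Davies-Bouldin: lower is better; Dunn: higher is better)
#>       method protocol    DB (SD)          Dunn (SD) groups (SD)
#>  generations per-tree   120 (57)   6.17e-05 (3e-05)  30.8 (2.9)
#>       orders per-tree 4.19 (3.1) 0.000324 (0.00019)  30.8 (2.9)
#>     strahler per-tree 2.31 (1.7) 0.000572 (0.00036)       5 (0)
#>          gmm   pooled      0.546           0.000578           5
```

Generations produce ~31 heterogeneous groups per tree with a Davies–Bouldin
index two orders of magnitude worse than the mixture's; Strahler orders come
closest among the branching schemes but are still outperformed. The group
comparison then runs per compartment:

```r
tab <- segment_table(gen$cohort)
tab$cluster <- as.character(fit$classification)
compare_groups(tab, "lumen_diameter", cluster = "cluster")
#> Two-group comparison: HYX vs NOX (Mann-Whitney U, effect size r)
#>       Parameter Cluster     Mean A (SD)     Mean B (SD)    p Effect
#>  lumen_diameter  Global  98.57 (102.84) 106.81 (123.33)   ns      -
#>  lumen_diameter     CL1 395.14 (108.78) 518.68 (110.37) **** medium
#>  lumen_diameter     CL2  198.61 (53.87)  244.31 (56.24) **** medium
#>  lumen_diameter     CL3  116.65 (15.96)  120.07 (15.79)   ns      -
#>  lumen_diameter     CL4    79.59 (8.56)    81.67 (9.59)   ns      -
#>  lumen_diameter     CL5    37.85 (6.21)    37.48 (6.36)   ns      -
```

This synthetic cohort carries a lumen reduction confined to the large-airway
archetypes — and that is precisely what the per-cluster analysis reveals
(CL1/CL2 highly significant, medium effect) while the global comparison sees
nothing. Localizing effects that a global test cannot detect is the point of
the method.

`run_pipeline()` executes the whole workflow (ingest or simulate → groupings
→ mixture → benchmark → comparison tables → figures) and
`export_report()` writes CSV/JSON/PNG artifacts stamped with package
version, seed and configuration hash; reruns are byte-identical. A thin
command-line front end lives at `inst/scripts/airwayclust.R`
(verbs `simulate`, `analyze`, `report`).

External tables are read with `read_segment_table(path, dialect = ...)`:
delimited text, one row per (segment, image) measurement with subject,
group, segment and parent ids plus inner/outer diameters (or pre-averaged
lumen/wall), and optional epithelium columns; the dialect map adapts any
header naming.

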