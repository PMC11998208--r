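---
title: "Morphology-based compartments of monopodial airway trees"
author: "airwayclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphology-based compartments of monopodial airway trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwayclust)
```

## The problem

The conducting airways of a lung are not one homogeneous tissue: epithelium
height, cell composition, wall structure and caliber all change from the main
bronchus down to the terminal bronchioles. A disease may strike these
sub-compartments unevenly, so a two-group morphometry study should compare
*like with like* — segments of the same compartment — rather than pool the
whole tree into one global test.

In primate lungs, whose airways branch roughly dichotomously, counting
*generations* from the trachea approximates such compartments. The lungs of
most laboratory species (mice, rats, rabbits) are instead **monopodial**: one
long central airway per lobe gives off much smaller lateral daughters. On
such a tree a generation label mixes a huge trunk segment with the tiny
laterals of all earlier branch points, and generation counts explode with
trunk length. Branching-based labels are structurally mismatched to the
morphology they are meant to stratify.

`airwayclust` implements the alternative: **cluster the segments by their
morphology directly** — lumen diameter and wall thickness, the two features
measurable for every segment — with a Gaussian mixture model, select the
number of compartments by BIC, and run the two-group comparison globally and
per cluster. Branching-based labelings (generations, Horsfield-style orders,
Strahler orders) are computed as baselines and benchmarked against the
mixture partition with cluster-validity indices.

## Data model

A **segment** is the piece of airway between two bifurcations; it is the unit
of measurement and labeling. Trees are stored as parent-pointer graphs
(`airway_tree`), cohorts as lists of trees (`airway_cohort`). Inputs are
delimited text tables, one row per (segment, image) measurement; a
column-name dialect map adapts arbitrary headers, because no standard format
exists for such tables. All lengths are micrometres throughout; no unit
inference is attempted.

Per-image wall thickness is $(\varnothing_{outer} - \varnothing_{inner})/2$,
and a segment visible in several consecutive images gets the arithmetic mean
of its per-image lumen diameters and wall thicknesses. We average the
per-image wall values rather than applying the formula to averaged diameters;
by linearity both give the same result, but stating the order makes the
averaging rule testable on its own.

Epithelium profiles (nuclei counted along a 100 µm ruler by cell category,
epithelial height, cilium length) are optional per segment; they yield the
derived parameters nuclear density (nuclei/mm) and cell-type percentages.
When no nuclei were counted the percentages are undefined and reported as
missing, never as 0/0.

## The mixture model

The clustering features are the raw (lumen diameter, wall thickness) pairs of
**all** segments of **all** trees, pooled. Pooling is essential: fitting one
model across animals is what makes cluster labels comparable between
subjects and groups. Features are not standardized by default — the model is
meant to operate on the natural micrometre scale, where lumen diameter
dominates, exactly as the field's standard mixture tooling does; a
`standardize` flag exists for other data.

`airway_gmm()` fits $k$-component bivariate Gaussian mixtures by EM for every
$k$ in 1–9 and five covariance families (shared/free spherical, free
diagonal, shared/free full covariance), and scores each fit with
$\mathrm{BIC} = 2\log L - m\ln n$, the convention under which the best model
has the *highest* score. Ties break toward fewer components, then the
simpler family. The default grid upper bound of nine components is the
customary mixture-scan default, overridable. The free-full family
("ellipsoids of variable volume, shape and orientation") is always part of
the default grid; it is the family real, tilted airway morphology clouds
select, while weakly correlated data may settle on the cheaper free-diagonal
family.

Numerical choices:

* **Restarts.** EM is restarted 10 times per $(k, \text{family})$: the first
  restart initializes from k-means, the rest from randomly chosen centers.
  The restart with the highest log-likelihood wins. All randomness derives
  from one integer seed, which is recorded in every output.
* **Convergence.** EM stops when the log-likelihood improves by less than
  $10^{-8}(1+|\log L|)$, or after 500 iterations (the best iterate is then
  returned with a warning). The per-iteration log-likelihood trace of the
  winning restart is exposed, so likelihood ascent is assertable in tests.
* **Covariance floor.** Component variances are floored at $10^{-6}$ times
  the feature variance (plus a tiny absolute guard), and the off-diagonal is
  shrunk if a determinant collapses. Duplicated measurement rows therefore
  degrade gracefully instead of producing singular components.
* **Implementation.** The EM inner loop is compiled C++ (RcppArmadillo),
  specialized to two dimensions with closed-form $2\times 2$ inverses; the
  model-selection scan fits 450 mixtures in a few seconds.

Components are relabeled canonically after selection: CL1, CL2, … CL$k$ in
strictly descending mean lumen diameter, with exact ties broken by
descending mean wall thickness, then component index. CL1 is therefore
always the large-central-airway cluster and CL$k$ the smallest, most distal
one, regardless of the order EM produced.

## Branching-based baselines

Three labelings are computed per tree, from topology alone:

* **generations** — root 0, incremented below every branch point;
* **orders** — terminals 1, parent = max(child orders) + 1 at every junction
  of two or more branches;
* **Strahler orders** — like orders, but incrementing only where two or more
  children of equal maximal order meet.

Single-child (pass-through) segments — which arise when trees are cut at the
terminal bronchioles — inherit their neighbour's label in all three schemes,
and junctions of three or more branches count like bifurcations (the
definitions say "two or more"). The root generation is 0 (trachea = 0
convention); only label names, not group structure, depend on that base
index. Strahler's defining property, and the reason it is the least-bad
branching scheme for monopodial trees, is compression: an arbitrarily long
trunk with small laterals keeps one low order, while generations grow
linearly with trunk length.

## Benchmarking partitions

Partitions are scored on the same two morphological features used for
clustering, with:

* **Davies–Bouldin**: mean over groups of the worst-case
  $(S_i + S_j)/d(c_i, c_j)$, with $S_i$ the mean distance to the group
  centroid (the classical $q{=}1, p{=}2$ form). Lower is better.
* **Dunn**: minimum single-linkage inter-group distance over maximum
  complete-diameter, i.e. a pure worst-case ratio. Higher is better.

Branching-based labelings are defined per tree, so they are evaluated per
tree and summarized as mean (SD) across trees; the pooled mixture is
evaluated once on the full feature matrix and carries no SD. Single-point
groups contribute zero dispersion/diameter rather than being dropped; a
method that produces fewer than two groups on some tree is excluded from
that method's mean with a warning.

## Two-group comparisons

`compare_groups()` compares the treated and control group for each parameter
globally and within every cluster, with the Mann–Whitney U test. Group
summaries give mean, SD, median and n; observations enter as collected, with
no outlier removal. For small tie-free samples (both $n \le 8$) the p-value
is exact; otherwise the normal approximation with tie-corrected variance and
continuity correction is used. The standardized $Z$ that feeds the effect
size $r = |Z|/\sqrt{N}$ is computed *without* the continuity correction — the
convention under which the canonical worked example ($n = 3$ vs $3$, $U = 0$)
gives $r = 0.802$ — while the correction is applied inside the approximate
p-value. Effects are interpreted on Cohen's benchmarks with half-open
intervals ($r < 0.1$ none, $< 0.3$ small, $< 0.5$ medium, else large;
boundary values belong to the higher category), and reported only for
significant rows — non-significant rows carry "–". Significance stars use
the inclusive caption mapping (ns $> 0.05$, * $\le 0.05$, ** $\le 0.01$,
*** $\le 0.001$, **** $\le 0.0001$).

Raw per-scope p-values are reported without multiple-testing correction, for
fidelity to the table convention of the study design this package supports; a
Holm option exists but is off by default. Per-segment observations are
treated as independent even though they cluster within a handful of animals —
that is a real limitation of the underlying design (two animals per group),
documented rather than "fixed" here; a full-size study should model the
animal level explicitly.

## The synthetic cohort generator

No public per-segment airway dataset exists at this scale, so the package
ships a generator whose defaults emulate the study conditions: two subjects
per group (normoxia vs hyperoxia), one monopodial tree each, on the order of
700 segments per group.

**Topology.** A central trunk of 26 segments; every trunk segment spawns one
lateral subtree, itself a smaller monopodial trunk, recursively down to
terminal segments. A lateral at relative trunk position $p$ roots a subtree
whose caliber class is one step below its trunk's, plus
$\mathrm{Binomial}(2,\,0.35 + 0.5p)$ extra steps — proximal laterals carry
deep subtrees, distal laterals shallow ones, the hallmark of monopodial
branching. Trunk tips end in two terminal daughters. This construction
yields generation and order counts around 30 per tree, a Strahler depth of
4–5, and realistic mixing of calibers within branching-based label
classes.

**Morphology.** Each caliber class maps to one of five archetypes — CL1
trunk, CL2 medium, CL3 small/thin-walled, CL4 small/medium, CL5 smallest
with the widest wall spread — each a bivariate Gaussian on (lumen, wall),
truncated at zero by resampling. No published per-cluster moments exist, so
the archetype means and SDs are free modelling parameters, chosen once so
that the five clusters form overlapping but recoverable ellipses (adjacent
lumen means 2–5 SD apart) and then frozen. Epithelium parameters (height,
cilium length, density, cell-category probabilities) follow the magnitudes
reported for healthy rabbit airways; goblet-cell probability is nonzero only
in the two large-airway archetypes, where rabbits actually have goblet
cells. Nuclei counts are Poisson with mean density × ruler/1000 and
multinomial categories.

**Effects.** The treated group's archetype parameters are shifted *before*
sampling (multiplicatively on the means), so recovery tests have analytically
known targets: lumen ×0.8 and wall ×1.2 on CL1–CL2 only, epithelium height
×1.3, cilium length ×0.85 and density ×0.9 everywhere. The within-archetype
SDs were calibrated once against two opposing requirements — the rank test
must detect the shifts per cluster (≥ 0.8 SD per feature at n ≈ 40–130 per
scope), while BIC must *not* split a pooled two-group archetype into
treatment sub-clusters (joint Mahalanobis shift below ≈ 1.3 SD at those
sizes) — and then frozen.

**What passing tests show, and what they do not.** The generator produces
honestly Gaussian archetypes, independent segments, and effects applied
exactly where configured. Real data adds within-trunk tapering,
animal-level correlation, measurement error correlated along a segment
chain, and archetypes that are at best approximately Gaussian. Recovery of
$k = 5$ and of injected effects on this test bed validates the machinery —
model selection, relabeling, indices, tests — not the biological claim that
a particular lung has five compartments.

One deliberate consequence of confining the lumen/wall effects to the two
large-airway archetypes: the *global* lumen comparison is expected to stay
non-significant on synthetic cohorts. Large airways hold ~13% of segments
and their lumen range barely overlaps the small-airway mass, so shifting
them moves the global rank statistic by almost nothing. A global difference
emerges only when small airways are affected too — which is exactly the
argument for per-compartment comparisons.

A related subtlety: because the generator's topology makes the per-group
archetype composition nearly deterministic, the *global* null comparison is
effectively stratified — both groups always carry almost the same share of
each compartment — and the unstratified rank-test variance overstates the
true variability. The global test is therefore conservative on null
synthetic cohorts (observed rejection ≈ 0 at nominal 5%), while within each
cluster scope, where both groups are genuine draws from one archetype
distribution, the empirical type-I rate sits at the nominal level
(0.04–0.06 across 500 null cohorts).

## Problem sizes used by the test suite

The packaged validation uses: 200 random trees (≤ 50 segments) against naive
recursive labeling oracles; 100 random labeled point sets against brute-force
index recomputation; exhaustive Mann–Whitney enumeration for all tie-free
sample sizes up to 7; 50 seeded default cohorts (~1480 segments each) for
cluster-number recovery, label recovery (adjusted Rand index) and the
method-ranking benchmark; 50 cohorts for effect recovery; and 500 null
cohorts for the type-I error of the per-scope comparisons. With the compiled
EM core the complete suite runs in well under half an hour on one CPU, the
default pipeline itself in a few seconds.

## Known limitations

* Cluster labels are statistical compartments, not anatomy; they inherit the
  assumption that treatment groups still share their gross morphology. If a
  pathology reshapes one group wholesale, fit the mixture per group (pass a
  subset cohort) and compare cluster structures instead.
* Exact Mann–Whitney p-values are limited to tiny tie-free samples; at the
  study scale (hundreds of segments) the tie-corrected normal approximation
  is what the reference R implementation would use as well.
* The epithelium cell counts are plain ruler counts, not unbiased
  stereological estimates; the generator and the comparisons reproduce that
  protocol, including its bias.
* One tree per subject; multi-lobe lungs enter either as separate trees or
  joined under a common root by the caller.
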