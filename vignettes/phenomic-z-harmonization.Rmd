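---
title: "Harmonizing heterogeneous phenotyping screens with bootstrap Z scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing heterogeneous phenotyping screens with bootstrap Z scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoz)
```

## The model

A mutant-collection screen measures the same genotypes — a wild-type
reference (Col-0) and a panel of insertion lines, some genes represented by
two independent alleles — across many experiments that differ in measurement
scale, replication and design. `phenoz` reduces every experiment to one
question, *how does each line differ from the reference?*, and expresses the
answer on a single scale: the signed standard-normal Z statistic.

### Per-assay adapters

Each assay family routes to the statistical adapter that fits its data:

* **Continuous endpoints, burst totals, germination-curve endpoints** —
  pooled two-sample contrast, `z = (x̄ − ȳ) / SE_pooled`, referred to the
  standard normal rather than a t distribution. The pipeline converts every
  statistic to a Z score by design; the small-sample conservatism this
  ignores is absorbed by the bootstrap commensuration below.
* **Ordinal 0–3 severity scores** — Mann–Whitney U from midranks with the
  tie-corrected variance and *no* continuity correction, so that z and p
  remain exactly invertible through Φ. Positive z means the line scores
  stochastically higher than the reference.
* **Time courses** — each timepoint is analysed separately (so each has
  power comparable to an endpoint assay) with a linear mixed model:
  genotype as fixed effect and a random intercept per experiment block.
  The block-variance ratio λ = σ²_block/σ²_resid is estimated by profiling
  the restricted likelihood on a fixed log-spaced grid
  (λ ∈ {0} ∪ 10^[−3,3], 31 points); for a single random intercept the GLS
  solution at each λ is closed-form in per-block sufficient statistics, so
  the fit is deterministic, exact to grid resolution, and fast enough to sit
  inside the bootstrap. With a single block the model degrades to the
  unblocked contrast with a warning.

For within-experiment figure annotations the package also provides the
single-step max-|Z| family-wise adjustment (`single_step_adjust()`), the
multivariate-normal analogue of Dunnett/Tukey corrections, evaluated by
Monte Carlo (100,000 draws by default) under a fixed seed.

### Bootstrap commensuration to n = 15

Experiments differ in replication, and a Z score's magnitude scales with
√n. To make Z scores comparable, every condition cell (genotype × treatment
arm × timepoint, pooled over experiment blocks) is resampled with
replacement to a common size n = 15; the adapter's Z is computed on each of
B bootstrap data sets and the B estimates are averaged. The averaging
removes the bootstrap-resampling noise (the mean converges to a functional
of the observed cell data), leaving a statistic whose scale corresponds to
n = 15 power regardless of the native sample size.

Two consequences are worth stating plainly, because the validation suite
relies on them:

* When the native cell is larger than 15, the commensurated Z̄ is
  *deliberately deflated* relative to a full-data test — its null spread is
  roughly √(15/n_native). This is the point of the procedure (no experiment
  dominates because it was better replicated), not a bug, and calibration
  checks that expect standard-normal null Z therefore use screens whose
  native cell size is 15.
* Within one screen, every line shares the same reference cell, so line-level
  Z scores are positively correlated: a fortunate or unfortunate reference
  draw shifts the whole column. Marginal calibration can only be assessed by
  pooling across independent screens, which is how the null-calibration test
  is built (250 screens of 2 lines rather than one screen of 500).

B is not stated by the procedure's sources and is a free parameter: the
default is B = 200 (B = 50 in the Monte-Carlo suites, where thousands of
fits are run); the bootstrap mean stabilises well before that.

### Sign-preserving BH adjustment in Z-space

Raw Z̄ matrices are corrected for multiplicity in Z-space:

1. p = 2(1 − Φ(|Z̄|)),
2. Benjamini–Hochberg step-up within each family — by default one family
   per assay column ("per experiment"); a single global family is available
   via `family_scope = "global"`,
3. z_adj = sign(Z̄) · Φ⁻¹(1 − p_adj/2).

Because the transforms are exact inverses, thresholding |z_adj| at
Φ⁻¹(1 − q/2) reproduces the BH rejection set at level q *exactly*; the
suite verifies this identity on random p-vectors. BH never decreases
p-values, so |z_adj| ≤ |Z̄| cellwise and ranking within a family is
preserved. Tiers are labelled from |z_adj| with the conventional guideline
cutpoints 1.67 (FDR < 10%), 2 (FDR < 5%) and 2.6 (FDR < 1%); the exact
quantiles are 1.645, 1.960 and 2.576, so the printed guidelines are slightly
conservative. (Guideline texts occasionally print "|Z| < 2.6" for the
strongest tier; the direction is implemented as ">", the only reading
consistent with the other two thresholds.) Unmeasured line × assay cells
carry an explicit missingness mask, never a value, and do not count toward
family sizes. An adjusted p that underflows to 0 maps to the cap
|z_adj| = Z_CAP = 8; the same cap is applied to raw statistics from
perfectly separated samples.

Allele averaging (`average_alleles()`) collapses multiple alleles of a gene
by the arithmetic mean of their adjusted Z values, ignoring missing cells;
averaging raw Z instead is available as a sensitivity mode.

### Clustering recipes

Two agglomerative recipes serve the integrated heatmaps:

* `cluster_ward_euclidean()` — Ward linkage on Euclidean distances of the
  adjusted-Z matrix. Unmeasured cells are set to 0 first: the semantically
  neutral "no difference from the reference" value on the adjusted-Z scale.
* `cluster_complete_pearson()` — complete linkage on d = 1 − r with Pearson
  r over pairwise-complete columns, grouping lines by response *shape*.
  Zero-variance rows are rejected by name, and every pair of rows must share
  at least three measured assays.

Both delegate to `stats::hclust` (whose agglomeration order fixes
tie-breaking deterministically) and are validated against independently
coded O(n³) brute-force linkage implementations via cophenetic matrices.
`export_newick()` writes ultrametric trees (each node at half its merge
height, so two leaves merging at height h read `(A:h/2,B:h/2);`), quoting
labels per the Newick convention.

## The synthetic generator

Because raw screen data of this kind are rarely deposited, the package
includes a first-class generator (`sim_config()`, `simulate_phenotypes()`)
whose defaults are the study conditions the pipeline targets:

| parameter | default | meaning |
|---|---|---|
| `n_per_cell` | 15 | replicates per genotype × arm × timepoint cell per block — the common n the screen's assays aimed for |
| `n_blocks` | 3 | independent experiment replicates per assay |
| `block_sd` | 0.5 | between-experiment random-intercept SD, in residual-SD units |
| `noise_sd` | per assay | residual SD in assay units (latent units for ordinal scores) |
| `effect_matrix` | 0 | planted gene × assay effects in residual-SD units |

Mechanics per family: continuous cells are baseline + effect·σ + block
effect + N(0, σ²); ordinal scores threshold a latent Gaussian at fixed
quartile cutpoints (a controllable-effect 0–3 scale); germination is
simulated per dish as 50 logistic germination times whose half-time shifts
by 2 h per residual-SD unit of effect, read out as percent germinated every
5 h up to 51 h — monotone nondecreasing within a dish by construction, with
the assay's endpoint timepoint defaulting to the observation nearest the
baseline half-time, where dishes discriminate best. Each assay draws from
its own RNG substream keyed by a stable hash of the assay id, so adding an
assay never perturbs another's draws and identical configurations are
byte-identical.

What the generator does *not* emulate: instrument-level noise spectra
(conductivity meters, luminometers), spatial or temporal autocorrelation
within an experiment, and non-Gaussian residual shapes beyond the
latent-threshold and logistic constructions. Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
model, not robustness to arbitrary real-world noise.

## Validation design and problem sizes

The Monte-Carlo suites fix their own scales (chosen for tight estimates at
desk scale, and stated here as the package's reference conditions):

* **Null calibration** — 200 fully null screens of 50 lines × 6 assays
  (every family represented), B = 50. The false discovery proportion is
  computed per BH family (one assay column), V/max(R,1), and averaged over
  all 1,200 screen × assay families; under a full null this is the quantity
  BH bounds. Pooling rejections across the six independent families first
  would instead estimate the union's family-wise error rate (~1−(1−q)⁶),
  which no FDR procedure controls.
* **Power** — 2σ effects planted one-gene-per-assay in 100 screens of 20
  lines; detection is a tier ≥ fdr5 call. The reference value is an
  adapter-level Monte-Carlo oracle: each family's detection rate at
  |z| > 2 on fresh n = 15 data with the same planted effect, outside the
  bootstrap/BH pipeline.
* **Clustering recovery** — 50 seeds of a 16-line, 8-assay matrix with two
  planted line blocks (within-block effect correlation 0.9, across-block 0),
  scored by adjusted Rand index after cutting the 1−Pearson tree at k = 2.

## Known limitations

* The normal approximation for Mann–Whitney is poor at very small group
  sizes: against exact enumeration the two-sided p can deviate by up to
  ~0.68 at n = 1 + 1 and still ~0.12 when both groups have ≥ 4
  observations (the acceptance script measures both). The design keeps the
  approximation anyway because exact invertibility of z ↔ p through Φ is
  what makes the Z-space BH machinery exact; ordinal assays at such sizes
  should simply not be trusted at face value.
* Commensuration treats a small experiment as if it carried n = 15 worth of
  evidence; Z scores from natively tiny cells are anti-conservative to the
  same degree that large cells are shrunk. The screen design this targets
  used n ≈ 15 throughout.
* The mixed model profiles a single random intercept on a fixed grid; more
  complex random structures (crossed effects, heteroscedastic blocks) are
  out of scope, and grid resolution limits the standard error to about a
  percent of the exact REML optimum.
* BH family scope is genuinely ambiguous in integrated screens (per
  experiment vs per experiment × timepoint vs global); both supported
  scopes are exposed and the default (per assay column) is the most common
  reading.
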