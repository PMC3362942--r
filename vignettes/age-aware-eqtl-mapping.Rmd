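---
title: "Age-aware eQTL mapping in RIL panels: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-aware eQTL mapping in RIL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormAgeQTL)
```

# The emulated study

The package is organized around a two-parent *C. elegans* RIL aging
design: 36 recombinant inbred lines genotyped at 121 markers on six
chromosomes, plus the parental strains N2 and CB4856, with genome-wide
log2 expression measured at three ages — 40 h (t1, juvenile), 96 h (t2,
reproductive) and 214 h (t3, old). Parents contribute six independent
replicates per age, RILs one sample per age. Two-age windows combine
t1 + t2 ("developing") and t2 + t3 ("aging").

Strains differ in mean lifespan (defaults: N2 16 d, CB4856 13 d, RIL
lifespans uniform in between), so a fixed chronological sampling time
hits different life stages in different strains. All two-age models
therefore use **physiological age**, the sampling age divided by the
strain's mean lifespan — a dimensionless fraction of life lived
(`physiologicalAge()`).

# The simulator

`simulateGenotypes()` draws fully inbred RIL genomes chromosome by
chromosome as a two-state Markov chain on \{−1, +1\}. For adjacent
markers `d` cM apart the per-meiosis recombination fraction under the
Haldane map function is `r = (1 − exp(−2d/100))/2`; repeated selfing
fixes additional recombinants, giving the observed switch probability
between RIL genotypes `R = 2r/(1 + 2r)`. The first marker of each
chromosome is ±1 with equal probability, chromosomes are independent,
and the parents are appended as the constant +1 and −1 rows. The default
map has 121 markers spread evenly over six 50 cM chromosomes — one
consequence worth keeping in mind is that markers on the same chromosome
are strongly correlated (adjacent-marker correlation ≈ 0.9, and ≈ 0.4
even 25 cM apart), so a chromosome behaves much like a single block in a
36-line panel.

`simulateExpression()` generates, for gene *g*, strain *s* and sample
with physiological age τ,

```
y = baseline + Σ a_m·g_m  + Σ e_mm'·g_m·g_m' + (slope_age + Σ i_m·g_m)·τ + N(0, σ)
```

with all effects specified per gene by an `architectureSpec()`. Noise is
Gaussian on the log2 scale, matching analyses that operate on log2
normalized intensities.

**What the simulator does not emulate:** probe-level microarray
artifacts, dye effects, normalization residue, batch structure,
heavy-tailed or heteroskedastic noise, genomic positions of the genes
themselves (so no cis/trans distinction), and biological correlation
among genes (genes are generated independently unless architectures
share markers). Passing calibration tests on these data therefore shows
the *statistical machinery* is correct and calibrated under its own
assumptions; it does not certify performance on real arrays.

## The three architecture scenarios

`categoryArchitectures()` generates the canonical scenarios relating
parental differential expression to eQTL detectability:

- **A** — one strong locus (effect 1.0, residual SD 0.2): parents
  differ by 2.0 log2 units and the locus maps essentially always.
- **B** — many small same-direction loci. The default splits a total
  parental gap of 0.5 log2 units over 20 loci (+0.0125 each) allocated
  round-robin across chromosomes. This is a deliberate power
  construction. The gap must exceed ≈ 0.45 for the 6 + 6 parental
  replicates to detect it reliably at −log10 p ≥ 2 (noncentrality
  ≈ 4.3). At the same time, because whole chromosomes co-segregate, what
  a single-marker scan sees per chromosome is the *chromosome aggregate*
  — roughly (gap/2)/6 ≈ 0.04 on the allele scale — which at 36 lines
  stays far below the −log10 p = 3 calling threshold. Notably, the
  aggregate is independent of how many loci carry it, so dispersing a
  larger gap over more loci does **not** rescue per-locus
  undetectability; only the gap-to-noise ratio matters. Unbalanced locus
  placement would concentrate several effects on one chromosome and turn
  the gene into a de-facto category A, which is why placement is
  stratified.
- **C** — effects that cancel in the parents: either one epistatic
  marker pair (product effect 1.0; both parents carry `g·g' = +1`, so
  parental means coincide while RILs with product −1 sit 2.0 log2 units
  away — the transgression-prone case) or two opposite-sign additive
  loci.

# Mapping models and conventions

`fitModel1()` regresses expression on one marker per age group
(equivalent to the pooled-variance two-sample t test; the reported
effect is the slope on the ±1 coding, i.e. half the group difference).
`fitModel2()` adds physiological age and the marker × age product over a
two-age window. Scores are −log10 two-sided p-values, **capped at 300**
to keep tables finite under double-precision underflow. Conventions for
degenerate fits, chosen so tables stay complete rather than turning
`NaN`:

- monomorphic marker or too few samples → untestable flag, score 0,
  effect `NA`;
- zero total variance, or zero group separation with zero residual
  variance → score 0, effect 0 (p = 1 by convention);
- nonzero coefficients with (numerically) zero residual variance →
  score at the cap. "Zero" is judged relative to the total sum of
  squares (`RSS ≤ TSS·1e-20`), which keeps all scores invariant to
  affine rescaling of the expression values.
- constant physiological age degrades model 2 gracefully: the age and
  interaction terms become untestable and the marker term equals the
  model-1 fit on the pooled samples.

A caveat inherited from the model parameterization: with the
uncentered `g·τ` product in the model, the marker coefficient measures
the effect extrapolated to τ = 0 and is strongly collinear with the
interaction term, so model-2 marker scores are systematically more
conservative than a per-age model-1 scan of the same data.

`mapGenome()` scans every marker for every gene, reports one peak per
gene × term × window (ties at the peak go to the first marker in map
order) and calls an eQTL when the peak reaches the threshold (defaults:
3 for RIL linkage, 2 for the parental contrast, which reuses the same
code path with strain identity as a pseudo-marker). Masked values are
dropped per gene × marker fit (per-marker complete cases, not listwise
deletion across markers). Thresholds of 8 (developing) and 6 (aging)
are the defaults for the physiological-age term in the FDR tables,
where the age effect is pervasive.

# Permutation thresholds

`permuteLabels()` permutes the sample-to-strain assignment (and, for
model 2, the sample-to-age assignment independently), always relabeling
whole sample columns so each gene's value multiset and the among-gene
correlation structure are untouched; physiological age is recomputed
from the permuted strain/age pairs. `permutationNull()` restricts the
permutation to the samples the scan actually uses. `estimateFdr()` is
the plug-in ratio: mean permuted count of genes at or above the
threshold over the observed count (clipped to 1; reported as 1 when
nothing is observed but permutations call genes, and as `NA` when both
counts are zero). Defaults follow the emulated study: 100 permutations
for genome-wide FDRs, 30 for the joint-FDR.

`jointFdr()` estimates the chance of a gene passing *both* the parental
threshold and the RIL eQTL threshold: the numerator averages the joint
count over all pairs of one parental and one RIL permutation (drawn
independently), which algebraically reduces to the per-gene product of
marginal permutation pass rates. The independence-based product-rule
value (universe × overall marginal rates) is attached as an attribute
for comparison, since the two estimators differ exactly when per-gene
pass rates are heterogeneous.

# Heritability estimators

Single age: `H² = (V_RIL − V_P)/V_RIL` with `V_RIL` the n−1 sample
variance across RIL values and `V_P` the two parents' within-strain
variances pooled with replicate-degrees-of-freedom weights (the pooling
weights are a package choice; df-weighting is the standard pooled
variance). `H² ≤ 1` always; negative values are retained in all tables
(they are informative about sampling noise) and excluded only from
threshold-crossing counts.

Over time, the goal is the genotype *main* effect with the
genotype × age interaction excluded. The estimator: `V_RIL` is the
variance across RILs of each RIL's two-age mean — an age main effect
cancels in the comparison and a pure crossing interaction leaves all
two-age means equal, contributing nothing. For consistency `V_P` must
then be the *environmental variance of a two-age mean*, which is half
the pooled age-centered replicate variance (averaging one independent
draw per age halves the variance). An ANOVA genotype mean square would
be the natural alternative estimator for the numerator; the variance of
strain means was chosen as the simplest estimator satisfying the
exclusion property, and the /2 scaling of `V_P` is what makes the
estimator consistent for σ²g/(σ²g + σ²e/2) — the expectation the
calibration tests check against (with the additional exact finite-sample
factor ν/(ν−2) from E[1/V_RIL]).

`highH2Cutoff()` randomizes the sample-to-strain assignment within each
age group, recomputes the full H² vector per permutation, and returns
the smallest observed H² at which (mean permuted count ≥ t)/(observed
count ≥ t) drops below the target rate (default 1%).

# Transgression

Per gene and age, the upper bound is the higher-mean parent's
`mean + 2 SD` and the lower bound the lower-mean parent's
`mean − 2 SD`, each parent contributing its own replicate SD; parents
are re-ranked per gene and per age. A gene is transgressive when at
least 6 RILs fall **strictly** outside a bound (ties do not count —
a documented convention), and in two-age windows a RIL must exceed the
age-specific bound at both ages in the same direction. The single-age
statistic has a substantial sampling-noise background (parental SDs
estimated from 6 replicates are noisy, and an underestimated SD
tightens the bounds), which is precisely why the over-time statistic
exists: the both-age requirement suppresses that background by an order
of magnitude. The permutation FDR shuffles the strain labels (and with
them the RIL-vs-parent roles) within each age.

# Multi-locus models

`selectCandidateMarkers()` picks 4 markers per chromosome maximizing
the minimum pairwise genetic distance (exhaustive over combinations;
deterministic, ties resolved toward the lexicographically smallest
position vector — on evenly spaced maps several sets tie at the
optimum, so determinism matters more than which tied set wins).

`stepwiseBic()` starts from the age-only model and greedily adds or
removes one term per step — marker main effects, all 276 marker-pair
products, marker × age products, and the age term itself — choosing the
move with the largest BIC decrease; ties prefer removal, then the
earlier term in the canonical candidate order. There is **no heredity
constraint**: an interaction may enter without its main effects, which
is essential for purely epistatic genes whose marginal effects are
near zero. `BIC = n·ln(RSS/n) + k·ln(n)` with k counting all
coefficients including the intercept. Selection stops when no move
improves, at 2000 steps, or at 6 terms with no helpful removal.
Implementation notes: additions are evaluated via projection of each
candidate column on the current model's orthogonal complement (exact,
one matrix product per step), the final model is refit exactly, RSS is
floored at `TSS·1e-12` to keep BIC finite on exact fits, and selection
uses no randomness, so fixed data give identical models.

**Known limitation — false entry on null genes.** With ~320 candidate
terms and n = 72 samples, a term enters whenever its partial t² exceeds
ln(72) ≈ 4.3, i.e. |t| ≈ 2.07 (per-candidate p ≈ 0.04). The maximum
over hundreds of weakly correlated candidates exceeds this with
probability near 1, so pure-noise genes typically acquire one to three
spurious terms: greedy BIC over a large dictionary controls *average*
model complexity, not the family-wise false-entry rate. Per-gene
multi-locus counts should therefore be read descriptively and compared
against a permutation baseline (as the polygenic summaries do via
heritability binning), not as calibrated per-gene tests. A
significance-to-enter guard could suppress this, but would change the
stated selection rule and is deliberately not applied.

# Outlier handling

Two procedures, both applied to the replicated parental samples by
default (the only samples with within-strain replication): a
single-pass per gene × age group × strain screen at `mean ± 2 SD`, and
a recursive procedure that fits expression on the two-level age-group
factor, removes the single most extreme externally studentized residual
outside the two-sided 99.5% interval, refits, and stops after at most 6
removals. A t2 value is an outlier when either the developing or the
aging run removes it (union of masks). Masked values become missing and
all downstream statistics use pairwise-complete observations; nothing
is imputed. On Gaussian null data the recursive procedure removes well
under 1% of values.

# Enrichment

`hypergeomEnrich()` is the one-sided upper-tail hypergeometric test of
a gene set against an annotation table; terms with fewer than two genes
are discarded at load, the universe defaults to the genes on the
expression matrix (not all annotated genes), and no multiple-testing
correction is applied by default (an `adjust` argument is available).

# Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run
in minutes on one CPU: 1000 genes for null calibration (p-value
uniformity, permutation FDR with 100 permutations), 5000 genes for
heritability recovery at four truth levels, 100 genes per architecture
class for the recovery experiments, and exhaustive enumeration up to
universe size 12 for the hypergeometric oracle. All stochastic steps
take explicit seeds; identical seeds give bit-identical panels,
expression matrices and downstream tables, and `runPipeline()` writes a
manifest echoing the configuration so a run can be replayed.
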