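---
title: "Methods: lipidomic structure, pathway flux and co-occurrence analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipidomic structure, pathway flux and co-occurrence analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidaxis)
```

## Scope and design

`lipidaxis` implements the computational core of a two-group
microbiota-gut-brain study design: depression-like (`DL`) versus healthy
control (`HC`) animals, n = 6 per group, with untargeted LC-MS lipidomics of
three brain regions (prefrontal cortex, amygdala, hippocampus) and plasma,
shotgun-metagenomic taxon profiles, and five scored behaviors (huddle, sit
alone, locomotion, amicable, communication). The package takes the
*processed* tables such a study produces — a LipidSearch-style peak-area
export with QC fields, a rank-prefixed relative-abundance taxon table, and
per-animal behavior durations — and carries them through QC, normalization,
differential analysis, reaction-network activity scoring, a two-class LDA
effect-size screen, and a thresholded Spearman co-occurrence network.
Upstream steps (peak identification, read assembly and annotation, video
scoring) are out of scope; a seeded synthetic-data generator stands in for
raw data so that every stage is testable end to end.

## Quality control and normalization

A feature is retained when all four criteria hold: `Rej == 0`,
`PQ > 0.85`, `CV < 0.3`, and `|ppm| <= 5`. The boundary semantics follow
the wording of the acceptance rules literally: "higher than" and "below"
are strict inequalities, the reject flag is an exact match, and a
"tolerance" of 5 ppm is inclusive. Filtering is a pure conjunction and
therefore idempotent; a per-criterion rejection count is logged so every
removal is auditable. Positive- and negative-mode tables, when present,
are filtered separately and concatenated, resolving duplicate species by
the higher mean abundance.

Normalization replaces each value by `100 * value / column_sum`, so every
sample column sums to 100 (percent of total peak area). Percent rather
than proportion is cosmetic — every downstream statistic is a ratio or a
rank and is scale-invariant — but it is fixed for reproducibility, and a
double-normalization guard prevents accidental re-scaling.

## Lipid shorthand and molecular geometry

`parse_lipid_name()` handles the shorthand dialect of LipidSearch exports:
`"DG(22:6/22:6)"` (sn-resolved), `"PE(16:0_18:1)"` (unresolved),
sum-composition forms like `"PC(34:2)"`, and ether/plasmalogen chains
(`O-`/`P-` prefixes or trailing `e`/`p`). Total carbons and double bonds
are always the sum over chains; a single chain supplied for a multi-chain
subclass is treated as a sum composition carried by one pseudo-chain.
Linkage is recorded but never adjusts the double-bond totals, because the
downstream analyses use totals only. GM1 is annotated at the
sum-composition level only, as its species are not chain-resolved in this
kind of export. Subclass tokens are case-sensitive (the exports are
case-consistent), and the controlled vocabulary covers the 18 subclasses
the analyses touch.

Molecular geometry is a total mapping from subclass to shape class, by the
head-to-tail size ratio: cone (DG, PA, TG), cylinder (PC, PI), inverted
cone (LPI, LPC), everything else `unclassified`.

## Differential lipids

Subclass abundance is the per-sample sum of normalized species abundances;
when subclasses partition the features the aggregate columns still sum
to 100. Group differences are tested per subclass with an unpaired
two-sided t test and summarized as the fold change `mean(DL)/mean(HC)`.
The pooled-variance (Student's) form is the default, with Welch available
by flag. Structure profiles re-aggregate one subclass by total carbon
count or total double bonds — the bins are exactly the values observed in
the annotation set — and apply the same test per bin.

PLS-DA is fitted by NIPALS on mean-centred, unit-variance-scaled data with
a centred ±1 dummy response, the convention of SIMCA-style workflows; the
default is 2 components, matching the usual score-plot use. Variable
importance in projection is computed across all fitted components,

$$\mathrm{VIP}_j \;=\; \sqrt{\,p \cdot
  \frac{\sum_h SS_h\, w_{jh}^2}{\sum_h SS_h}\,},
  \qquad SS_h = q_h^2\, \mathbf{t}_h^\top \mathbf{t}_h ,$$

whose mean square over features is exactly 1 because each weight vector
has unit norm. A species is *discriminating* when `VIP > 1.0` **and** its
univariate two-sided t test gives `p < 0.05` — the double cutoff is a
conjunction and both thresholds are strict. The p value in the double
cutoff is the univariate t test (the conventional pairing with VIP); no
multiple-testing correction is applied anywhere, matching the stated
thresholds, though a Benjamini–Hochberg option exists off by default. The
suite cross-checks scores and VIP against `mixOmics` to machine precision
on small fixtures.

## Reaction-network activity

This is the package's analytical core. A pathway is an ordered chain of
lipid classes, read left-to-right as substrate → product; the shipped
default network is the union of six such chains
(LPC-PC-PA-DG-TG, LPC-PC-PA-LPA, LPC-LPA, DG-PC-LPC, DG-PA-PI-LPI,
LPA-PA-PG-LPG), with any user network loadable from TSV. The class
abundance $A_i$ is the per-sample sum of normalized species abundances of
class $i$ (the class-level granularity matches class-node pathway
diagrams; the source method leaves the granularity open). For each edge,

$$\omega_i = A_{i+1} / A_i$$

per sample; a one-sided Student's t test of the weights in the DL > HC
direction gives $P^+$, and

$$Z_i = \Phi^{-1}(1 - P^{+}).$$

Computing the one-sided test once, in a fixed direction, is deliberate:
$\Phi^{-1}(1-P^+)$ is negative exactly when the effect favours HC, so the
single formula realizes the "multiply by −1 for HC-active reactions"
presentation without a second test. A reaction is *active* when
$Z_i > 1.645$ (one-sided 0.05) and *inactive* when $Z_i < -1.645$.
Pathway aggregation is

$$Z_A = \frac{1}{\sqrt{k-1}} \sum_{i=1}^{k-1} Z_i ,$$

standard normal under independent null edges (verified by Monte Carlo in
the suite), so the same ±1.645 cutoff applies. Synthesis and degradation
scores for a class aggregate its incoming and outgoing edge scores with
the same formula. The t test runs on raw ω by default, following the
stated method literally; a log-ω flag exists because ratios are skewed.
The empirical size of the activity call under a null simulation with
study-sized classes (15 species per class) is 0.048–0.052 at the nominal
0.05 (5,000 simulated reactions), so the raw-ω default is well calibrated
at n = 6 + 6; with much smaller classes the class-sum ratios are more
skewed and the call becomes slightly conservative (~0.045).

Numerical details: p values are clamped to `[1e-300, 1 - 1e-16]` before
the normal quantile; zero substrate abundance in a sample drops that
sample for that edge (default) or fails, per configuration; an edge whose
class is absent from the data is skipped with a warning, and a pathway
with missing edges is `not_evaluable` unless renormalization over the
available edges is explicitly allowed; two equal constant weight vectors
give Z = 0 (`ns`).

## Differential taxa

The two-class LDA effect-size screen has two stages. Stage 1 is a
per-taxon Kruskal–Wallis test at α = 0.05 (with two classes this is the
Wilcoxon rank-sum test). Stage 2, on the survivors jointly: 30 bootstrap
rounds, each subsampling ⌈2n/3⌉ samples per class without replacement,
fitting a two-class linear discriminant (`MASS::lda`) on abundances
brought to a per-million scale, and recording per taxon the average of its
raw class-mean difference and its share of the mean difference projected
on the unit discriminant direction. The reported LDA score is
`log10(1 + mean effect)`, on the familiar scale where a strong enrichment
scores 4–6; the default pass threshold is 2.0 with the stricter 2.5
selectable. The canonical all-against-all subclass stage is omitted: with
exactly two classes and no subclass factor it is vacuous. A tiny seeded
jitter keeps within-class covariances non-degenerate (features can exceed
samples at n = 12); a fully degenerate bootstrap round is skipped and
counted. The bootstrap is seeded and exactly reproducible; exchanging
class labels flips every enrichment call and leaves the rank-test p values
identical (the bootstrapped scores are equal in distribution, not bitwise,
since the subsample draws differ).

## Co-occurrence network

All pairwise Spearman correlations (midranks for ties) among the aligned
node blocks — taxa, lipid species, behaviors — with edges retained when
`p < 0.05` **and** `|rho| > 0.70`, both strict. P values use the
t approximation on n − 2 degrees of freedom by default; an exact
permutation p (via `cor.test`, tie-free case) is available and matters at
the study's n = 12, where |rho| = 0.9 at n = 5 is *not* significant
exactly. Constant node vectors are excluded with a warning. Export is
GraphML (node kind, edge rho/p attributes) plus a flat edge TSV; layout is
deliberately out of scope, and cluster membership, if requested, is the
connected components of the thresholded graph — a reimplementation choice,
not the published layout algorithm.

## The synthetic generator

The generator's defaults are the study conditions: 6 animals per group;
tissues PFC, AMY, HIP, plasma; ~1,940 brain and ~1,560 plasma species
across 14 subclasses (DG = 15 and PA = 108 in brain, matching the sizes
of the species lists analysed downstream); brain DG chains span 34–40
carbons with 2–6 double bonds and plasma DG 49–54 with 0–3. Peak areas
are lognormal — MS peak areas are strictly positive and right-skewed —
with a per-feature log-mean (spread 1) and within-feature log-sd 0.4, and
group effects act multiplicatively, matching the fold-change
parameterization of the differential analyses. The source study states no
abundance distribution or variance; these are generator choices, made
once. QC failures are planted at an exact count with the failing
criterion drawn uniformly. Microbiome zeros are structural (set before
closure to column sums of 1); lipid tables contain no zeros, since
QC-passing MS features are quantified. Behavior coupling blends feature
ranks with noise ranks at weight `|strength|`, so the target Spearman
strength is directly interpretable and `noise_sd = 0` yields rho = ±1
exactly; durations are a positive monotone (exponential) transform of the
blended score, which preserves rank correlations exactly.

What the generator does *not* emulate: correlated species within a
subclass (co-regulation), heavy-tailed or missing-at-random peak areas,
compositional coupling between lipid classes beyond closure, phylogenetic
correlation among taxa, or behavioral time structure. Passing recovery
tests therefore demonstrates that the statistical machinery is correct
and calibrated under the declared generating process, not that the
biological effect sizes of any real study are reproduced.

### Null-screen fixture

The null calibration of the rank screen uses `zero_inflation = 0`:
structural zeros create heavy ties, which make rank tests conservative
and would mix the generator's zero process into what is meant to be a
calibration of the test itself.

### Fixture sizes in the test suite

Property and recovery tests run on deliberately small instances so the
default suite completes in about a minute: 50–70-species lipidomes,
40-taxon microbiomes, 50-replicate recovery loops, 5,000 simulated null
reactions, and 10,000 Monte-Carlo pathways. The bin-level (chain-length)
recovery test uses 40 DG species so each carbon bin sums over several
species; with one species per bin the bin abundance inherits the full
lognormal coefficient of variation and the check measures single-feature
noise rather than the binned test. The planted-pathway recovery test
grades fold changes 1→2→4→8→16 along LPC-PC-PA-DG-TG, i.e. a uniform
2-fold step on every reaction weight — a strong, unambiguous flux signal.

## Known limitations

- The shipped reaction network is the six published chains, not a full
  Reactome-derived network, which is not reconstructible from the
  printed material; any network can be supplied as TSV.
- The LDA effect size is a faithful re-implementation of the canonical
  convention but small numerical differences from other LEfSe ports are
  expected (jitter, solver, subsample draws).
- Headline biological counts from the original data (72 discriminating
  species, 33 + 14 differential taxa) depend on raw data that is not
  available; the package reproduces the *procedures* and the printed
  self-contained quantities, and validates recovery on planted effects.
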