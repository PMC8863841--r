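# lipidaxis

Analytics for two-group microbiota-gut-brain studies that combine
untargeted MS lipidomics of brain tissue and plasma, shotgun-metagenomic
taxon profiles, and scored behaviors. The package is aimed at analysts who
receive *processed* tables — a LipidSearch-style peak-area export with QC
fields, a relative-abundance taxon table with rank-prefixed lineages, and
per-animal behavior durations — and need a reproducible, tested route from
those tables to differential lipids, lipid pathway flux calls, differential
taxa, and a cross-omics co-occurrence network.

## What it computes

- **Lipid shorthand parsing** — `"DG(22:6/22:6)"`, `"PC(34:2)"`,
  ether/plasmalogen dialects — into subclass, per-chain and total
  carbons/double bonds, and molecular geometry class (cone: DG/PA/TG;
  cylinder: PC/PI; inverted cone: LPI/LPC).
- **QC filtering and normalization**: retain features with `Rej == 0`,
  `PQ > 0.85`, `CV < 0.3`, `|ppm| <= 5`; normalize each sample to percent
  of total peak area.
- **Differential lipids**: subclass fold changes with unpaired t tests,
  chain-length and unsaturation profiles, and PLS-DA (NIPALS, autoscaled)
  with the VIP > 1.0 & p < 0.05 double cutoff. VIP has mean square 1 by
  construction.
- **Reaction-network activity** (the core method): for each pathway edge
  the per-sample reaction weight ω = A(product)/A(substrate); a one-sided
  Student's t test between groups converted to Z = Φ⁻¹(1 − P), active when
  Z > 1.645, inactive when Z < −1.645; pathway aggregation
  Z_A = Σ Zᵢ / √(k−1); synthesis/degradation scores per lipid class.
- **Differential taxa**: a two-class LDA effect-size screen
  (Kruskal–Wallis at 0.05, then bootstrapped linear discriminant effect
  sizes on a per-million scale, LDA score threshold 2.0, with 2.5
  selectable).
- **Co-occurrence network**: all pairwise Spearman correlations among
  taxa, lipid species and behaviors; edges kept when p < 0.05 and
  |ρ| > 0.70; GraphML + TSV export.
- **Synthetic data**: seeded generators for lipidome, microbiome and
  behavior tables with planted, recoverable effects, emulating the
  two-group (n = 6), four-tissue study design.

## Worked example

Simulate a prefrontal-cortex lipidome with a planted 1.38-fold DG increase,
filter, normalize, and run the subclass and pathway analyses:

```r
library(lipidaxis)

cfg <- lipidome_sim_config(
  n_per_group = 6, tissues = "PFC",
  n_species_per_subclass = c(DG = 15, PC = 30, PA = 20, LPC = 10, TG = 15,
                             LPA = 6, PI = 10, LPI = 6, PG = 8, LPG = 6),
  subclass_effects = data.frame(tissue = "PFC", subclass = "DG",
                                fold_change = 1.38),
  qc_fail_fraction = 0.1, seed = 42)
sim <- generate_lipidome(cfg)

filtered <- apply_qc_filters(sim$PFC$table, sim$PFC$qc)
tab <- normalize_total_area(filtered)
ann <- sim$PFC$annotations

res <- subclass_test(subclass_abundance(tab, ann), ft_groups(tab), ann)
res[order(res$p_value), ][1:4, ]
#>  subclass fold_change      t p_value n_species
#>        DG       1.194  2.468  0.0332        15
#>       LPI       0.875 -1.085  0.3033         6
#>       LPG       1.107  0.961  0.3591         6
#>        TG       0.917 -0.829  0.4263        15

net  <- reaction_network()
acts <- reaction_activities(class_abundance(tab, ann), net, ft_groups(tab))
pathway_activities(acts, net)
#>          pathway k n_edges    z_a  verdict
#>  LPC-PC-PA-DG-TG 5       4  0.292       ns
#>    LPC-PC-PA-LPA 4       3  0.928       ns
#>          LPC-LPA 2       1  1.163       ns
#>        DG-PC-LPC 3       2 -1.686 inactive
#>     DG-PA-PI-LPI 4       3 -1.302       ns
#>    LPA-PA-PG-LPG 4       3  0.164       ns

synthesis_degradation(net, acts, "DG")[c("z_synthesis", "z_degradation")]
#> $z_synthesis   1.36
#> $z_degradation -2.95
```

At this single seed the planted DG increase is detected (FC = 1.19,
p = 0.033; the fold-change estimate at n = 6 is noisy, and its median over
replicates sits within a few percent of 1.38 — see the test suite), and the
machinery attributes the DG accumulation to suppressed outgoing flux: both
DG-consuming pathways score negative and the DG degradation score is
−2.95 (inactive) while synthesis is not significant.

The whole pipeline — simulation through network export, with a manifest of
checksums and seeds — runs as:

```r
run_pipeline(default_config(seed = 1), outdir = "run1")
```

or from the shell via `inst/scripts/pipeline.R`.

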