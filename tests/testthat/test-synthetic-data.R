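test_that("lipidome generation is deterministic under a fixed seed", {
  cfg <- small_lipidome_cfg(seed = 9, qc_fail_fraction = 0.1)
  s1 <- generate_lipidome(cfg)
  s2 <- generate_lipidome(cfg)
  expect_identical(s1$PFC$table$values, s2$PFC$table$values)
  expect_identical(s1$PFC$qc, s2$PFC$qc)
  expect_identical(s1$PFC$annotations, s2$PFC$annotations)
})

test_that("generated species names are well-formed and tissue-appropriate", {
  cfg <- lipidome_sim_config(tissues = c("PFC", "plasma"),
                             n_species_per_subclass = c(DG = 12, PC = 10),
                             seed = 3)
  sim <- generate_lipidome(cfg)
  for (tissue in c("PFC", "plasma")) {
    ann <- annotate_species(rownames(sim[[tissue]]$table$values))
    expect_false(anyNA(ann$subclass))
    dg <- ann[ann$subclass == "DG", ]
    if (tissue == "PFC") {
      expect_true(all(dg$total_carbons >= 34 & dg$total_carbons <= 40))
      expect_true(all(dg$total_double_bonds >= 2 & dg$total_double_bonds <= 6))
    } else {
      expect_true(all(dg$total_carbons >= 49 & dg$total_carbons <= 54))
      expect_true(all(dg$total_double_bonds <= 3))
    }
  }
})

test_that("a planted DG fold change is recovered from the raw matrix at n=100", {
  cfg <- small_lipidome_cfg(
    seed = 21, n_per_group = 100,
    subclass_effects = data.frame(tissue = "PFC", subclass = "DG",
                                  fold_change = 1.38))
  sim <- generate_lipidome(cfg)
  ann <- sim$PFC$annotations
  g <- ft_groups(sim$PFC$table)
  dg <- colSums(sim$PFC$table$values[ann$subclass == "DG", ])
  ratio <- mean(dg[g == "DL"]) / mean(dg[g == "HC"])
  expect_gt(ratio, 1.38 * 0.9)
  expect_lt(ratio, 1.38 * 1.1)
})

test_that("the planted QC failure count is exact", {
  cfg <- lipidome_sim_config(tissues = "PFC",
                             n_species_per_subclass = c(PC = 500, PE = 500),
                             qc_fail_fraction = 0.25, seed = 5)
  sim <- generate_lipidome(cfg)
  keep <- qc_filter_oracle(sim$PFC$qc)
  expect_equal(sum(!keep), 250L)
  expect_equal(sum(keep), 750L)
  # configuration errors name the offender
  expect_error(lipidome_sim_config(subclass_effects = data.frame(
    tissue = "PFC", subclass = "NOTALIPID", fold_change = 2)), "NOTALIPID")
  expect_error(lipidome_sim_config(subclass_effects = data.frame(
    tissue = "PFC", subclass = "DG", fold_change = -1)), "positive")
})

test_that("microbiome tables are compositional, deterministic and parseable", {
  cfg <- microbiome_sim_config(n_taxa = 50, zero_inflation = 0.2, seed = 8)
  t1 <- generate_microbiome(cfg)
  t2 <- generate_microbiome(cfg)
  expect_identical(t1$values, t2$values)
  expect_true(all(abs(colSums(t1$values) - 1) < 1e-9))
  for (ln in t1$lineages) expect_length(parse_lineage(ln), 7)
  expect_error(microbiome_sim_config(
    n_taxa = 2,
    differential_taxa = data.frame(taxon = 1:3, enriched_class = "DL",
                                   multiplier = 2)), "n_taxa")
})

test_that("a multiplier-8 differential taxon is enriched in every replicate", {
  hits <- vapply(1:50, function(i) {
    cfg <- microbiome_sim_config(
      n_taxa = 30,
      differential_taxa = data.frame(taxon = 1, enriched_class = "DL",
                                     multiplier = 8),
      zero_inflation = 0.1, seed = 1000 + i)
    tt <- generate_microbiome(cfg)
    g <- tt$sample_info$group
    mean(tt$values[1, g == "DL"]) > mean(tt$values[1, g == "HC"])
  }, logical(1))
  expect_true(all(hits))
})

test_that("under a global null the rank-test screen passes ~5% of taxa", {
  cfg <- microbiome_sim_config(n_taxa = 1000, zero_inflation = 0, seed = 77)
  tt <- generate_microbiome(cfg)
  g <- tt$sample_info$group
  p <- apply(tt$values, 1, function(v) kruskal.test(v, factor(g))$p.value)
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), 2 * se + 0.01)
})

test_that("behavior coupling honours sign, strength and determinism", {
  np <- normalized_pfc(seed = 4)
  feat <- rownames(np$table$values)[1]
  cfg0 <- behavior_sim_config(
    couplings = data.frame(behavior = "huddle", feature = feat, strength = 1),
    noise_sd = 0, seed = 2)
  b <- generate_behaviors(cfg0, np$table)
  expect_identical(b$values, generate_behaviors(cfg0, np$table)$values)
  expect_true(all(b$values > 0))
  rho <- cor(b$values["huddle", ], np$table$values[feat, ], method = "spearman")
  expect_equal(rho, 1)                      # exact monotone transform
  cfgneg <- behavior_sim_config(
    couplings = data.frame(behavior = "locomotion", feature = feat,
                           strength = -1),
    noise_sd = 0, seed = 2)
  bn <- generate_behaviors(cfgneg, np$table)
  expect_equal(cor(bn$values["locomotion", ], np$table$values[feat, ],
                   method = "spearman"), -1)
  expect_error(generate_behaviors(
    behavior_sim_config(couplings = data.frame(
      behavior = "huddle", feature = "NOPE(1:0)", strength = 0.5)),
    np$table), "NOPE\\(1:0\\)")
})

test_that("a strength-0.95 coupling is recovered with the right sign", {
  np <- normalized_pfc(seed = 6)
  feat <- rownames(np$table$values)[3]
  hits <- vapply(1:100, function(i) {
    cfg <- behavior_sim_config(
      couplings = data.frame(behavior = "huddle", feature = feat,
                             strength = 0.95),
      noise_sd = 1, seed = 5000 + i)
    b <- generate_behaviors(cfg, np$table)
    x <- np$table$values[feat, ]
    y <- b$values["huddle", ]
    rho <- cor(x, y, method = "spearman")
    p <- cor.test(x, y, method = "spearman", exact = FALSE)$p.value
    rho > 0.70 && p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("uncoupled behaviors match the permutation null edge rate", {
  np <- normalized_pfc(seed = 13)
  feat <- rownames(np$table$values)[1]
  x <- np$table$values[feat, ]
  n <- length(x)
  edge <- function(y) {
    rho <- cor(x, y, method = "spearman")
    p <- if (abs(rho) >= 1) 0 else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tt), n - 2)
    }
    abs(rho) > 0.70 && p < 0.05
  }
  obs <- vapply(1:200, function(i) {
    cfg <- behavior_sim_config(couplings = NULL, noise_sd = 1, seed = 9000 + i)
    edge(generate_behaviors(cfg, np$table)$values["huddle", ])
  }, logical(1))
  set.seed(321)   # permutation oracle for the same criterion
  perm <- vapply(1:2000, function(i) edge(sample(x)), logical(1))
  tol <- 2 * sqrt(mean(perm) * (1 - mean(perm)) * (1 / 200 + 1 / 2000)) + 0.02
  expect_lt(abs(mean(obs) - mean(perm)), tol)
})
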