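test_that("subclass aggregation is additive, conserving and order-invariant", {
  np <- normalized_pfc(seed = 1)
  mat <- subclass_abundance(np$table, np$annotations)
  # additivity: DG row equals the sum of DG species
  dg_species <- np$annotations$name[np$annotations$subclass == "DG"]
  expect_equal(mat["DG", ], colSums(np$table$values[dg_species, ]))
  # conservation: subclasses partition the features, columns sum to 100
  expect_true(all(abs(colSums(mat) - 100) < 1e-9))
  # permuting feature order leaves the matrix unchanged
  perm <- sample(nrow(np$table$values))
  shuffled <- subset_features(np$table, perm)
  shuffled$normalized <- TRUE
  expect_equal(subclass_abundance(shuffled, np$annotations)[rownames(mat), ],
               mat)
  # unannotated features error unless skip policy is chosen
  extra <- np$table
  rownames(extra$values)[1] <- "mystery_feature"
  expect_error(subclass_abundance(extra, np$annotations), "mystery_feature")
  expect_message(subclass_abundance(extra, np$annotations, unparseable = "skip"),
                 "skipping 1")
})

test_that("subclass tests handle identical, shifted and degenerate groups", {
  mat <- rbind(DG = c(5, 5, 5, 5, 5, 5))
  colnames(mat) <- paste0("s", 1:6)
  g <- rep(c("DL", "HC"), each = 3)
  r <- subclass_test(mat, g)
  expect_equal(r$fold_change, 1)
  expect_equal(r$p_value, 1)
  set.seed(2)
  mat2 <- rbind(DG = c(2, 2, 2, 1, 1, 1) + rnorm(6, 0, 1e-6))
  colnames(mat2) <- paste0("s", 1:6)
  r2 <- subclass_test(mat2, g)
  expect_equal(r2$fold_change, 2, tolerance = 1e-4)
  expect_lt(r2$p_value, 1e-6)
  # zero control mean flags the fold change rather than erroring
  mat3 <- rbind(PA = c(1, 2, 3, 0, 0, 0))
  colnames(mat3) <- paste0("s", 1:6)
  expect_true(is.na(subclass_test(mat3, g)$fold_change))
})

test_that("a planted 1.38 DG fold change is recovered in the median over replicates", {
  fcs <- vapply(1:50, function(i) {
    np <- normalized_pfc(
      seed = 300 + i,
      subclass_effects = data.frame(tissue = "PFC", subclass = "DG",
                                    fold_change = 1.38))
    mat <- subclass_abundance(np$table, np$annotations)
    subclass_test(mat, ft_groups(np$table))$fold_change[
      rownames(mat) == "DG"]
  }, numeric(1))
  med <- median(fcs)
  expect_gte(med, 1.30)
  expect_lte(med, 1.46)
})

test_that("structure profiles bin by totals and conserve subclass abundance", {
  np <- normalized_pfc(seed = 11)
  g <- ft_groups(np$table)
  prof <- structure_profile(np$table, np$annotations, "DG", "total_carbons", g)
  # species with equal totals share a bin
  ann_dg <- np$annotations[np$annotations$subclass == "DG", ]
  expect_setequal(prof$bin, unique(ann_dg$total_carbons))
  expect_equal(prof$n_species[order(prof$bin)],
               as.integer(table(ann_dg$total_carbons)))
  # partition conservation: bin means sum to the subclass mean
  mat <- subclass_abundance(np$table, np$annotations)
  expect_equal(sum(prof$mean_case), mean(mat["DG", g == "DL"]))
  expect_equal(sum(prof$mean_control), mean(mat["DG", g == "HC"]))
  expect_warning(structure_profile(np$table, np$annotations, "MG",
                                   "total_carbons", g), "no MG species")
})

test_that("a planted chain-length enrichment is flagged in most replicates", {
  # 40 DG species so each carbon bin sums over several species: bin-level
  # power reflects the test, not single-species abundance noise
  hits <- vapply(1:50, function(i) {
    np <- normalized_pfc(
      seed = 700 + i,
      counts = c(DG = 40, PC = 10, PA = 8, LPC = 6, TG = 6),
      chain_effects = data.frame(tissue = "PFC", subclass = "DG",
                                 total_carbons = 36, fold_change = 2))
    prof <- structure_profile(np$table, np$annotations, "DG",
                              "total_carbons", ft_groups(np$table))
    any(prof$bin == 36 & prof$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("PLS-DA satisfies the VIP normalization and symmetry properties", {
  np <- normalized_pfc(seed = 5)
  g <- ft_groups(np$table)
  m <- plsda_fit(np$table, g, n_components = 2)
  expect_equal(mean(m$vip^2), 1, tolerance = 1e-6)
  expect_equal(sum(m$explained_y_variance > 0), 2L)
  # duplicated feature column gets an identical VIP
  vals <- np$table$values
  vals <- rbind(vals, `dup_feature` = vals[1, ])
  m2 <- plsda_fit(vals, g)
  expect_equal(unname(m2$vip["dup_feature"]),
               unname(m2$vip[rownames(np$table$values)[1]]), tolerance = 1e-9)
  # zero-variance features are dropped with a log message
  vals2 <- rbind(np$table$values, flat = rep(1, ncol(vals)))
  expect_message(m3 <- plsda_fit(vals2, g), "zero-variance")
  expect_false("flat" %in% m3$features)
  expect_error(plsda_fit(np$table, g, n_components = 50), "n_components")
})

test_that("a single perfectly separating feature attains the maximum VIP", {
  set.seed(8)
  n <- 12; p <- 15
  X <- matrix(rnorm(p * n), nrow = p,
              dimnames = list(paste0("f", 1:p), paste0("s", 1:n)))
  g <- rep(c("DL", "HC"), each = 6)
  X["f1", ] <- ifelse(g == "DL", 10, -10) + rnorm(n, 0, 0.01)
  m <- plsda_fit(X, g, n_components = 1)
  expect_equal(names(which.max(m$vip)), "f1")
  # one-component closed form: VIP_j = sqrt(p) * |w_j| / ||w||
  w <- m$weights[, 1]
  expect_equal(unname(m$vip), unname(sqrt(length(w)) * abs(w) / sqrt(sum(w^2))),
               tolerance = 1e-10)
})

test_that("PLS-DA scores and VIP agree with an independent implementation", {
  set.seed(31)
  p <- 25; n <- 14
  X <- matrix(rexp(p * n), nrow = p,
              dimnames = list(paste0("f", 1:p), paste0("s", 1:n)))
  g <- rep(c("DL", "HC"), each = 7)
  X[1:3, g == "DL"] <- X[1:3, g == "DL"] * 3
  m <- plsda_fit(X, g, n_components = 2)
  ref <- mixOmics::plsda(t(X), factor(g), ncomp = 2, scale = TRUE)
  vip_ref <- mixOmics::vip(ref)[names(m$vip), 2]
  expect_equal(unname(m$vip), unname(vip_ref), tolerance = 1e-8)
  for (h in 1:2)
    expect_equal(abs(cor(m$scores[, h], ref$variates$X[, h])), 1,
                 tolerance = 1e-8)
})

test_that("the VIP/p double cutoff excludes on either criterion alone", {
  np <- normalized_pfc(
    seed = 14,
    subclass_effects = data.frame(tissue = "PFC", subclass = "DG",
                                  fold_change = 3))
  g <- ft_groups(np$table)
  m <- plsda_fit(np$table, g)
  disc <- discriminating_species(np$table, g, m)
  expect_true(all(disc$vip > 1.0))
  expect_true(all(disc$p_value < 0.05))
  # manual reconstruction of the double cutoff over all features
  all_p <- vapply(m$features, function(f) {
    t.test(np$table$values[f, g == "DL"], np$table$values[f, g == "HC"],
           var.equal = TRUE)$p.value
  }, numeric(1))
  manual <- sort(names(which(m$vip > 1.0 & all_p < 0.05)))
  expect_setequal(disc$species, manual)
  # direction matches the sign of the mean difference
  for (k in seq_len(min(5, nrow(disc)))) {
    f <- disc$species[k]
    up <- mean(np$table$values[f, g == "DL"]) > mean(np$table$values[f, g == "HC"])
    expect_equal(disc$direction[k], if (up) "up_in_DL" else "down_in_DL")
  }
})

test_that("planted discriminators are recalled by the double cutoff", {
  recalls <- vapply(1:50, function(i) {
    np <- normalized_pfc(
      seed = 1200 + i,
      counts = c(DG = 10, PC = 20, PA = 15, LPC = 8, TG = 7),
      subclass_effects = data.frame(tissue = "PFC", subclass = "DG",
                                    fold_change = 3))
    g <- ft_groups(np$table)
    m <- plsda_fit(np$table, g)
    disc <- discriminating_species(np$table, g, m)
    planted <- np$annotations$name[np$annotations$subclass == "DG"]
    mean(planted %in% disc$species)
  }, numeric(1))
  expect_gte(mean(recalls), 0.8)
})
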