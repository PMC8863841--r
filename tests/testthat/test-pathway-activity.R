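test_that("the default reaction network encodes the six pathway chains", {
  net <- reaction_network()
  expect_length(net$pathways, 6)
  expect_equal(net$pathways[["LPC-PC-PA-DG-TG"]],
               c("LPC", "PC", "PA", "DG", "TG"))
  expect_false(any(net$edges$substrate == net$edges$product))
  # every pathway edge exists in the edge set
  for (chain in net$pathways) {
    k <- length(chain)
    for (i in seq_len(k - 1))
      expect_true(any(net$edges$substrate == chain[i] &
                        net$edges$product == chain[i + 1]))
  }
  expect_error(reaction_network(list(bad = c("DG", "DG"))), "self-loop")
})

test_that("reaction networks round-trip through the TSV interface", {
  net <- reaction_network()
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  rows <- do.call(rbind, lapply(names(net$pathways), function(nm) {
    chain <- net$pathways[[nm]]
    data.frame(pathway_id = nm, step_index = seq_len(length(chain) - 1),
               substrate = chain[-length(chain)], product = chain[-1])
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_reaction_tsv(path)
  expect_equal(back$pathways[sort(names(back$pathways))],
               net$pathways[sort(names(net$pathways))])
})

test_that("reaction weights are per-sample ratios with a zero-substrate policy", {
  A <- rbind(PA = c(2, 4), DG = c(1, 1))
  colnames(A) <- c("s1", "s2")
  expect_equal(reaction_weights(A, "PA", "DG"), c(s1 = 0.5, s2 = 0.25))
  # scale invariance per sample
  A2 <- A; A2[, 1] <- A2[, 1] * 1000
  expect_equal(reaction_weights(A2, "PA", "DG"),
               reaction_weights(A, "PA", "DG"))
  A3 <- rbind(PA = c(0, 4, 2), DG = c(1, 1, 1))
  colnames(A3) <- paste0("s", 1:3)
  expect_warning(w <- reaction_weights(A3, "PA", "DG"), "zero substrate")
  expect_length(w, 2)
  expect_error(reaction_weights(A3, "PA", "DG", zero_policy = "fail"), "s1")
  expect_error(reaction_weights(A, "PA", "TG"), "TG")
})

test_that("reaction Z scores follow the inverse-normal transform and verdicts", {
  # identical weight vectors: P = 0.5, z = 0, ns
  w <- c(1, 2, 3, 4, 5, 6)
  r <- reaction_z(w, w)
  expect_equal(r$z, 0, tolerance = 1e-12)
  expect_equal(r$p_one_sided, 0.5)
  expect_equal(r$verdict, "ns")
  # the z value is exactly qnorm(1 - P)
  set.seed(4)
  a <- rlnorm(6); b <- rlnorm(6) * 2
  r2 <- reaction_z(a, b)
  p_ref <- t.test(a, b, alternative = "greater", var.equal = TRUE)$p.value
  expect_equal(r2$z, qnorm(1 - p_ref), tolerance = 1e-12)
  # swapping the groups negates z (antisymmetry of the one-sided test)
  r3 <- reaction_z(b, a)
  expect_equal(r3$z, -r2$z, tolerance = 1e-9)
  # degenerate equal-constant groups are ns at z = 0
  r4 <- reaction_z(c(1, 1, 1), c(1, 1, 1))
  expect_equal(r4$z, 0)
  expect_equal(r4$verdict, "ns")
  expect_error(reaction_z(1, c(1, 2)), "at least 2")
})

test_that("the critical value machinery reproduces the 1.645 cutoff", {
  expect_equal(z_critical(0.05), qnorm(0.95))
  expect_equal(round(z_critical(0.05), 3), 1.645)
  # verdicts flip exactly at the cutoff
  expect_equal(pathway_z(1.65, k = 2)$verdict, "active")
  expect_equal(pathway_z(1.64, k = 2)$verdict, "ns")
  expect_equal(pathway_z(-1.65, k = 2)$verdict, "inactive")
})

test_that("pathway aggregation matches the 1/sqrt(k-1) formula", {
  r <- pathway_z(rep(1.645, 4), k = 5)
  expect_equal(r$z_a, 4 * 1.645 / 2)
  expect_equal(r$verdict, "active")
  expect_equal(pathway_z(rep(0, 3), k = 4)$z_a, 0)
  expect_equal(pathway_z(rep(0, 3), k = 4)$verdict, "ns")
  # 2-node pathway: Z_A equals the single edge z exactly
  expect_equal(pathway_z(1.2, k = 2)$z_a, 1.2)
  expect_error(pathway_z(c(1, 2), k = 4), "expected 3")
})

test_that("aggregated pathway scores are standard normal under the null", {
  set.seed(99)
  z_a <- vapply(1:10000, function(i) pathway_z(rnorm(4), k = 5)$z_a,
                numeric(1))
  ks <- ks.test(z_a, "pnorm")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(z_a)), 0.05)
  expect_lt(abs(sd(z_a) - 1), 0.05)
})

test_that("activity scores are scale invariant and label-antisymmetric", {
  np <- normalized_pfc(seed = 23)
  net <- reaction_network()
  g <- ft_groups(np$table)
  A <- class_abundance(np$table, np$annotations)
  acts <- reaction_activities(A, net, g)
  # multiplying any sample's abundances by a constant changes nothing
  raw <- generate_lipidome(small_lipidome_cfg(seed = 23))$PFC
  scaled_vals <- raw$table$values
  scaled_vals[, 3] <- scaled_vals[, 3] * 57.3
  scaled_tab <- normalize_total_area(
    feature_table(scaled_vals, group = g, tissue = "PFC"))
  A_s <- class_abundance(scaled_tab, np$annotations)
  acts_s <- reaction_activities(A_s, net, g)
  expect_equal(acts_s$z, acts$z, tolerance = 1e-9)
  # exchanging group labels negates every z and swaps the verdicts
  g_swap <- ifelse(g == "DL", "HC", "DL")
  acts_swap <- reaction_activities(A, net, g_swap)
  expect_equal(acts_swap$z, -acts$z, tolerance = 1e-9)
  pw <- pathway_activities(acts, net)
  pw_swap <- pathway_activities(acts_swap, net)
  expect_equal(pw_swap$z_a, -pw$z_a, tolerance = 1e-9)
  swap_map <- c(active = "inactive", inactive = "active", ns = "ns")
  expect_equal(unname(swap_map[pw$verdict]), pw_swap$verdict)
})

test_that("missing classes skip edges and partial pathways are flagged", {
  np <- normalized_pfc(seed = 2, counts = c(DG = 8, PC = 8, PA = 8, TG = 6))
  net <- reaction_network()
  A <- class_abundance(np$table, np$annotations)
  warns <- capture_warnings(
    acts <- reaction_activities(A, net, ft_groups(np$table)))
  expect_true(any(grepl("skipped: class absent", warns)))
  pw <- suppressMessages(pathway_activities(acts, net))
  expect_equal(pw$verdict[pw$pathway == "LPC-LPA"], "not_evaluable")
  pw2 <- suppressMessages(pathway_activities(acts, net, allow_partial = TRUE))
  # only LPC->PC is missing; the remaining 3 edges renormalize
  expect_equal(pw2$n_edges[pw2$pathway == "LPC-PC-PA-DG-TG"], 3L)
  expect_false(is.na(pw2$z_a[pw2$pathway == "LPC-PC-PA-DG-TG"]))
})

test_that("synthesis/degradation aggregate incoming and outgoing edges", {
  np <- normalized_pfc(seed = 3)
  net <- reaction_network()
  A <- class_abundance(np$table, np$annotations)
  acts <- reaction_activities(A, net, ft_groups(np$table))
  sd_tg <- synthesis_degradation(net, acts, "TG")
  # TG has a single incoming edge DG->TG and no outgoing edges
  expect_equal(sd_tg$n_in, 1L)
  expect_equal(sd_tg$z_synthesis,
               acts$z[acts$substrate == "DG" & acts$product == "TG"])
  expect_equal(sd_tg$verdict_degradation, "undefined")
  expect_true(is.na(sd_tg$z_degradation))
  sd_dg <- synthesis_degradation(net, acts, "DG")
  expect_equal(sd_dg$n_in, 1L)   # PA->DG
  expect_equal(sd_dg$n_out, 3L)  # DG->TG, DG->PC, DG->PA
  expect_equal(sd_dg$z_degradation,
               sum(acts$z[acts$substrate == "DG"]) / sqrt(3))
  expect_error(synthesis_degradation(net, acts, "SM"), "no incoming")
})

test_that("DG accumulation from suppressed outgoing flux is detected", {
  hits <- vapply(1:50, function(i) {
    np <- normalized_pfc(
      seed = 2500 + i,
      subclass_effects = data.frame(tissue = "PFC", subclass = "DG",
                                    fold_change = 3))
    net <- reaction_network()
    A <- class_abundance(np$table, np$annotations)
    acts <- reaction_activities(A, net, ft_groups(np$table))
    sd_dg <- synthesis_degradation(net, acts, "DG")
    sd_dg$z_degradation < -1.645
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("synthesis and degradation scores are centred under the null", {
  zs <- t(vapply(1:50, function(i) {
    np <- normalized_pfc(seed = 4000 + i)
    net <- reaction_network()
    A <- class_abundance(np$table, np$annotations)
    acts <- reaction_activities(A, net, ft_groups(np$table))
    sd_dg <- synthesis_degradation(net, acts, "DG")
    c(sd_dg$z_synthesis, sd_dg$z_degradation)
  }, numeric(2)))
  expect_lt(abs(mean(zs[, 1])), 0.5)
  expect_lt(abs(mean(zs[, 2])), 0.5)
})
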