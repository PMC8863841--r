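# Shared fixtures and independent brute-force oracles.

small_lipidome_cfg <- function(seed = 1, n_per_group = 6,
                               subclass_effects = NULL,
                               chain_effects = NULL, unsat_effects = NULL,
                               qc_fail_fraction = 0,
                               counts = c(DG = 10, PC = 10, PA = 8, LPC = 6,
                                          TG = 6, LPA = 4, PI = 5, LPI = 4,
                                          PG = 4, LPG = 4)) {
  lipidome_sim_config(
    n_per_group = n_per_group, tissues = "PFC",
    n_species_per_subclass = counts,
    subclass_effects = subclass_effects, chain_effects = chain_effects,
    unsat_effects = unsat_effects,
    qc_fail_fraction = qc_fail_fraction, seed = seed)
}

normalized_pfc <- function(seed = 1, ...) {
  sim <- generate_lipidome(small_lipidome_cfg(seed = seed, ...))
  list(table = normalize_total_area(sim$PFC$table),
       annotations = sim$PFC$annotations, qc = sim$PFC$qc)
}

# brute-force QC filter: evaluates each criterion feature by feature
qc_filter_oracle <- function(qc, th = qc_thresholds()) {
  keep <- logical(nrow(qc))
  for (i in seq_len(nrow(qc))) {
    keep[i] <- (qc$rej[i] == th$rej_eq) && (qc$pq[i] > th$pq_gt) &&
      (qc$cv[i] < th$cv_lt) && (abs(qc$ppm[i]) <= th$ppm_le)
  }
  keep
}

# brute-force Spearman edge set: explicit midrank transform + pairwise loop
spearman_oracle <- function(values, rho_threshold = 0.70, alpha = 0.05) {
  n <- nrow(values)
  ranks <- apply(values, 2, rank, ties.method = "average")
  ids <- colnames(values)
  out <- NULL
  for (i in seq_len(ncol(values) - 1)) {
    for (j in seq((i + 1), ncol(values))) {
      r <- stats::cor(ranks[, i], ranks[, j])
      p <- if (abs(r) >= 1) 0 else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        2 * stats::pt(-abs(tt), n - 2)
      }
      if (abs(r) > rho_threshold && p < alpha) {
        out <- rbind(out, data.frame(
          a = min(ids[i], ids[j]), b = max(ids[i], ids[j]),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) out <- data.frame(a = character(0), b = character(0))
  out[order(out$a, out$b), , drop = FALSE]
}

# random valid molecular-species names for parser property tests
random_lipid_names <- function(n, seed) {
  set.seed(seed)
  two_chain <- c("PC", "PE", "PA", "PG", "PI", "PS", "DG", "Cer", "SM")
  one_chain <- c("LPC", "LPE", "LPA", "LPI", "LPG", "MG", "So")
  replicate(n, {
    if (runif(1) < 0.5) {
      sc <- sample(two_chain, 1)
      sep <- sample(c("/", "_"), 1)
      sprintf("%s(%d:%d%s%d:%d)", sc, sample(10:24, 1), sample(0:6, 1),
              sep, sample(10:24, 1), sample(0:6, 1))
    } else {
      sc <- sample(one_chain, 1)
      sprintf("%s(%d:%d)", sc, sample(12:24, 1), sample(0:6, 1))
    }
  })
}

# Count-level stand-ins for the published species lists (synthetic names,
# published cardinalities): 33 differential viruses of which 25 Caudovirales,
# 14 differential bacteria of which 9 Firmicutes, 15 DG species with 10
# shared across the three brain regions, 108 PA species with 71 shared, and
# 1591 plasma species with 548 found in brain.
printed_count_fixtures <- function() {
  viral <- data.frame(
    species = sprintf("virus_%02d", 1:33),
    family = c(rep("Myoviridae", 7), rep("Siphoviridae", 4),
               rep("Caudovirales_unclassified", 2), rep("Inoviridae", 3),
               rep("Podoviridae", 6), rep("Siphoviridae", 6),
               rep("Microviridae", 5)),
    stringsAsFactors = FALSE)
  caudo <- c("Myoviridae", "Siphoviridae", "Podoviridae",
             "Caudovirales_unclassified")
  viral$order <- ifelse(viral$family %in% caudo, "Caudovirales", "other")
  bacterial <- data.frame(
    species = sprintf("bact_%02d", 1:14),
    phylum = c(rep("Firmicutes", 9), rep("Bacteroidetes", 3),
               rep("Proteobacteria", 2)),
    stringsAsFactors = FALSE)
  shared_dg <- sprintf("DG_shared_%02d", 1:10)
  dg_sets <- list(
    PFC = c(shared_dg, "DG_pfc_1", "DG_pfc_2"),
    AMY = c(shared_dg, "DG_amy_1", "DG_amy_2"),
    HIP = c(shared_dg, "DG_hip_1"))
  shared_pa <- sprintf("PA_shared_%03d", 1:71)
  pa_sets <- list(
    PFC = c(shared_pa, sprintf("PA_pfc_%02d", 1:15)),
    AMY = c(shared_pa, sprintf("PA_amy_%02d", 1:12)),
    HIP = c(shared_pa, sprintf("PA_hip_%02d", 1:10)))
  brain <- sprintf("brain_sp_%04d", 1:1990)
  plasma <- c(brain[1:548], sprintf("plasma_sp_%04d", 1:1043))
  list(viral = viral, bacterial = bacterial, dg_sets = dg_sets,
       pa_sets = pa_sets, brain = brain, plasma = plasma)
}

# chain-graded fold changes that make every edge of LPC->PC->PA->DG->TG
# more active in the DL group (ratio 2 per step)
planted_pathway_cfg <- function(seed) {
  small_lipidome_cfg(
    seed = seed,
    subclass_effects = data.frame(
      tissue = "PFC",
      subclass = c("PC", "PA", "DG", "TG"),
      fold_change = c(2, 4, 8, 16)))
}
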