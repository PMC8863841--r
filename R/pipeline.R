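#' Default pipeline configuration
#'
#' Collects every stage's inputs, thresholds and seeds in one list. The
#' threshold defaults are the published cutoffs: QC (`Rej == 0`,
#' `PQ > 0.85`, `CV < 0.3`, `ppm <= 5`), `VIP > 1.0` with `p < 0.05`,
#' LDA score `> 2.0` with Kruskal-Wallis `p < 0.05`, Spearman
#' `|rho| > 0.70` with `p < 0.05`, and activity `|Z| > 1.645`. The
#' simulation block plants the effects the downstream stages are expected
#' to recover: DG x1.38 in PFC, PA x1.18 in AMY, GM1 x1.51 in HIP, a 36-C
#' DG chain shift, depleted di-unsaturated DG, eight differential taxa, and
#' behaviors coupled to a planted PFC DG species.
#'
#' @param seed Master seed; stage seeds derive from it.
#' @return Nested configuration list (class `run_config`).
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    thresholds = list(
      qc = qc_thresholds(),
      vip = 1.0, alpha = 0.05,
      lda = 2.0,
      rho = 0.70,
      z = 1.645
    ),
    lipidome = lipidome_sim_config(
      n_per_group = 6,
      tissues = c("PFC", "AMY", "HIP", "plasma"),
      subclass_effects = data.frame(
        tissue = c("PFC", "AMY", "HIP"),
        subclass = c("DG", "PA", "GM1"),
        fold_change = c(1.38, 1.18, 1.51)),
      chain_effects = data.frame(
        tissue = "PFC", subclass = "DG", total_carbons = 36,
        fold_change = 1.5),
      unsat_effects = data.frame(
        tissue = "PFC", subclass = "DG", double_bonds = 2,
        fold_change = 0.7),
      qc_fail_fraction = 0.05,
      seed = seed),
    microbiome = microbiome_sim_config(
      n_per_group = 6, n_taxa = 200,
      differential_taxa = data.frame(
        taxon = 1:8,
        enriched_class = rep(c("DL", "HC"), each = 4),
        multiplier = c(8, 8, 6, 6, 8, 8, 6, 6)),
      seed = seed + 1L),
    behaviors = behavior_sim_config(
      couplings = NULL,     # filled at run time with a planted PFC DG species
      noise_sd = 1,
      seed = seed + 2L),
    stages = c(simulate = TRUE, qc = TRUE, lipids = TRUE, pathways = TRUE,
               taxa = TRUE, network = TRUE)
  ), class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param config A `run_config`.
#' @return `read_config()` returns a `run_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  plain <- rapply(unclass(config), function(x)
    if (is.data.frame(x)) as.list(x) else x, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_config(seed = raw$seed %||% 1L)
  mod <- utils::modifyList(unclass(cfg), raw)
  class(mod) <- "run_config"
  for (f in c("lipidome", "microbiome", "behaviors"))
    if (!inherits(mod[[f]], paste0(sub("s$", "", f), "_sim_config")))
      mod[[f]] <- structure(mod[[f]], class = switch(f,
        lipidome = "lipidome_sim_config",
        microbiome = "microbiome_sim_config",
        behaviors = "behavior_sim_config"))
  mod
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.write_tsv <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' simulate (lipidome, microbiome, behaviors), qc (filters +
#' normalization), lipids (subclass tests, DG structure profiles, PLS-DA,
#' discriminating species), pathways (reaction and pathway Z scores,
#' DG/PA synthesis-degradation), taxa (LEfSe-style screen), network
#' (Spearman co-occurrence over differential taxa, PFC DG species and
#' behaviors). All results are written as TSV under `outdir` together with
#' a JSON manifest (config echo, seeds, output checksums, versions) that
#' makes a rerun reproducible bit-for-bit.
#'
#' @param config A `run_config` from [default_config()] or [read_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  th <- config$thresholds
  res <- list()

  if (!st[["simulate"]])
    stop("stage 'simulate' is required as the data source; enable it first",
         call. = FALSE)
  sim <- generate_lipidome(config$lipidome)
  micro <- generate_microbiome(config$microbiome)
  for (tissue in names(sim))
    write_feature_table(sim[[tissue]]$table,
                        file.path(outdir, sprintf("lipidome_%s_raw.tsv", tissue)),
                        qc = sim[[tissue]]$qc, seed = config$lipidome$seed)
  .write_tsv(data.frame(lineage = rownames(micro$values), micro$values,
                        check.names = FALSE),
             file.path(outdir, "microbiome.tsv"), seed = config$microbiome$seed)
  res$sim <- sim; res$micro <- micro

  if (st[["qc"]]) {
    res$norm <- lapply(sim, function(x) {
      filt <- apply_qc_filters(x$table, x$qc, th$qc)
      list(table = normalize_total_area(filt),
           report = attr(filt, "filter_report"))
    })
    rep_df <- do.call(rbind, lapply(names(res$norm), function(tn)
      cbind(tissue = tn, res$norm[[tn]]$report)))
    .write_tsv(rep_df, file.path(outdir, "qc_filter_report.tsv"))
  }

  # behaviors: couple negative-emotion behaviors to a planted PFC DG species
  bcfg <- config$behaviors
  if (nrow(bcfg$couplings) == 0 && "PFC" %in% names(sim)) {
    dg <- sim$PFC$annotations
    dg36 <- dg$name[dg$subclass == "DG" & dg$total_carbons == 36]
    if (!length(dg36)) dg36 <- dg$name[dg$subclass == "DG"]
    bcfg$couplings <- data.frame(
      behavior = c("huddle", "sit_alone", "locomotion"),
      feature = dg36[1],
      strength = c(0.9, 0.85, -0.8),
      stringsAsFactors = FALSE)
  }
  behav <- generate_behaviors(bcfg, sim[[1]]$table)
  .write_tsv(data.frame(behavior = rownames(behav$values), behav$values,
                        check.names = FALSE),
             file.path(outdir, "behaviors.tsv"), seed = bcfg$seed)
  res$behav <- behav

  if (st[["lipids"]]) {
    stopifnot(st[["qc"]])
    res$lipids <- lapply(names(res$norm), function(tn) {
      tab <- res$norm[[tn]]$table
      ann <- sim[[tn]]$annotations
      groups <- ft_groups(tab)
      mat <- subclass_abundance(tab, ann)
      sub <- cbind(tissue = tn, subclass_test(mat, groups, ann))
      prof <- rbind(
        structure_profile(tab, ann, "DG", "total_carbons", groups),
        structure_profile(tab, ann, "DG", "double_bonds", groups))
      prof <- cbind(tissue = tn, prof)
      model <- plsda_fit(tab, groups, n_components = 2)
      disc <- cbind(tissue = tn,
                    discriminating_species(tab, groups, model,
                                           vip_threshold = th$vip,
                                           alpha = th$alpha))
      list(subclass = sub, profiles = prof, model = model, disc = disc)
    })
    names(res$lipids) <- names(res$norm)
    .write_tsv(do.call(rbind, lapply(res$lipids, `[[`, "subclass")),
               file.path(outdir, "subclass_results.tsv"))
    .write_tsv(do.call(rbind, lapply(res$lipids, `[[`, "profiles")),
               file.path(outdir, "structure_profiles.tsv"))
    .write_tsv(do.call(rbind, lapply(res$lipids, `[[`, "disc")),
               file.path(outdir, "discriminating_species.tsv"))
    scores <- do.call(rbind, lapply(names(res$lipids), function(tn) {
      sc <- res$lipids[[tn]]$model$scores
      data.frame(tissue = tn, sample = rownames(sc),
                 comp1 = sc[, 1], comp2 = sc[, 2], stringsAsFactors = FALSE)
    }))
    .write_tsv(scores, file.path(outdir, "plsda_scores.tsv"))
  }

  if (st[["pathways"]]) {
    stopifnot(st[["qc"]])
    network <- reaction_network()
    brain <- setdiff(names(res$norm), "plasma")
    res$pathways <- lapply(brain, function(tn) {
      tab <- res$norm[[tn]]$table
      A <- class_abundance(tab, sim[[tn]]$annotations)
      acts <- reaction_activities(A, network, ft_groups(tab),
                                  z_cut = th$z)
      pw <- pathway_activities(acts, network, z_cut = th$z)
      sd_dg <- synthesis_degradation(network, acts, "DG", z_cut = th$z)
      sd_pa <- synthesis_degradation(network, acts, "PA", z_cut = th$z)
      list(activities = cbind(tissue = tn, acts),
           pathways = cbind(tissue = tn, pw),
           syn_deg = data.frame(
             tissue = tn, class = c("DG", "PA"),
             z_synthesis = c(sd_dg$z_synthesis, sd_pa$z_synthesis),
             z_degradation = c(sd_dg$z_degradation, sd_pa$z_degradation),
             stringsAsFactors = FALSE))
    })
    names(res$pathways) <- brain
    .write_tsv(do.call(rbind, lapply(res$pathways, `[[`, "activities")),
               file.path(outdir, "reactions.tsv"))
    .write_tsv(do.call(rbind, lapply(res$pathways, `[[`, "pathways")),
               file.path(outdir, "pathways.tsv"))
    .write_tsv(do.call(rbind, lapply(res$pathways, `[[`, "syn_deg")),
               file.path(outdir, "synthesis_degradation.tsv"))
  }

  if (st[["taxa"]]) {
    res$taxa <- lefse_two_class(micro, threshold = th$lda, alpha = th$alpha,
                                seed = config$microbiome$seed)
    .write_tsv(res$taxa, file.path(outdir, "lefse_results.tsv"))
  }

  if (st[["network"]]) {
    if (!st[["taxa"]] || !st[["lipids"]])
      stop("stage 'network' needs stages 'taxa' and 'lipids'; enable them first",
           call. = FALSE)
    animals <- sub("^[^_]+_", "", colnames(sim[[1]]$table$values))
    taxa_pass <- res$taxa$taxon[res$taxa$passes]
    taxa_mat <- micro$values[taxa_pass, , drop = FALSE]
    colnames(taxa_mat) <- micro$sample_info$sample
    pfc <- res$norm$PFC$table
    dg_names <- sim$PFC$annotations$name[sim$PFC$annotations$subclass == "DG"]
    dg_names <- intersect(dg_names, rownames(pfc$values))
    lipid_mat <- pfc$values[dg_names, , drop = FALSE]
    colnames(lipid_mat) <- animals
    behav_mat <- behav$values
    colnames(behav_mat) <- animals
    taxa_mat <- taxa_mat[, animals, drop = FALSE]
    ns <- node_set(list(taxon = taxa_mat, lipid = lipid_mat,
                        behavior = behav_mat))
    res$graph <- spearman_edges(ns, rho_threshold = th$rho, alpha = th$alpha)
    export_graph(res$graph, file.path(outdir, "network.graphml"),
                 edges_tsv = file.path(outdir, "edges.tsv"))
  }

  outputs <- sort(list.files(outdir, full.names = FALSE))
  manifest <- list(
    package = "lipidaxis",
    package_version = as.character(utils::packageVersion("lipidaxis")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    thresholds = config$thresholds,
    stages = as.list(config$stages),
    checksums = as.list(tools::md5sum(file.path(outdir, outputs)))
  )
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$outdir <- outdir
  invisible(res)
}
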