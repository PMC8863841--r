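# Per-compartment chain composition ranges (total carbons, total double
# bonds) used when sampling species. Brain DG spans 34-40 C / 2-6 db and
# plasma DG 49-54 C / 0-3 db; other subclasses use generic ranges typical of
# mammalian tissue.
.chain_ranges <- function(subclass, compartment = c("brain", "plasma")) {
  compartment <- match.arg(compartment)
  if (subclass == "DG") {
    if (compartment == "brain") return(list(carbons = 34:40, db = 2:6))
    return(list(carbons = 49:54, db = 0:3))
  }
  switch(subclass,
    TG = list(carbons = 48:58, db = 0:6),
    MG = list(carbons = 14:22, db = 0:2),
    So = list(carbons = 16:20, db = 0:2),
    GM1 = list(carbons = 34:42, db = 1:3),
    LPC = , LPE = , LPA = , LPI = , LPG = list(carbons = 16:22, db = 0:4),
    Cer = , SM = list(carbons = 32:42, db = 0:3),
    list(carbons = 30:44, db = 0:8)            # diacyl glycerophospholipids
  )
}

# Default species counts per subclass: ~1940 species for brain tissues,
# ~1560 for plasma, across 14 subclasses; DG and PA counts match the sizes
# of the species lists analysed downstream (15 and 108).
.default_species_counts <- function(tissue) {
  if (identical(tissue, "plasma"))
    c(PC = 260, PE = 250, TG = 270, PS = 90, PI = 70, PG = 40, PA = 60,
      SM = 130, Cer = 120, DG = 30, LPC = 110, LPE = 90, So = 30, GM1 = 7)
  else
    c(PC = 330, PE = 330, PS = 240, PI = 110, PG = 70, PA = 108, SM = 170,
      Cer = 170, DG = 15, TG = 190, LPC = 80, LPE = 80, So = 40, GM1 = 7)
}

.as_effect_df <- function(x, cols) {
  if (is.null(x))
    return(as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)),
                                         cols)))
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(cols %in% names(df)))
    stop("effect specification needs columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  df
}

#' Configuration for the synthetic lipidome generator
#'
#' Defaults emulate a two-group (`DL` vs `HC`) design with 6 animals per
#' group, four tissues (PFC, AMY, HIP, plasma), roughly 1900 brain and 1560
#' plasma lipid species over 14 subclasses, lognormal peak areas, and
#' multiplicative group effects planted at subclass, chain-length or
#' unsaturation resolution.
#'
#' @param n_per_group Animals per group (>= 3).
#' @param tissues Tissue labels; `"plasma"` selects plasma chain ranges, all
#'   other labels use brain ranges.
#' @param n_species_per_subclass Named vector subclass -> species count, or
#'   `NULL` for per-tissue defaults.
#' @param base_log_mean,base_log_sd Mean and within-feature sd of log peak
#'   area (natural log).
#' @param feature_spread Between-feature sd of the log mean.
#' @param subclass_effects Data frame (`tissue`, `subclass`, `fold_change`):
#'   multiplies every species of the subclass in DL samples of the tissue.
#' @param chain_effects Data frame (`tissue`, `subclass`, `total_carbons`,
#'   `fold_change`).
#' @param unsat_effects Data frame (`tissue`, `subclass`, `double_bonds`,
#'   `fold_change`).
#' @param qc_fail_fraction Fraction of features given QC fields failing at
#'   least one criterion (exact count by construction).
#' @param seed Integer seed.
#' @return A `lipidome_sim_config` list.
#' @export
lipidome_sim_config <- function(n_per_group = 6,
                                tissues = c("PFC", "AMY", "HIP", "plasma"),
                                n_species_per_subclass = NULL,
                                base_log_mean = 4, base_log_sd = 0.4,
                                feature_spread = 1,
                                subclass_effects = NULL,
                                chain_effects = NULL,
                                unsat_effects = NULL,
                                qc_fail_fraction = 0,
                                seed = 1L) {
  if (n_per_group < 3) stop("n_per_group must be at least 3", call. = FALSE)
  if (qc_fail_fraction < 0 || qc_fail_fraction > 1)
    stop("qc_fail_fraction must lie in [0, 1]", call. = FALSE)
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    tissues = tissues,
    n_species_per_subclass = n_species_per_subclass,
    base_log_mean = base_log_mean, base_log_sd = base_log_sd,
    feature_spread = feature_spread,
    subclass_effects = .as_effect_df(subclass_effects,
                                     c("tissue", "subclass", "fold_change")),
    chain_effects = .as_effect_df(chain_effects,
                                  c("tissue", "subclass", "total_carbons", "fold_change")),
    unsat_effects = .as_effect_df(unsat_effects,
                                  c("tissue", "subclass", "double_bonds", "fold_change")),
    qc_fail_fraction = qc_fail_fraction,
    seed = as.integer(seed)
  )
  for (ef in list(cfg$subclass_effects, cfg$chain_effects, cfg$unsat_effects)) {
    if (nrow(ef) && any(ef$fold_change <= 0))
      stop("planted fold changes must be positive", call. = FALSE)
    bad <- setdiff(ef$subclass, lipid_subclasses())
    if (length(bad))
      stop("unknown lipid subclass in effect specification: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  known <- names(cfg$n_species_per_subclass)
  bad <- setdiff(known, lipid_subclasses())
  if (length(bad))
    stop("unknown lipid subclass in n_species_per_subclass: ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(cfg, class = "lipidome_sim_config")
}

# Sample `n` distinct species of one subclass as shorthand names plus totals.
.sample_species <- function(subclass, n, compartment) {
  rng <- .chain_ranges(subclass, compartment)
  n_chains <- .lipid_vocab$n_chains[.lipid_vocab$subclass == subclass]
  make_one <- function() {
    tc <- if (length(rng$carbons) == 1) rng$carbons else sample(rng$carbons, 1)
    td <- if (length(rng$db) == 1) rng$db else sample(rng$db, 1)
    if (is.na(n_chains) || n_chains == 1L)
      return(sprintf("%s(%d:%d)", subclass, tc, td))
    k <- n_chains
    # split total carbons into k chains of >= 10 C each (stars and bars)
    cmin <- 10L
    m <- tc - k * cmin
    cuts <- if (k > 1) sort(sample(m + k - 1, k - 1)) else integer(0)
    carbons <- diff(c(0L, cuts, m + k)) - 1L + cmin
    dbs <- stats::rmultinom(1, td, rep(1, k))[, 1]
    sprintf("%s(%s)", subclass,
            paste(sprintf("%d:%d", carbons, dbs), collapse = "/"))
  }
  names <- character(0)
  tries <- 0L
  while (length(names) < n && tries < 200L * n) {
    names <- unique(c(names, make_one()))
    tries <- tries + 1L
  }
  if (length(names) < n)
    stop(sprintf("could not draw %d distinct %s species from the configured chain ranges",
                 n, subclass), call. = FALSE)
  names[seq_len(n)]
}

#' Generate a synthetic lipidome
#'
#' Draws, per tissue, a species set with well-formed shorthand names, a
#' features x samples peak-area matrix with lognormal abundances (each
#' feature has its own log mean; no zeros, as QC-passing MS features are
#' quantified), planted multiplicative group effects in DL samples, and a
#' QC table in which exactly `round(qc_fail_fraction * n_features)` features
#' fail at least one QC criterion.
#'
#' @param config A [lipidome_sim_config()].
#' @return A list of class `lipidome_sim`, one element per tissue, each with
#'   `table` (raw `feature_table`), `annotations` (from
#'   [annotate_species()]) and `qc` (QC data frame).
#' @export
generate_lipidome <- function(config) {
  stopifnot(inherits(config, "lipidome_sim_config"))
  .with_seed(config$seed, {
    n <- config$n_per_group
    animals <- c(sprintf("DL_%02d", seq_len(n)), sprintf("HC_%02d", seq_len(n)))
    groups <- rep(c("DL", "HC"), each = n)
    out <- lapply(config$tissues, function(tissue) {
      compartment <- if (identical(tissue, "plasma")) "plasma" else "brain"
      counts <- config$n_species_per_subclass
      if (is.null(counts)) counts <- .default_species_counts(tissue)
      species <- unlist(lapply(names(counts), function(sc)
        .sample_species(sc, counts[[sc]], compartment)), use.names = FALSE)
      ann <- annotate_species(species)
      p <- length(species)
      mu <- config$base_log_mean + stats::rnorm(p, 0, config$feature_spread)
      vals <- exp(matrix(stats::rnorm(p * 2 * n, mean = mu, sd = config$base_log_sd),
                         nrow = p, ncol = 2 * n))
      dimnames(vals) <- list(species, paste(tissue, animals, sep = "_"))
      # planted multiplicative effects on DL columns
      fc <- rep(1, p)
      se <- config$subclass_effects
      se <- se[se$tissue == tissue, , drop = FALSE]
      for (i in seq_len(nrow(se)))
        fc[ann$subclass == se$subclass[i]] <-
          fc[ann$subclass == se$subclass[i]] * se$fold_change[i]
      ce <- config$chain_effects
      ce <- ce[ce$tissue == tissue, , drop = FALSE]
      for (i in seq_len(nrow(ce)))
        fc[ann$subclass == ce$subclass[i] &
             ann$total_carbons == ce$total_carbons[i]] <-
          fc[ann$subclass == ce$subclass[i] &
               ann$total_carbons == ce$total_carbons[i]] * ce$fold_change[i]
      ue <- config$unsat_effects
      ue <- ue[ue$tissue == tissue, , drop = FALSE]
      for (i in seq_len(nrow(ue)))
        fc[ann$subclass == ue$subclass[i] &
             ann$total_double_bonds == ue$double_bonds[i]] <-
          fc[ann$subclass == ue$subclass[i] &
               ann$total_double_bonds == ue$double_bonds[i]] * ue$fold_change[i]
      vals[, groups == "DL"] <- vals[, groups == "DL"] * fc
      # QC fields: exact planted failure count
      n_fail <- round(config$qc_fail_fraction * p)
      fail <- rep(FALSE, p)
      if (n_fail > 0) fail[sample.int(p, n_fail)] <- TRUE
      qc <- data.frame(
        name = species,
        rej = 0L,
        pq = stats::runif(p, 0.86, 1),
        cv = stats::runif(p, 0.02, 0.28),
        ppm = stats::runif(p, 0, 4.9),
        stringsAsFactors = FALSE
      )
      which_crit <- if (n_fail > 0) sample(4L, n_fail, replace = TRUE) else integer(0)
      idx <- which(fail)
      qc$rej[idx[which_crit == 1]] <- 1L
      qc$pq[idx[which_crit == 2]] <- stats::runif(sum(which_crit == 2), 0.4, 0.85)
      qc$cv[idx[which_crit == 3]] <- stats::runif(sum(which_crit == 3), 0.31, 0.8)
      qc$ppm[idx[which_crit == 4]] <- stats::runif(sum(which_crit == 4), 5.1, 12)
      list(table = feature_table(vals, group = groups, tissue = tissue),
           annotations = ann, qc = qc)
    })
    names(out) <- config$tissues
    structure(out, class = "lipidome_sim", config = config)
  })
}
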