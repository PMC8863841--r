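.phylum_pool <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                  "Actinobacteria", "Spirochaetes", "Tenericutes")

#' Configuration for the synthetic microbiome generator
#'
#' Emulates a shotgun-metagenomics relative-abundance table: rank-prefixed
#' lineages, lognormal abundances with structural zeros, closure to
#' column sums of 1, and planted multiplicative enrichments.
#'
#' @param n_per_group Animals per group.
#' @param n_taxa Number of taxa.
#' @param lineage_depth Number of ranks per lineage (2..7, kingdom through
#'   species).
#' @param differential_taxa Data frame (`taxon`, `enriched_class`,
#'   `multiplier`): `taxon` is a row index, `enriched_class` one of
#'   `"DL"`/`"HC"`, `multiplier > 0` applied to that class's samples before
#'   closure.
#' @param zero_inflation Probability that a cell is a structural zero (set
#'   before closure).
#' @param log_mean_sd Between-taxon sd of the log mean abundance.
#' @param log_sd Within-taxon sd of log abundance.
#' @param seed Integer seed.
#' @return A `microbiome_sim_config` list.
#' @export
microbiome_sim_config <- function(n_per_group = 6, n_taxa = 200,
                                  lineage_depth = 7,
                                  differential_taxa = NULL,
                                  zero_inflation = 0.1,
                                  log_mean_sd = 1.5, log_sd = 0.5,
                                  seed = 1L) {
  if (n_per_group < 3) stop("n_per_group must be at least 3", call. = FALSE)
  if (lineage_depth < 2 || lineage_depth > 7)
    stop("lineage_depth must lie in 2..7", call. = FALSE)
  if (zero_inflation < 0 || zero_inflation >= 1)
    stop("zero_inflation must lie in [0, 1)", call. = FALSE)
  diff <- if (is.null(differential_taxa))
    data.frame(taxon = integer(0), enriched_class = character(0),
               multiplier = numeric(0))
  else as.data.frame(differential_taxa, stringsAsFactors = FALSE)
  if (nrow(diff)) {
    if (!all(c("taxon", "enriched_class", "multiplier") %in% names(diff)))
      stop("differential_taxa needs columns taxon, enriched_class, multiplier",
           call. = FALSE)
    if (any(diff$multiplier <= 0))
      stop("effect multipliers must be positive", call. = FALSE)
    if (!all(diff$enriched_class %in% c("DL", "HC")))
      stop("enriched_class must be 'DL' or 'HC'", call. = FALSE)
    if (nrow(diff) > n_taxa || any(diff$taxon > n_taxa))
      stop("n_taxa is smaller than the differential taxa specification",
           call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 n_taxa = as.integer(n_taxa),
                 lineage_depth = as.integer(lineage_depth),
                 differential_taxa = diff,
                 zero_inflation = zero_inflation,
                 log_mean_sd = log_mean_sd, log_sd = log_sd,
                 seed = as.integer(seed)),
            class = "microbiome_sim_config")
}

.make_lineages <- function(n, depth) {
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  phyla <- sample(.phylum_pool, n, replace = TRUE)
  vapply(seq_len(n), function(i) {
    ranks <- c("Bacteria", phyla[i],
               paste0(c("Class", "Order", "Family", "Genus", "Species"),
                      "_", sprintf("%03d", i)))
    paste(paste0(prefixes[seq_len(depth)], ranks[seq_len(depth)]),
          collapse = ";")
  }, character(1))
}

#' Generate a synthetic microbiome relative-abundance table
#'
#' Lognormal abundances with structural zeros, planted class enrichments,
#' then closure so that every sample column sums to 1 (within 1e-9).
#'
#' @param config A [microbiome_sim_config()].
#' @return A `taxon_table`: list with `values` (taxa x samples, rownames =
#'   lineage strings), `sample_info` and `lineages`.
#' @export
generate_microbiome <- function(config) {
  stopifnot(inherits(config, "microbiome_sim_config"))
  .with_seed(config$seed, {
    n <- config$n_per_group
    p <- config$n_taxa
    samples <- c(sprintf("DL_%02d", seq_len(n)), sprintf("HC_%02d", seq_len(n)))
    groups <- rep(c("DL", "HC"), each = n)
    lineages <- .make_lineages(p, config$lineage_depth)
    mu <- stats::rnorm(p, 0, config$log_mean_sd)
    vals <- exp(matrix(stats::rnorm(p * 2 * n, mean = mu, sd = config$log_sd),
                       nrow = p))
    dimnames(vals) <- list(lineages, samples)
    dt <- config$differential_taxa
    for (i in seq_len(nrow(dt)))
      vals[dt$taxon[i], groups == dt$enriched_class[i]] <-
        vals[dt$taxon[i], groups == dt$enriched_class[i]] * dt$multiplier[i]
    if (config$zero_inflation > 0) {
      zero <- matrix(stats::runif(p * 2 * n) < config$zero_inflation, nrow = p)
      # planted differential taxa stay present so their enrichment is testable
      if (nrow(dt)) zero[dt$taxon, ] <- FALSE
      vals[zero] <- 0
    }
    cs <- colSums(vals)
    if (any(cs == 0))
      stop("zero_inflation produced an empty sample; lower it", call. = FALSE)
    vals <- sweep(vals, 2, cs, "/")
    structure(list(values = vals,
                   sample_info = data.frame(sample = samples, group = groups,
                                            stringsAsFactors = FALSE),
                   lineages = lineages),
              class = "taxon_table", config = config)
  })
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("<taxon_table> %d taxa x %d samples (relative abundance)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
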