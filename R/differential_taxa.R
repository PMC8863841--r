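.rank_prefixes <- c(k = "k__", p = "p__", c = "c__", o = "o__", f = "f__",
                    g = "g__", s = "s__")
.rank_names <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                 f = "family", g = "genus", s = "species")

#' Parse a rank-prefixed lineage string
#'
#' Lineages are `;`-separated with GreenGenes-style prefixes
#' (`k__ ... s__`); trailing ranks may be missing.
#'
#' @param text Lineage string, e.g.
#'   `"k__Bacteria;p__Firmicutes;...;s__Speciesname"`.
#' @return Named character vector, names among kingdom..species.
#' @export
parse_lineage <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text) || !nzchar(text))
    stop("lineage must be a single nonempty string", call. = FALSE)
  parts <- trimws(strsplit(text, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) stop("lineage must be a single nonempty string", call. = FALSE)
  pre <- substr(parts, 1, 3)
  bad <- !pre %in% .rank_prefixes
  if (any(bad))
    stop("unknown rank prefix in lineage: '", parts[bad][1], "'", call. = FALSE)
  keys <- names(.rank_prefixes)[match(pre, .rank_prefixes)]
  if (anyDuplicated(keys))
    stop("duplicate rank in lineage: ",
         .rank_names[keys[duplicated(keys)][1]], call. = FALSE)
  stats::setNames(substring(parts, 4), .rank_names[keys])
}

#' Two-class LEfSe-style differential abundance
#'
#' Stage 1 screens each taxon with a Kruskal-Wallis rank test at
#' `alpha`. Stage 2, on the survivors jointly: over `n_boot` bootstrap
#' rounds, subsample `ceiling(2/3 * n)` samples per class (without
#' replacement), fit a two-class linear discriminant
#' (via \code{MASS::lda}) on the abundances rescaled to a per-million
#' scale, and record a per-taxon effect size combining the raw class mean
#' difference with the taxon's share of the mean difference projected on
#' the discriminant direction (LEfSe convention). The LDA score is
#' `log10(1 + mean effect size)`; the enriched class is the class with the
#' larger mean on the full data. The canonical all-against-all subclass
#' Wilcoxon stage is vacuous for a plain two-class design and is omitted.
#'
#' @param table A `taxon_table` (or numeric matrix taxa x samples of
#'   relative abundances in `[0, 1]`).
#' @param groups Class label per sample (exactly two classes, >= 3 samples
#'   each); defaults to the `taxon_table` sample info.
#' @param threshold LDA score cutoff (2.0 by default; 2.5 is the stricter
#'   published alternative).
#' @param alpha Stage-1 significance level.
#' @param n_boot Bootstrap rounds (canonical default 30).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame sorted by signed LDA score: `taxon`, `kw_p`,
#'   `lda_score`, `enriched_class`, `passes`
#'   (`kw_p < alpha & lda_score > threshold`). Attribute `n_skipped` counts
#'   degenerate bootstrap rounds that were skipped.
#' @export
lefse_two_class <- function(table, groups = NULL, threshold = 2.0,
                            alpha = 0.05, n_boot = 30, seed = 1L) {
  vals <- if (inherits(table, "taxon_table")) table$values else table
  if (is.null(groups) && inherits(table, "taxon_table"))
    groups <- table$sample_info$group
  groups <- as.character(groups)
  cls <- sort(unique(groups))
  if (length(cls) != 2)
    stop("exactly two classes are required", call. = FALSE)
  if (any(table(groups) < 3))
    stop("at least 3 samples per class are required", call. = FALSE)
  taxa <- rownames(vals)
  kw_p <- apply(vals, 1, function(v)
    suppressWarnings(stats::kruskal.test(v, factor(groups))$p.value))
  surv <- which(kw_p < alpha)
  lda_score <- rep(NA_real_, length(taxa))
  n_skipped <- 0L
  if (length(surv)) {
    X <- t(vals[surv, , drop = FALSE]) * 1e6      # per-million scale
    colnames(X) <- taxa[surv]
    idx1 <- which(groups == cls[1]); idx2 <- which(groups == cls[2])
    m1 <- ceiling(2 / 3 * length(idx1)); m2 <- ceiling(2 / 3 * length(idx2))
    acc <- matrix(0, nrow = 0, ncol = length(surv))
    .with_seed(seed, {
      for (b in seq_len(n_boot)) {
        take <- c(sample(idx1, m1), sample(idx2, m2))
        Xb <- X[take, , drop = FALSE]
        gb <- groups[take]
        if (all(apply(Xb, 2, function(v) length(unique(v)) == 1))) {
          n_skipped <- n_skipped + 1L
          next
        }
        # tiny jitter keeps within-class covariances non-degenerate
        Xb <- Xb + matrix(stats::rnorm(length(Xb), 0, 1e-6 * max(1, mean(abs(Xb)))),
                          nrow = nrow(Xb))
        fit <- tryCatch(
          suppressWarnings(MASS::lda(Xb, grouping = factor(gb, levels = cls))),
          error = function(e) NULL)
        if (is.null(fit)) { n_skipped <- n_skipped + 1L; next }
        w <- fit$scaling[, 1]
        w <- w / sqrt(sum(w^2))
        mdiff <- colMeans(Xb[gb == cls[1], , drop = FALSE]) -
          colMeans(Xb[gb == cls[2], , drop = FALSE])
        ld_effect <- abs(sum(w * mdiff))           # class separation along LD1
        eff <- (abs(mdiff) + abs(w * ld_effect)) / 2
        acc <- rbind(acc, eff)
      }
    })
    if (nrow(acc))
      lda_score[surv] <- log10(1 + colMeans(acc))
  }
  m_by_class <- vapply(cls, function(cl)
    rowMeans(vals[, groups == cl, drop = FALSE]), numeric(length(taxa)))
  if (is.null(dim(m_by_class))) m_by_class <- matrix(m_by_class, nrow = 1)
  enriched <- cls[max.col(m_by_class, ties.method = "first")]
  out <- data.frame(taxon = taxa, kw_p = kw_p, lda_score = lda_score,
                    enriched_class = enriched,
                    passes = !is.na(lda_score) & kw_p < alpha &
                      lda_score > threshold,
                    stringsAsFactors = FALSE)
  signed <- ifelse(out$enriched_class == cls[1], 1, -1) *
    ifelse(is.na(out$lda_score), 0, out$lda_score)
  out <- out[order(-signed), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
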