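#' Build a lipid reaction network
#'
#' A reaction network is a set of named pathways, each an ordered chain of
#' lipid subclass nodes read left-to-right as substrate -> product; a chain
#' of `k` nodes induces `k - 1` directed edges. The default network is the
#' union of the six chains reported for the prefrontal cortex and
#' hippocampus analyses: LPC-PC-PA-DG-TG, LPC-PC-PA-LPA, LPC-LPA,
#' DG-PC-LPC, DG-PA-PI-LPI and LPA-PA-PG-LPG.
#'
#' @param pathways Named list of character vectors (ordered subclass
#'   chains), or `NULL` for the default network.
#' @return An object of class `reaction_network`: `pathways` and `edges`
#'   (unique data frame `substrate`, `product`).
#' @export
reaction_network <- function(pathways = NULL) {
  if (is.null(pathways))
    pathways <- list(
      "LPC-PC-PA-DG-TG" = c("LPC", "PC", "PA", "DG", "TG"),
      "LPC-PC-PA-LPA"   = c("LPC", "PC", "PA", "LPA"),
      "LPC-LPA"         = c("LPC", "LPA"),
      "DG-PC-LPC"       = c("DG", "PC", "LPC"),
      "DG-PA-PI-LPI"    = c("DG", "PA", "PI", "LPI"),
      "LPA-PA-PG-LPG"   = c("LPA", "PA", "PG", "LPG")
    )
  stopifnot(is.list(pathways), length(names(pathways)) == length(pathways))
  if (any(vapply(pathways, length, integer(1)) < 2))
    stop("every pathway needs at least 2 nodes", call. = FALSE)
  edges <- unique(do.call(rbind, lapply(pathways, function(chain) {
    if (any(chain[-1] == chain[-length(chain)]))
      stop("self-loop in pathway chain: ", paste(chain, collapse = "-"),
           call. = FALSE)
    data.frame(substrate = chain[-length(chain)], product = chain[-1],
               stringsAsFactors = FALSE)
  })))
  rownames(edges) <- NULL
  structure(list(pathways = pathways, edges = edges),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d pathways, %d unique edges\n",
              length(x$pathways), nrow(x$edges)))
  invisible(x)
}

#' Read a reaction network from TSV
#'
#' Expects columns `pathway_id`, `step_index`, `substrate`, `product`; steps
#' are ordered by `step_index` within each pathway.
#'
#' @param path TSV path.
#' @return A `reaction_network`.
#' @export
read_reaction_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "step_index", "substrate", "product")
  if (!all(need %in% names(df)))
    stop("reaction TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  pw <- lapply(split(df, df$pathway_id), function(d) {
    d <- d[order(d$step_index), ]
    c(d$substrate[1], d$product)
  })
  reaction_network(pw)
}

#' Class-level abundance matrix
#'
#' Per-sample abundance of each lipid class: the sum of normalized species
#' abundances of that class (the scalar `A_i` entering the reaction
#' weights).
#'
#' @inheritParams subclass_abundance
#' @return Matrix classes x samples.
#' @export
class_abundance <- function(table, annotations, unparseable = c("error", "skip")) {
  subclass_abundance(table, annotations, unparseable = unparseable)
}

#' Per-sample reaction weights for one edge
#'
#' The reaction weight is the elementwise per-sample ratio of product-class
#' over substrate-class abundance, `w = A_product / A_substrate`; it is
#' invariant to rescaling a sample's abundances.
#'
#' @param A Class x sample abundance matrix from [class_abundance()].
#' @param substrate,product Class codes (rows of `A`).
#' @param zero_policy `"drop"` (default): samples with zero substrate are
#'   dropped for this edge with a warning; `"fail"`: error instead.
#' @return Named numeric vector of weights (possibly fewer samples than
#'   `ncol(A)` under the drop policy).
#' @export
reaction_weights <- function(A, substrate, product,
                             zero_policy = c("drop", "fail")) {
  zero_policy <- match.arg(zero_policy)
  miss <- setdiff(c(substrate, product), rownames(A))
  if (length(miss))
    stop("class(es) absent from abundance matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- A[substrate, ]
  zero <- s == 0
  if (any(zero)) {
    if (zero_policy == "fail")
      stop(sprintf("zero substrate (%s) abundance in sample(s): %s", substrate,
                   paste(colnames(A)[zero], collapse = ", ")), call. = FALSE)
    warning(sprintf("edge %s->%s: dropping %d sample(s) with zero substrate abundance",
                    substrate, product, sum(zero)))
  }
  A[product, !zero] / s[!zero]
}

#' One-sided critical Z value
#'
#' The activity cutoff used throughout the reaction scoring:
#' `qnorm(1 - alpha)`, i.e. 1.645 at the default `alpha = 0.05`.
#'
#' @param alpha One-sided significance level.
#' @return Critical value.
#' @export
z_critical <- function(alpha = 0.05) stats::qnorm(1 - alpha)

.z_verdict <- function(z, z_cut) {
  ifelse(z > z_cut, "active", ifelse(z < -z_cut, "inactive", "ns"))
}

#' Reaction activity Z score for one edge
#'
#' A one-sided Student's t test of the reaction weights in the
#' case-greater-than-control direction yields `P`; the activity score is
#' `Z = qnorm(1 - P)`. Because `qnorm(1 - P)` is negative whenever the
#' effect favours the control group, this single formula also realizes the
#' sign-flip convention for control-active reactions. Verdict: `active` if
#' `Z > z_cut`, `inactive` if `Z < -z_cut`, else `ns`.
#'
#' @param w_case,w_ctrl Reaction weights per group (>= 2 each).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @param log_weights Test `log(w)` instead of `w` (ratios are skewed; off
#'   by default).
#' @param z_cut Activity cutoff (default [z_critical()] at 0.05, i.e.
#'   1.645).
#' @return List: `t`, `p_one_sided`, `z`, `verdict`, `n_case`, `n_ctrl`.
#' @export
reaction_z <- function(w_case, w_ctrl, var_equal = TRUE, log_weights = FALSE,
                       z_cut = z_critical(0.05)) {
  if (length(w_case) < 2 || length(w_ctrl) < 2)
    stop("at least 2 weights per group are required", call. = FALSE)
  if (log_weights) { w_case <- log(w_case); w_ctrl <- log(w_ctrl) }
  tt <- tryCatch(stats::t.test(w_case, w_ctrl, alternative = "greater",
                               var.equal = var_equal),
                 error = function(e) NULL)
  if (is.null(tt)) {                     # zero variance in both groups
    if (mean(w_case) == mean(w_ctrl))
      return(list(t = 0, p_one_sided = 0.5, z = 0, verdict = "ns",
                  n_case = length(w_case), n_ctrl = length(w_ctrl)))
    z <- if (mean(w_case) > mean(w_ctrl)) Inf else -Inf
    return(list(t = z, p_one_sided = if (z > 0) 0 else 1, z = z,
                verdict = .z_verdict(z, z_cut),
                n_case = length(w_case), n_ctrl = length(w_ctrl)))
  }
  p <- min(max(tt$p.value, 1e-300), 1 - 1e-16)
  z <- stats::qnorm(1 - p)
  list(t = unname(tt$statistic), p_one_sided = tt$p.value, z = z,
       verdict = .z_verdict(z, z_cut),
       n_case = length(w_case), n_ctrl = length(w_ctrl))
}

#' Score every edge of a reaction network
#'
#' @param A Class x sample abundance matrix.
#' @param network A `reaction_network`.
#' @param groups Group label per sample column of `A`.
#' @param case,control Group labels (the one-sided test is in the
#'   case-greater direction).
#' @inheritParams reaction_z
#' @inheritParams reaction_weights
#' @return Data frame with one row per evaluable edge: `substrate`,
#'   `product`, `t`, `p_one_sided`, `z`, `verdict`, `n_case`, `n_ctrl`.
#'   Edges whose classes are absent from `A` are skipped with a warning.
#' @export
reaction_activities <- function(A, network, groups, case = "DL",
                                control = "HC", var_equal = TRUE,
                                log_weights = FALSE,
                                z_cut = z_critical(0.05),
                                zero_policy = "drop") {
  stopifnot(inherits(network, "reaction_network"))
  g <- .split_groups(groups, case, control)
  rows <- lapply(seq_len(nrow(network$edges)), function(i) {
    e <- network$edges[i, ]
    if (!all(c(e$substrate, e$product) %in% rownames(A))) {
      warning(sprintf("edge %s->%s skipped: class absent from data",
                      e$substrate, e$product))
      return(NULL)
    }
    w <- reaction_weights(A, e$substrate, e$product, zero_policy = zero_policy)
    w_case <- w[intersect(names(w), colnames(A)[g$case])]
    w_ctrl <- w[intersect(names(w), colnames(A)[g$control])]
    r <- reaction_z(w_case, w_ctrl, var_equal = var_equal,
                    log_weights = log_weights, z_cut = z_cut)
    data.frame(substrate = e$substrate, product = e$product, t = r$t,
               p_one_sided = r$p_one_sided, z = r$z, verdict = r$verdict,
               n_case = r$n_case, n_ctrl = r$n_ctrl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(substrate = character(0), product = character(0),
                      t = numeric(0), p_one_sided = numeric(0), z = numeric(0),
                      verdict = character(0), n_case = integer(0),
                      n_ctrl = integer(0), stringsAsFactors = FALSE)
  out
}

#' Pathway-level activity score
#'
#' Aggregates the edge Z scores of a pathway of `k` nodes as
#' `Z_A = sum(Z_i) / sqrt(k - 1)`; for independent standard-normal edge
#' scores `Z_A` is again standard normal, so the same +/-1.645 cutoff
#' applies.
#'
#' @param z Numeric vector of the pathway's `k - 1` edge Z scores.
#' @param k Node count of the pathway (default `length(z) + 1`).
#' @param z_cut Activity cutoff.
#' @return List: `z_a`, `k`, `verdict`.
#' @export
pathway_z <- function(z, k = length(z) + 1L, z_cut = z_critical(0.05)) {
  if (length(z) != k - 1)
    stop(sprintf("expected %d edge scores for a %d-node pathway, got %d",
                 k - 1, k, length(z)), call. = FALSE)
  z_a <- sum(z) / sqrt(k - 1)
  list(z_a = z_a, k = k, verdict = .z_verdict(z_a, z_cut))
}

#' Score every pathway of a network
#'
#' @param activities Edge table from [reaction_activities()].
#' @param network The `reaction_network`.
#' @param allow_partial If an edge was skipped upstream, renormalize by the
#'   available edge count (logged) instead of marking the pathway
#'   not-evaluable.
#' @param z_cut Activity cutoff.
#' @return Data frame: `pathway`, `k`, `n_edges`, `z_a`, `verdict`
#'   (`"not_evaluable"` when edges are missing and `allow_partial` is
#'   `FALSE`).
#' @export
pathway_activities <- function(activities, network, allow_partial = FALSE,
                               z_cut = z_critical(0.05)) {
  stopifnot(inherits(network, "reaction_network"))
  key <- paste(activities$substrate, activities$product, sep = "->")
  rows <- lapply(names(network$pathways), function(nm) {
    chain <- network$pathways[[nm]]
    k <- length(chain)
    want <- paste(chain[-k], chain[-1], sep = "->")
    z <- activities$z[match(want, key)]
    if (anyNA(z)) {
      if (!allow_partial || all(is.na(z)))
        return(data.frame(pathway = nm, k = k, n_edges = sum(!is.na(z)),
                          z_a = NA_real_, verdict = "not_evaluable",
                          stringsAsFactors = FALSE))
      message(sprintf("pathway %s: renormalizing over %d of %d edges",
                      nm, sum(!is.na(z)), k - 1))
      z <- z[!is.na(z)]
      r <- pathway_z(z, k = length(z) + 1L, z_cut = z_cut)
      return(data.frame(pathway = nm, k = k, n_edges = length(z),
                        z_a = r$z_a, verdict = r$verdict,
                        stringsAsFactors = FALSE))
    }
    r <- pathway_z(z, k = k, z_cut = z_cut)
    data.frame(pathway = nm, k = k, n_edges = k - 1L, z_a = r$z_a,
               verdict = r$verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthesis and degradation scores for one lipid class
#'
#' Aggregates the Z scores of the class's incoming edges (synthesis) and
#' outgoing edges (degradation), each with the pathway formula using the
#' respective edge count.
#'
#' @param network A `reaction_network`.
#' @param activities Edge table from [reaction_activities()].
#' @param target_class Lipid class code.
#' @param z_cut Activity cutoff.
#' @return List: `z_synthesis`, `z_degradation`, `n_in`, `n_out`,
#'   `verdict_synthesis`, `verdict_degradation`; a side with no edges is
#'   `NA` with verdict `"undefined"`.
#' @export
synthesis_degradation <- function(network, activities, target_class,
                                  z_cut = z_critical(0.05)) {
  stopifnot(inherits(network, "reaction_network"))
  has_any <- target_class %in% c(network$edges$substrate, network$edges$product)
  if (!has_any)
    stop(sprintf("class %s has no incoming or outgoing edges in the network",
                 target_class), call. = FALSE)
  z_in <- activities$z[activities$product == target_class]
  z_out <- activities$z[activities$substrate == target_class]
  agg <- function(z) {
    if (!length(z)) return(list(z = NA_real_, verdict = "undefined"))
    r <- pathway_z(z, k = length(z) + 1L, z_cut = z_cut)
    list(z = r$z_a, verdict = r$verdict)
  }
  s <- agg(z_in); d <- agg(z_out)
  list(z_synthesis = s$z, z_degradation = d$z,
       n_in = length(z_in), n_out = length(z_out),
       verdict_synthesis = s$verdict, verdict_degradation = d$verdict)
}
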