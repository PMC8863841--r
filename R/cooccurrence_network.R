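#' Assemble aligned node blocks for a co-occurrence network
#'
#' Stacks per-animal measurement blocks (taxa, lipid species, behaviors,
#' ...) into one samples x nodes matrix with a node-kind label, verifying
#' that every block shares the same sample ordering.
#'
#' @param blocks Named list of numeric matrices, each variables x samples
#'   with identical sample columns; names give the node kind
#'   (e.g. `"bacterium"`, `"virus"`, `"lipid"`, `"behavior"`).
#' @return An object of class `node_set`: `values` (samples x nodes),
#'   `kind` (per node), `samples`.
#' @export
node_set <- function(blocks) {
  stopifnot(is.list(blocks), length(blocks) >= 1,
            !is.null(names(blocks)), all(nzchar(names(blocks))))
  samples <- colnames(blocks[[1]])
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    if (!is.matrix(b) || is.null(colnames(b)) || is.null(rownames(b)))
      stop("every block must be a matrix with row and column names", call. = FALSE)
    if (!identical(colnames(b), samples))
      stop(sprintf("block '%s' does not share the common sample ordering", nm),
           call. = FALSE)
  }
  values <- t(do.call(rbind, unname(blocks)))
  kind <- rep(names(blocks), vapply(blocks, nrow, integer(1)))
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  if (anyDuplicated(ids))
    stop("node ids must be unique across blocks", call. = FALSE)
  colnames(values) <- ids
  structure(list(values = values, kind = stats::setNames(kind, ids),
                 samples = samples),
            class = "node_set")
}

#' Thresholded Spearman co-occurrence graph
#'
#' Computes all pairwise Spearman rank correlations (midranks for ties)
#' among the nodes and retains the edges with `p < alpha` and
#' `|rho| > rho_threshold` (both strict). Constant node vectors have
#' undefined rank correlations and are excluded with a warning. P values
#' use the t approximation on midranks by default; for small designs an
#' exact permutation p value (via `cor.test`, no-ties case) can be
#' requested.
#'
#' @param nodes A `node_set` (or samples x nodes numeric matrix).
#' @param rho_threshold Correlation magnitude cutoff (default 0.70,
#'   strict).
#' @param alpha Significance cutoff (default 0.05, strict).
#' @param p_method `"approx"` (t approximation) or `"exact"` (exact
#'   Spearman p via \code{cor.test} when there are no ties; falls back to
#'   the approximation with a warning otherwise).
#' @return An object of class `correlation_graph`: `nodes` (data frame
#'   `id`, `kind`), `edges` (retained edges: `a`, `b`, `rho`, `p_value`,
#'   with `a < b` canonically), and `all_pairs` (every tested pair).
#' @export
spearman_edges <- function(nodes, rho_threshold = 0.70, alpha = 0.05,
                           p_method = c("approx", "exact")) {
  p_method <- match.arg(p_method)
  if (inherits(nodes, "node_set")) {
    values <- nodes$values
    kind <- nodes$kind
  } else {
    values <- nodes
    kind <- stats::setNames(rep("node", ncol(values)), colnames(values))
  }
  n <- nrow(values)
  if (n < 5) stop("at least 5 aligned samples are required", call. = FALSE)
  const <- apply(values, 2, function(v) length(unique(v)) == 1)
  if (any(const)) {
    warning("excluding constant node(s): ",
            paste(colnames(values)[const], collapse = ", "))
    values <- values[, !const, drop = FALSE]
    kind <- kind[!const]
  }
  ids <- colnames(values)
  rho <- stats::cor(values, method = "spearman")
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  p <- vapply(seq_len(nrow(pairs)), function(i) {
    r <- rho[pairs[i, 1], pairs[i, 2]]
    if (p_method == "exact") {
      ct <- suppressWarnings(
        stats::cor.test(values[, pairs[i, 1]], values[, pairs[i, 2]],
                        method = "spearman", exact = TRUE))
      return(ct$p.value)
    }
    if (abs(r) >= 1) return(0)
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }, numeric(1))
  all_pairs <- data.frame(
    a = pmin(ids[pairs[, 1]], ids[pairs[, 2]]),
    b = pmax(ids[pairs[, 1]], ids[pairs[, 2]]),
    rho = rho[pairs],
    p_value = p,
    stringsAsFactors = FALSE
  )
  retained <- all_pairs[abs(all_pairs$rho) > rho_threshold &
                          all_pairs$p_value < alpha, , drop = FALSE]
  retained <- retained[order(retained$a, retained$b), , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(
    nodes = data.frame(id = ids, kind = unname(kind[ids]),
                       stringsAsFactors = FALSE),
    edges = retained,
    all_pairs = all_pairs,
    rho_threshold = rho_threshold, alpha = alpha
  ), class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat(sprintf("<correlation_graph> %d nodes, %d retained edges (|rho| > %.2f, p < %.2f)\n",
              nrow(x$nodes), nrow(x$edges), x$rho_threshold, x$alpha))
  invisible(x)
}

#' Connected-component clusters of a correlation graph
#'
#' Approximates visual cluster membership by the connected components of
#' the thresholded graph (a reimplementation choice; no layout is
#' computed).
#'
#' @param graph A `correlation_graph`.
#' @return Named integer vector: component id per node (isolated nodes get
#'   their own component).
#' @export
graph_clusters <- function(graph) {
  g <- .as_igraph(graph)
  stats::setNames(igraph::components(g)$membership, igraph::V(g)$name)
}

.as_igraph <- function(graph) {
  stopifnot(inherits(graph, "correlation_graph"))
  igraph::graph_from_data_frame(
    graph$edges[, c("a", "b", "rho", "p_value")],
    directed = FALSE,
    vertices = graph$nodes[, c("id", "kind")]
  )
}

#' Export a correlation graph
#'
#' Writes GraphML (node `kind` attribute; edge `rho` and `p_value`
#' attributes) and optionally a flat edge-list TSV.
#'
#' @param graph A `correlation_graph`.
#' @param path Output GraphML path.
#' @param edges_tsv Optional path for the edge-list TSV.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, edges_tsv = NULL) {
  g <- .as_igraph(graph)
  tryCatch(igraph::write_graph(g, path, format = "graphml"),
           error = function(e)
             stop("cannot write GraphML to '", path, "': ",
                  conditionMessage(e), call. = FALSE))
  if (!is.null(edges_tsv))
    utils::write.table(graph$edges, edges_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}
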