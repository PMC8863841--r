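#' Construct a feature table
#'
#' The central container for abundance data: a nonnegative numeric matrix of
#' features (rows) by samples (columns) with a group label (`"DL"` /
#' `"HC"` in the shipped defaults) and optional tissue label per sample, and
#' a flag recording whether the table has been normalized to percent of
#' total peak area.
#'
#' @param values Numeric matrix, features x samples, with rownames and
#'   colnames.
#' @param group Character/factor of length `ncol(values)`.
#' @param tissue Optional tissue label (length 1 or `ncol(values)`).
#' @param normalized Logical; if `TRUE` each column must sum to 100
#'   (within 1e-6).
#' @return An object of class `feature_table` with elements `values`,
#'   `sample_info` (data frame: sample, group, tissue) and `normalized`.
#' @export
feature_table <- function(values, group, tissue = NA_character_,
                          normalized = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("abundances must be nonnegative and non-missing", call. = FALSE)
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` must provide one label per sample column", call. = FALSE)
  tissue <- rep_len(as.character(tissue), ncol(values))
  if (isTRUE(normalized)) {
    bad <- which(abs(colSums(values) - 100) > 1e-6)
    if (length(bad))
      stop("normalized table columns must sum to 100; offending sample(s): ",
           paste(colnames(values)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(
    values = values,
    sample_info = data.frame(sample = colnames(values), group = group,
                             tissue = tissue, stringsAsFactors = FALSE),
    normalized = isTRUE(normalized)
  ), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) "normalized, %% of total area" else "raw peak areas"))
  tab <- table(x$sample_info$group)
  cat("  groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: rebuild preserving metadata, skipping the column-sum check
# (row subsets of a normalized table no longer sum to 100)
.ft_replace_values <- function(table, values, normalized = table$normalized) {
  out <- table
  out$values <- values
  out$normalized <- normalized
  out
}

#' Subset a feature table by feature
#'
#' @param table A `feature_table`.
#' @param keep Logical/integer/character index into the feature rows.
#' @return A `feature_table` with the selected rows. The `normalized` flag is
#'   cleared because a row subset of a normalized table no longer sums
#'   to 100.
#' @export
subset_features <- function(table, keep) {
  stopifnot(inherits(table, "feature_table"))
  .ft_replace_values(table, table$values[keep, , drop = FALSE],
                     normalized = FALSE)
}

#' Group labels of a feature table
#' @param table A `feature_table`.
#' @return Character vector aligned with the sample columns.
#' @export
ft_groups <- function(table) table$sample_info$group

#' Write / read a lipid feature table as TSV
#'
#' The on-disk layout mirrors a LipidSearch-style export: columns `name`,
#' `Rej`, `PQ`, `CV`, `ppm` (when a QC table is supplied), then one column
#' per sample. Comment header lines (`#`) record the seed and the sample ->
#' group/tissue map, so a table round-trips without a sidecar file; a
#' sidecar map is also accepted on read.
#'
#' @param table A `feature_table`.
#' @param path Output TSV path.
#' @param qc Optional QC data frame (`name`, `rej`, `pq`, `cv`, `ppm`)
#'   aligned with the feature rows.
#' @param seed Optional integer recorded in a header comment.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, qc = NULL, seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  si <- table$sample_info
  hdr <- c(
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    sprintf("# normalized: %s", table$normalized),
    sprintf("# sample: %s\tgroup=%s\ttissue=%s", si$sample, si$group, si$tissue)
  )
  df <- data.frame(name = rownames(table$values), stringsAsFactors = FALSE)
  if (!is.null(qc)) {
    if (nrow(qc) != nrow(table$values))
      stop("QC table must align 1:1 with feature rows", call. = FALSE)
    df$Rej <- qc$rej; df$PQ <- qc$pq; df$CV <- qc$cv; df$ppm <- qc$ppm
  }
  df <- cbind(df, as.data.frame(table$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param sample_map Optional path to a sidecar TSV with columns `sample`,
#'   `group`, `tissue`; overrides the header comments.
#' @return For `read_lipid_table()`: a list with `table` (a
#'   `feature_table`) and `qc` (a QC data frame or `NULL`).
#' @export
read_lipid_table <- function(path, sample_map = NULL) {
  hdr <- grep("^#", readLines(path, n = 200L), value = TRUE)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  qc_cols <- c("Rej", "PQ", "CV", "ppm")
  has_qc <- all(qc_cols %in% names(df))
  qc <- NULL
  if (has_qc)
    qc <- data.frame(name = df$name, rej = df$Rej, pq = df$PQ, cv = df$CV,
                     ppm = df$ppm, stringsAsFactors = FALSE)
  sample_cols <- setdiff(names(df), c("name", qc_cols))
  values <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(values) <- df$name
  if (!is.null(sample_map)) {
    map <- utils::read.delim(sample_map, stringsAsFactors = FALSE)
  } else {
    ln <- grep("^# sample:", hdr, value = TRUE)
    if (!length(ln))
      stop("no sample map: supply `sample_map` or header '# sample:' lines",
           call. = FALSE)
    fields <- strsplit(sub("^# sample: ", "", ln), "\t")
    map <- data.frame(
      sample = vapply(fields, `[`, character(1), 1),
      group = sub("^group=", "", vapply(fields, `[`, character(1), 2)),
      tissue = sub("^tissue=", "", vapply(fields, `[`, character(1), 3)),
      stringsAsFactors = FALSE
    )
  }
  map <- map[match(colnames(values), map$sample), ]
  if (anyNA(map$group))
    stop("sample map does not cover all sample columns", call. = FALSE)
  normalized <- any(grepl("^# normalized: TRUE", hdr))
  list(table = feature_table(values, group = map$group, tissue = map$tissue,
                             normalized = normalized),
       qc = qc)
}
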