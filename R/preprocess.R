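#' Quality-control thresholds for peak filtering
#'
#' Defaults follow the LipidSearch-style acceptance rules: a feature is kept
#' when `Rej == 0`, `PQ > 0.85` (strict), `CV < 0.3` (strict) and mass
#' deviation `|ppm| <= 5` (inclusive tolerance).
#'
#' @param rej_eq Required exact value of the reject flag.
#' @param pq_gt Peak-quality lower bound (strict).
#' @param cv_lt Coefficient-of-variation upper bound (strict).
#' @param ppm_le Mass-deviation tolerance in ppm (inclusive).
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(rej_eq = 0, pq_gt = 0.85, cv_lt = 0.3, ppm_le = 5) {
  stopifnot(pq_gt >= 0, pq_gt <= 1, cv_lt > 0, ppm_le > 0)
  list(rej_eq = rej_eq, pq_gt = pq_gt, cv_lt = cv_lt, ppm_le = ppm_le)
}

#' Apply peak quality-control filters
#'
#' Retains exactly the features whose QC fields satisfy every criterion in
#' `thresholds` (conjunction), preserving feature order. A per-criterion
#' rejection count is attached as attribute `"filter_report"` (a feature
#' failing several criteria is counted under each).
#'
#' @param table An un-normalized `feature_table`.
#' @param qc QC data frame aligned 1:1 with the feature rows, with columns
#'   `rej`, `pq`, `cv`, `ppm` (a `name` column, if present, must match the
#'   feature rownames).
#' @param thresholds See [qc_thresholds()].
#' @return Filtered `feature_table`; attributes `filter_report`
#'   (data frame criterion/removed) and `qc_keep` (logical keep mask).
#' @export
apply_qc_filters <- function(table, qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(table, "feature_table"))
  if (table$normalized)
    stop("QC filtering must run on the raw (un-normalized) table", call. = FALSE)
  if (nrow(qc) != nrow(table$values))
    stop(sprintf("QC table (%d rows) does not align with feature table (%d rows)",
                 nrow(qc), nrow(table$values)), call. = FALSE)
  if (!is.null(qc$name) && !identical(as.character(qc$name), rownames(table$values)))
    stop("QC `name` column does not match feature rownames", call. = FALSE)
  pass <- list(
    rej = qc$rej == thresholds$rej_eq,
    pq  = qc$pq > thresholds$pq_gt,
    cv  = qc$cv < thresholds$cv_lt,
    ppm = abs(qc$ppm) <= thresholds$ppm_le
  )
  keep <- Reduce(`&`, pass)
  report <- data.frame(
    criterion = c("rej", "pq", "cv", "ppm", "any"),
    removed = c(vapply(pass, function(p) sum(!p), integer(1)), sum(!keep)),
    stringsAsFactors = FALSE
  )
  out <- subset_features(table, keep)
  attr(out, "filter_report") <- report
  attr(out, "qc_keep") <- keep
  out
}

#' Normalize a feature table to percent of total peak area
#'
#' Each value is replaced by `100 * value / column_sum`, so every sample
#' column sums to 100. Refuses to run twice (double-normalization guard).
#'
#' @param table An un-normalized `feature_table` whose column sums are all
#'   positive.
#' @return A normalized `feature_table`.
#' @export
normalize_total_area <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$normalized)
    stop("table is already normalized to percent of total area", call. = FALSE)
  cs <- colSums(table$values)
  bad <- which(cs <= 0)
  if (length(bad))
    stop("cannot normalize sample(s) with zero total peak area: ",
         paste(colnames(table$values)[bad], collapse = ", "), call. = FALSE)
  vals <- sweep(table$values, 2, cs / 100, "/")
  .ft_replace_values(table, vals, normalized = TRUE)
}

#' Merge positive/negative ionization mode tables
#'
#' Filters are expected to have been applied per mode; this concatenates the
#' two feature sets and resolves species names present in both modes by
#' keeping the row with the higher mean abundance (logged via message).
#'
#' @param pos,neg `feature_table`s with identical sample columns.
#' @return Combined `feature_table`.
#' @export
merge_ion_modes <- function(pos, neg) {
  stopifnot(inherits(pos, "feature_table"), inherits(neg, "feature_table"))
  if (!identical(colnames(pos$values), colnames(neg$values)))
    stop("ionization-mode tables must share the same sample columns", call. = FALSE)
  dup <- intersect(rownames(pos$values), rownames(neg$values))
  if (length(dup)) {
    keep_pos <- rowMeans(pos$values[dup, , drop = FALSE]) >=
      rowMeans(neg$values[dup, , drop = FALSE])
    drop_neg <- dup[keep_pos]
    drop_pos <- dup[!keep_pos]
    message(sprintf("merge_ion_modes: %d duplicate species resolved by higher mean abundance",
                    length(dup)))
    pos <- subset_features(pos, setdiff(rownames(pos$values), drop_pos))
    neg <- subset_features(neg, setdiff(rownames(neg$values), drop_neg))
  }
  feature_table(rbind(pos$values, neg$values), group = pos$sample_info$group,
                tissue = pos$sample_info$tissue, normalized = FALSE)
}
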