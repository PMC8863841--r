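# two-sample t test returning fold change, t, p; pooled variance by default
# ("Student's"), Welch by flag. `case` mean in the numerator of the fold
# change.
.t_fold <- function(x_case, x_ctrl, var_equal = TRUE) {
  fc <- if (mean(x_ctrl) == 0) NA_real_ else mean(x_case) / mean(x_ctrl)
  tt <- tryCatch(stats::t.test(x_case, x_ctrl, var.equal = var_equal),
                 error = function(e) NULL)   # constant data
  if (is.null(tt))
    return(list(fold_change = fc, t = 0,
                p = if (mean(x_case) == mean(x_ctrl)) 1 else 0))
  list(fold_change = fc, t = unname(tt$statistic), p = tt$p.value)
}

.split_groups <- function(groups, case = "DL", control = "HC") {
  if (!all(c(case, control) %in% groups))
    stop(sprintf("both groups '%s' and '%s' must be present", case, control),
         call. = FALSE)
  list(case = which(groups == case), control = which(groups == control))
}

#' Aggregate a feature table to subclass abundance
#'
#' Sums normalized species abundances within each lipid subclass. When the
#' subclasses partition the feature set, columns still sum to 100.
#'
#' @param table A normalized `feature_table`.
#' @param annotations Data frame from [annotate_species()] covering the
#'   features (matched by `name`).
#' @param unparseable `"error"` (default) or `"skip"`: what to do with
#'   features missing from `annotations` (skipped features are logged via
#'   message).
#' @return Numeric matrix, subclasses x samples.
#' @export
subclass_abundance <- function(table, annotations, unparseable = c("error", "skip")) {
  stopifnot(inherits(table, "feature_table"))
  unparseable <- match.arg(unparseable)
  if (!table$normalized)
    stop("subclass aggregation expects a normalized table", call. = FALSE)
  idx <- match(rownames(table$values), annotations$name)
  if (anyNA(idx)) {
    miss <- rownames(table$values)[is.na(idx)]
    if (unparseable == "error")
      stop("features without annotation: ", paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5),
           call. = FALSE)
    message(sprintf("subclass_abundance: skipping %d unannotated feature(s)",
                    length(miss)))
  }
  keep <- !is.na(idx)
  sub <- annotations$subclass[idx[keep]]
  rowsum(table$values[keep, , drop = FALSE], group = sub)
}

#' Subclass-level differential test
#'
#' For each subclass, the fold change `mean(DL)/mean(HC)` of summed
#' normalized abundance and a two-sided unpaired t test on the per-sample
#' subclass abundances.
#'
#' @param mat Subclass x sample matrix from [subclass_abundance()].
#' @param groups Group label per sample column.
#' @param annotations Optional annotations to report `n_species` per
#'   subclass.
#' @param case,control Group labels (fold change = case mean / control mean).
#' @param var_equal `TRUE` for pooled-variance Student's t (default), `FALSE`
#'   for Welch.
#' @return Data frame: `subclass`, `fold_change`, `t`, `p_value`,
#'   `n_species` (NA when `annotations` is missing). A zero control mean
#'   yields `fold_change = NA` (flagged, not an error).
#' @export
subclass_test <- function(mat, groups, annotations = NULL,
                          case = "DL", control = "HC", var_equal = TRUE) {
  g <- .split_groups(groups, case, control)
  if (length(g$case) < 2 || length(g$control) < 2)
    stop("at least 2 samples per group are required", call. = FALSE)
  res <- lapply(rownames(mat), function(sc) {
    r <- .t_fold(mat[sc, g$case], mat[sc, g$control], var_equal)
    n_sp <- if (is.null(annotations)) NA_integer_
            else sum(annotations$subclass == sc)
    data.frame(subclass = sc, fold_change = r$fold_change, t = r$t,
               p_value = r$p, n_species = n_sp, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Chain-length / unsaturation structure profile
#'
#' Bins the species of one subclass by total carbon count or total double
#' bonds, sums normalized abundance within each bin per sample, and tests
#' each bin with a two-sided unpaired t test. Bins are exactly the values
#' observed in the annotation set for that subclass.
#'
#' @param table Normalized `feature_table`.
#' @param annotations Annotations covering the subclass' features.
#' @param subclass Subclass code.
#' @param axis `"total_carbons"` or `"double_bonds"`.
#' @inheritParams subclass_test
#' @return Data frame: `subclass`, `axis`, `bin`, `mean_case`, `mean_control`,
#'   `fold_change`, `p_value`, `n_species`. Empty (with a warning) when the
#'   subclass is absent.
#' @export
structure_profile <- function(table, annotations, subclass,
                              axis = c("total_carbons", "double_bonds"),
                              groups = ft_groups(table),
                              case = "DL", control = "HC", var_equal = TRUE) {
  axis <- match.arg(axis)
  stopifnot(inherits(table, "feature_table"))
  ann <- annotations[annotations$subclass == subclass &
                       annotations$name %in% rownames(table$values), , drop = FALSE]
  empty <- data.frame(subclass = character(0), axis = character(0),
                      bin = integer(0), mean_case = numeric(0),
                      mean_control = numeric(0), fold_change = numeric(0),
                      p_value = numeric(0), n_species = integer(0))
  if (!nrow(ann)) {
    warning(sprintf("no %s species in table; returning empty profile", subclass))
    return(empty)
  }
  col <- if (axis == "total_carbons") ann$total_carbons else ann$total_double_bonds
  g <- .split_groups(groups, case, control)
  binned <- rowsum(table$values[ann$name, , drop = FALSE], group = col)
  res <- lapply(rownames(binned), function(b) {
    r <- .t_fold(binned[b, g$case], binned[b, g$control], var_equal)
    data.frame(subclass = subclass, axis = axis, bin = as.integer(b),
               mean_case = mean(binned[b, g$case]),
               mean_control = mean(binned[b, g$control]),
               fold_change = r$fold_change, p_value = r$p,
               n_species = sum(col == as.integer(b)), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis by the NIPALS algorithm on
#' mean-centred, unit-variance-scaled data with a centred two-class dummy
#' response (+1 for `case`, -1 for `control`). Per-feature VIP (variable
#' importance in projection) scores are computed across all fitted
#' components; their mean square is 1 by construction.
#'
#' @param table A `feature_table` or numeric matrix (features x samples).
#' @param groups Group labels per sample.
#' @param n_components Number of latent components (default 2, the usual
#'   choice for score plots); must not exceed `min(samples - 1, features)`.
#' @param case,control Group labels.
#' @return An object of class `plsda_model`: `scores` (samples x comps),
#'   `weights`, `loadings` (features x comps), `q` (response loadings),
#'   `explained_y_variance`, `vip` (named per-feature), `features` (kept
#'   feature names), `dropped` (zero-variance features).
#' @export
plsda_fit <- function(table, groups, n_components = 2,
                      case = "DL", control = "HC") {
  vals <- if (inherits(table, "feature_table")) table$values else table
  g <- .split_groups(groups, case, control)
  X <- t(vals)                                   # samples x features
  y <- ifelse(groups == case, 1, -1)
  keep <- apply(X, 2, stats::sd) > 0
  if (any(!keep))
    message(sprintf("plsda_fit: dropping %d zero-variance feature(s)", sum(!keep)))
  X <- X[, keep, drop = FALSE]
  p <- ncol(X)
  n <- nrow(X)
  if (n_components > min(n - 1, p))
    stop("n_components exceeds min(samples - 1, features)", call. = FALSE)
  X <- scale(X)                                  # autoscale (SIMCA convention)
  y <- y - mean(y)
  ss_y <- sum(y^2)
  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xd <- X; yd <- y
  for (h in seq_len(n_components)) {
    w <- drop(crossprod(Xd, yd))
    w <- w / sqrt(sum(w^2))
    t_h <- drop(Xd %*% w)
    tt <- sum(t_h^2)
    p_h <- drop(crossprod(Xd, t_h)) / tt
    q_h <- sum(yd * t_h) / tt
    Xd <- Xd - tcrossprod(t_h, p_h)
    yd <- yd - q_h * t_h
    W[, h] <- w; P[, h] <- p_h; Tm[, h] <- t_h; q[h] <- q_h
  }
  expl_y <- q^2 * colSums(Tm^2) / ss_y
  ss_h <- q^2 * colSums(Tm^2)                    # response SS per component
  vip <- sqrt(p * drop(W^2 %*% ss_h) / sum(ss_h))
  names(vip) <- colnames(X)
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(Tm) <- rownames(X)
  structure(list(scores = Tm, weights = W, loadings = P, q = q,
                 explained_y_variance = expl_y, vip = vip,
                 features = colnames(X),
                 dropped = rownames(vals)[!keep],
                 groups = groups, case = case, control = control),
            class = "plsda_model")
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d features, %d components; R2Y = %s\n",
              length(x$vip), length(x$q),
              paste(sprintf("%.3f", x$explained_y_variance), collapse = " + ")))
  invisible(x)
}

#' Discriminating species by the VIP / p-value double cutoff
#'
#' Returns exactly the features with `VIP > vip_threshold` and a two-sided
#' unpaired t-test `p < alpha` on normalized abundance; direction is the
#' sign of the case-control mean difference.
#'
#' @param table Normalized `feature_table` the model was fitted on.
#' @param groups Group labels.
#' @param model A `plsda_model` from [plsda_fit()].
#' @param vip_threshold VIP cutoff (default 1.0, strict).
#' @param alpha Significance level (default 0.05, strict).
#' @inheritParams subclass_test
#' @return Data frame: `species`, `vip`, `p_value`, `direction`
#'   (`"up_in_DL"` / `"down_in_DL"`, with `DL` replaced by `case`), sorted
#'   by decreasing VIP.
#' @export
discriminating_species <- function(table, groups, model, vip_threshold = 1.0,
                                   alpha = 0.05, case = "DL", control = "HC",
                                   var_equal = TRUE) {
  stopifnot(inherits(model, "plsda_model"))
  vals <- if (inherits(table, "feature_table")) table$values else table
  g <- .split_groups(groups, case, control)
  feats <- model$features
  stats_ <- lapply(feats, function(f)
    .t_fold(vals[f, g$case], vals[f, g$control], var_equal))
  p <- vapply(stats_, `[[`, numeric(1), "p")
  up <- vapply(feats, function(f)
    mean(vals[f, g$case]) > mean(vals[f, g$control]), logical(1))
  out <- data.frame(species = feats, vip = unname(model$vip[feats]),
                    p_value = p,
                    direction = ifelse(up, paste0("up_in_", case),
                                       paste0("down_in_", case)),
                    stringsAsFactors = FALSE)
  out <- out[out$vip > vip_threshold & out$p_value < alpha, , drop = FALSE]
  out[order(-out$vip), , drop = FALSE]
}
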