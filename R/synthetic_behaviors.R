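.default_behaviors <- c("huddle", "sit_alone", "locomotion", "amicable",
                        "communication")

# plausible mean observation durations (seconds) per behavior
.behavior_base <- c(huddle = 1200, sit_alone = 900, locomotion = 600,
                    amicable = 300, communication = 120)

#' Configuration for the synthetic behavior generator
#'
#' Behaviors are per-animal observation durations (seconds). A coupling
#' ties a behavior to a molecular feature at a target Spearman sign and
#' strength via rank blending: the behavior's latent score is a weighted
#' average of the feature's (possibly reversed) ranks and independent noise
#' ranks, so `strength` is directly interpretable as the share of rank
#' signal.
#'
#' @param behaviors Behavior labels.
#' @param couplings Data frame (`behavior`, `feature`, `strength`) with
#'   `|strength| <= 1`; the sign sets the target correlation direction.
#' @param noise_sd Standard deviation of the latent noise; `0` makes a
#'   coupled behavior an exact monotone transform of its feature.
#' @param seed Integer seed.
#' @return A `behavior_sim_config` list.
#' @export
behavior_sim_config <- function(behaviors = .default_behaviors,
                                couplings = NULL, noise_sd = 1, seed = 1L) {
  cpl <- if (is.null(couplings))
    data.frame(behavior = character(0), feature = character(0),
               strength = numeric(0), stringsAsFactors = FALSE)
  else as.data.frame(couplings, stringsAsFactors = FALSE)
  if (nrow(cpl)) {
    if (!all(c("behavior", "feature", "strength") %in% names(cpl)))
      stop("couplings needs columns behavior, feature, strength", call. = FALSE)
    if (any(abs(cpl$strength) > 1))
      stop("coupling |strength| must not exceed 1", call. = FALSE)
    bad <- setdiff(cpl$behavior, behaviors)
    if (length(bad))
      stop("coupling references unknown behavior(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(behaviors = behaviors, couplings = cpl, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Generate synthetic behavior durations
#'
#' @param config A [behavior_sim_config()].
#' @param features A `feature_table` (or numeric matrix features x samples)
#'   supplying the molecular signals that coupled behaviors track. Sample
#'   columns define the animals.
#' @return A `behavior_table`: list with `values` (behaviors x animals,
#'   strictly positive durations in seconds) and `sample_info`.
#' @export
generate_behaviors <- function(config, features) {
  stopifnot(inherits(config, "behavior_sim_config"))
  vals_in <- if (inherits(features, "feature_table")) features$values else features
  if (!is.matrix(vals_in)) stop("`features` must be a feature_table or matrix",
                                call. = FALSE)
  cpl <- config$couplings
  missing_feat <- setdiff(cpl$feature, rownames(vals_in))
  if (length(missing_feat))
    stop("coupled feature id(s) not present in `features`: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  n <- ncol(vals_in)
  .with_seed(config$seed, {
    out <- matrix(NA_real_, nrow = length(config$behaviors), ncol = n,
                  dimnames = list(config$behaviors, colnames(vals_in)))
    for (b in config$behaviors) {
      base <- if (b %in% names(.behavior_base)) .behavior_base[[b]] else 600
      row <- cpl[cpl$behavior == b, , drop = FALSE]
      if (nrow(row)) {
        s <- row$strength[1]
        x <- vals_in[row$feature[1], ]
        r_f <- rank(if (s >= 0) x else -x, ties.method = "average")
        noise <- stats::rnorm(n, 0, config$noise_sd)
        r_n <- rank(noise, ties.method = "average")
        blended <- abs(s) * r_f + (1 - abs(s)) * r_n
        z <- (blended - mean(blended)) / max(stats::sd(blended), 1e-12)
        out[b, ] <- base * exp(0.4 * z)   # monotone, strictly positive
      } else {
        out[b, ] <- base * exp(stats::rnorm(n, 0, 0.5))
      }
    }
    structure(list(values = out,
                   sample_info = data.frame(sample = colnames(vals_in),
                                            stringsAsFactors = FALSE)),
              class = "behavior_table", config = config)
  })
}

#' @export
print.behavior_table <- function(x, ...) {
  cat(sprintf("<behavior_table> %d behaviors x %d animals (seconds)\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}
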