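# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Set overlap utilities
#'
#' Small helpers for the overlap and composition summaries used when
#' comparing species lists across tissues or annotating differential taxa:
#' `overlap_fraction(a, b)` is the fraction of `a`'s elements also present
#' in `b`; `shared_fraction(sets)` is the size of the intersection of all
#' sets over the size of their union; `fraction_matching(x, target)` is the
#' fraction of annotation values falling in `target`.
#'
#' @param a,b Character vectors (duplicates ignored).
#' @param sets A list of character vectors.
#' @param x Vector of annotation values (e.g. taxonomic order per species).
#' @param target Value(s) counted as a match.
#' @return A proportion in `[0, 1]`.
#' @examples
#' overlap_fraction(letters[1:4], letters[3:6])  # 0.5
#' @export
overlap_fraction <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (!length(a)) stop("`a` must be nonempty", call. = FALSE)
  length(intersect(a, b)) / length(a)
}

#' @rdname overlap_fraction
#' @export
shared_fraction <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, unique)
  length(Reduce(intersect, sets)) / length(Reduce(union, sets))
}

#' @rdname overlap_fraction
#' @export
fraction_matching <- function(x, target) {
  if (!length(x)) stop("`x` must be nonempty", call. = FALSE)
  mean(x %in% target)
}
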