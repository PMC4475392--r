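#' Normal-scores (rank-order) transformation
#'
#' Maps data to standard-normal quantiles of their Hazen plotting positions
#' \eqn{(r - 0.5)/n}, so that Gaussian geostatistics can be applied to
#' arbitrarily distributed variables.  Ties receive average ranks and hence a
#' shared score.  The returned map supports the inverse transform.
#'
#' @param values numeric vector, n >= 3, all finite.
#' @return list with elements `scores` (numeric, same order as input) and
#'   `map` (class `normal_scores_map`, the empirical score-value graph).
#' @export
normal_scores_transform <- function(values) {
  if (length(values) < 3L || any(!is.finite(values)))
    stop("need >= 3 finite values", call. = FALSE)
  if (length(unique(values)) == 1L)
    stop("all values identical: no rank information to transform",
         call. = FALSE)
  n <- length(values)
  r <- rank(values, ties.method = "average")
  scores <- qnorm((r - 0.5) / n)
  ord <- order(values)
  knots <- unique(data.frame(value = values[ord], score = scores[ord]))
  map <- structure(
    list(values = knots$value, scores = knots$score, n = n,
         tie_policy = "average-rank, shared score (Hazen positions)"),
    class = "normal_scores_map"
  )
  list(scores = scores, map = map)
}

#' Back-transform normal scores to the original scale
#'
#' Piecewise-linear inverse of the empirical score-value graph; scores beyond
#' the observed score range clamp to the minimum/maximum observed value (no
#' tail model is invented).
#'
#' @param scores numeric vector of normal scores.
#' @param map a `normal_scores_map` from [normal_scores_transform()].
#' @return numeric vector on the original scale.
#' @export
normal_scores_backtransform <- function(scores, map) {
  if (!inherits(map, "normal_scores_map") || length(map$values) == 0L)
    stop("`map` must be a non-empty normal_scores_map", call. = FALSE)
  if (length(map$values) == 1L) return(rep(map$values, length(scores)))
  approx(x = map$scores, y = map$values, xout = scores, rule = 2,
         ties = "ordered")$y
}
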