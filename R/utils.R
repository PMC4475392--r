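#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx aggregate cmdscale cor dist lm model.matrix
#'   optim pnorm prcomp qnorm quantile rnorm runif sd setNames uniroot var
#'   median rmultinom complete.cases
#' @importFrom utils read.csv write.csv read.delim write.table head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a named child seed from a master seed
#'
#' Every stochastic pipeline stage receives its own deterministic seed so that
#' stages can be re-run in isolation without replaying the whole stream.
#' The result is always a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return integer child seed.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- as.double(master) %% 2147483647
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h + 1)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

# Ezekiel adjustment of R-squared for a model with k predictors (no
# intercept counted) fitted to n observations.
adjust_r2 <- function(r2, n, k) {
  if (k <= 0) return(0)
  if (n - k - 1 <= 0) return(NA_real_)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

# Add-one permutation p-value: #{null >= observed} with the observed value
# counted once in both numerator and denominator.
perm_pvalue <- function(observed, null) {
  (1 + sum(null >= observed)) / (1 + length(null))
}
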