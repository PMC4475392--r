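#' Specification of a synthetic soil field
#'
#' Bundles the name, Matern variogram, mean and target cross-correlations of
#' one simulated soil variable.  The variogram's total sill (`c0 + c1`) is
#' the marginal variance of the field.
#'
#' @param name field name (becomes the site-table column).
#' @param variogram a [variogram_model()].
#' @param mean field mean, in the variable's units.
#' @param cross_correlations named numeric vector of target Pearson
#'   correlations with partner fields; values in \[-1, 1\].
#' @return object of class `field_spec`.
#' @export
field_spec <- function(name, variogram, mean = 0, cross_correlations = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(variogram, "variogram_model"),
            is.numeric(mean), length(mean) == 1L)
  if (!is.null(cross_correlations)) {
    if (is.null(names(cross_correlations)) ||
        any(!nzchar(names(cross_correlations))))
      stop("cross_correlations must be a named vector", call. = FALSE)
    if (any(abs(cross_correlations) > 1))
      stop("target correlations must lie in [-1, 1]", call. = FALSE)
  }
  structure(list(name = name, variogram = variogram, mean = mean,
                 cross_correlations = cross_correlations),
            class = "field_spec")
}

#' Simulate a stationary Gaussian random field at the design sites
#'
#' One unconditional realization with Matern covariance
#' \eqn{c_1 \rho(h) + c_0 1\{h = 0\}} and the specified mean, drawn by
#' Cholesky factorization of the site covariance matrix.  Deterministic for
#' a given seed.
#'
#' @param design a [generate_sampling_design()] result, or any two-column
#'   coordinate matrix.
#' @param spec a [field_spec()].
#' @param seed integer seed.
#' @return numeric vector of per-site values.
#' @export
simulate_gaussian_field <- function(design, spec, seed = 1) {
  stopifnot(inherits(spec, "field_spec"))
  xy <- design_xy(design)
  C <- matern_covariance(as.matrix(dist(xy)), spec$variogram)
  cC <- tryCatch(chol(C), error = function(e)
    stop(sprintf(paste0("covariance matrix not positive definite at the ",
                        "site set for (c0=%.3g, c1=%.3g, a=%.3g, v=%.3g)"),
                 spec$variogram$c0, spec$variogram$c1, spec$variogram$a,
                 spec$variogram$v), call. = FALSE))
  z <- with_seed(seed, rnorm(nrow(xy)))
  spec$mean + as.numeric(crossprod(cC, z))
}

design_xy <- function(design) {
  if (is.data.frame(design) && all(c("x", "y") %in% names(design))) {
    cbind(design$x, design$y)
  } else {
    as.matrix(design)[, 1:2, drop = FALSE]
  }
}
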