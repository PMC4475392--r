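#' Matern variogram model
#'
#' Container for the parameters of an isotropic Matern variogram
#' \deqn{\gamma(h) = c_0 + c_1\,[1 - \rho(h)], \quad
#'       \rho(h) = \frac{2^{1-v}}{\Gamma(v)} (h/a)^v K_v(h/a),}
#' where \eqn{c_0} is the nugget, \eqn{c_1} the partial sill, \eqn{a} the
#' range parameter (distance units of the coordinates, metres throughout),
#' \eqn{v} the smoothness, and \eqn{K_v} the modified Bessel function of the
#' second kind.  \eqn{v = 0.5} recovers the exponential model.
#'
#' @param c0 nugget variance, >= 0.
#' @param c1 partial sill, >= 0.
#' @param a  range parameter in metres, > 0.
#' @param v  smoothness parameter, > 0.
#' @param method how the model was obtained ("manual", "wls" or "ml").
#' @param objective objective value at the optimum (WLS sum of squares or
#'   negative log-likelihood), if fitted.
#' @param at_bounds logical, TRUE when the optimizer stopped on a bound.
#' @return an object of class `variogram_model`.
#' @export
variogram_model <- function(c0, c1, a, v = 0.5, method = "manual",
                            objective = NA_real_, at_bounds = FALSE) {
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0)
    stop("nugget `c0` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(c1) || length(c1) != 1L || !is.finite(c1) || c1 < 0)
    stop("partial sill `c1` must be a single finite number >= 0", call. = FALSE)
  stop_if_not_scalar_pos(a, "a")
  stop_if_not_scalar_pos(v, "v")
  structure(
    list(c0 = c0, c1 = c1, a = a, v = v, method = method,
         objective = objective, at_bounds = isTRUE(at_bounds)),
    class = "variogram_model"
  )
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf(
    "Matern variogram model (%s): c0 = %.4g, c1 = %.4g, a = %.4g m, v = %.4g\n",
    x$method, x$c0, x$c1, x$a, x$v))
  if (is.finite(x$objective))
    cat(sprintf("  objective: %.6g%s\n", x$objective,
                if (x$at_bounds) "  [optimizer at bounds]" else ""))
  invisible(x)
}

# Matern correlation rho(h); rho(0) = 1.  Vectorised over h.
matern_correlation <- function(h, a, v) {
  u <- h / a
  out <- u * 0 # preserves dim for matrix input
  tiny <- u < 1e-10
  out[tiny] <- 1
  ub <- u[!tiny]
  if (length(ub)) {
    # besselK underflows to 0 for large u; the limit rho -> 0 is correct.
    out[!tiny] <- (2^(1 - v) / gamma(v)) * ub^v * besselK(ub, v)
  }
  out[!is.finite(out)] <- 0
  pmin(pmax(out, 0), 1)
}

#' Matern semivariance
#'
#' Evaluates the model semivariance \eqn{\gamma(h)}; \eqn{\gamma(0) = 0} by
#' convention (the nugget is a discontinuity at the origin).
#'
#' @param h nonnegative lag distances (metres).
#' @param model a [variogram_model()].
#' @return numeric vector of semivariances.
#' @export
matern_semivariance <- function(h, model) {
  stopifnot(inherits(model, "variogram_model"))
  if (any(h < 0)) stop("lag distances must be >= 0", call. = FALSE)
  gam <- model$c0 + model$c1 * (1 - matern_correlation(h, model$a, model$v))
  gam[h == 0] <- 0
  gam
}

# Covariance matrix of the model at a set of sites (stationary form):
# C_ij = c1 * rho(d_ij) for i != j, C_ii = c0 + c1.
matern_covariance <- function(dmat, model) {
  C <- model$c1 * matern_correlation(dmat, model$a, model$v)
  diag(C) <- model$c0 + model$c1
  C
}

#' Empirical variogram by the method of moments
#'
#' \deqn{\hat\gamma(h) = \frac{1}{2 N(h)} \sum_{(i,j) \in h} (z_i - z_j)^2}
#' over distance bins of equal width up to `max_lag`.  Empty bins are
#' reported with `NA` semivariance, not zero.
#'
#' @param site_xy two-column matrix of coordinates (metres).
#' @param values numeric vector of site values.
#' @param n_bins number of equal-width lag bins (default 15).
#' @param max_lag maximum pair distance retained; default half the maximum
#'   inter-site distance.
#' @return an object of class `empirical_variogram`: data frame with columns
#'   `h` (bin centre), `gamma_hat`, `n_pairs`.
#' @export
empirical_variogram <- function(site_xy, values, n_bins = 15, max_lag = NULL) {
  site_xy <- as.matrix(site_xy)
  if (nrow(site_xy) < 2L) stop("need at least 2 sites", call. = FALSE)
  stopifnot(length(values) == nrow(site_xy))
  d <- dist(site_xy)
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stop_if_not_scalar_pos(max_lag, "max_lag")
  dz2 <- dist(matrix(values, ncol = 1))^2
  keep <- d <= max_lag & d > 0
  breaks <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- cut(as.numeric(d)[keep], breaks, include.lowest = TRUE,
             labels = FALSE)
  n_pairs <- tabulate(bin, nbins = n_bins)
  ssq <- vapply(seq_len(n_bins), function(b) {
    sum(as.numeric(dz2)[keep][bin == b])
  }, numeric(1))
  gamma_hat <- ifelse(n_pairs > 0, ssq / (2 * n_pairs), NA_real_)
  structure(
    data.frame(h = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
               gamma_hat = gamma_hat, n_pairs = n_pairs),
    class = c("empirical_variogram", "data.frame"),
    max_lag = max_lag
  )
}

#' Fit a Matern variogram model
#'
#' Two routes, mirroring standard geostatistical practice:
#' \describe{
#'   \item{`method = "wls"`}{weighted nonlinear least squares on an
#'     [empirical_variogram()], minimizing
#'     \eqn{\sum_h N(h) (\hat\gamma(h) - \gamma(h;\theta))^2}.}
#'   \item{`method = "ml"`}{maximum likelihood under a stationary Gaussian
#'     model with constant unknown mean and Matern covariance, fitted
#'     directly to the site values (typically normal scores).  The total
#'     variance is profiled out analytically.}
#' }
#' Both routes run multiple optimizer starts and return the best; a model
#' whose optimum sits on a parameter bound is flagged.
#'
#' @param empirical an `empirical_variogram` (WLS) or NULL (ML).
#' @param method "wls" or "ml".
#' @param site_xy,values site coordinates and values, required for ML.
#' @param v smoothness; a fixed number, or NA to estimate it (ML bounds
#'   \[0.05, 5\]).
#' @param n_starts number of optimizer starts (default 5).
#' @param seed seed for the random starts.
#' @return a [variogram_model()].
#' @export
fit_variogram <- function(empirical = NULL, method = c("wls", "ml"),
                          site_xy = NULL, values = NULL, v = 0.5,
                          n_starts = 5, seed = 1) {
  method <- match.arg(method)
  if (method == "wls") {
    fit_variogram_wls(empirical, v = v, n_starts = n_starts, seed = seed)
  } else {
    fit_variogram_ml(site_xy, values, v = v, n_starts = n_starts, seed = seed)
  }
}

fit_variogram_wls <- function(empirical, v = 0.5, n_starts = 5, seed = 1) {
  stopifnot(inherits(empirical, "empirical_variogram"))
  ok <- is.finite(empirical$gamma_hat) & empirical$n_pairs > 0
  if (sum(ok) < 4L) stop("need at least 4 populated bins for WLS",
                         call. = FALSE)
  h <- empirical$h[ok]; g <- empirical$gamma_hat[ok]; w <- empirical$n_pairs[ok]
  est_v <- is.na(v)
  sill0 <- max(g)
  if (sill0 <= 0) { # constant field: gamma identically 0
    return(variogram_model(0, 0 + 1e-12, a = max(h), v = if (est_v) 0.5 else v,
                           method = "wls", objective = 0))
  }
  obj <- function(p) {
    m <- list(c0 = exp(p[1]), c1 = exp(p[2]), a = exp(p[3]),
              v = if (est_v) exp(p[4]) else v)
    gam <- m$c0 + m$c1 * (1 - matern_correlation(h, m$a, m$v))
    sum(w * (g - gam)^2)
  }
  starts <- with_seed(seed, {
    s <- list(c(log(sill0 * 0.1 + 1e-8), log(sill0 * 0.9), log(max(h) / 3),
                log(0.5)))
    for (i in seq_len(n_starts - 1L)) {
      s[[i + 1L]] <- c(log(sill0 * runif(1, 0.01, 0.5)),
                       log(sill0 * runif(1, 0.5, 1.5)),
                       log(max(h) * runif(1, 0.05, 1)),
                       log(runif(1, 0.2, 2)))
    }
    s
  })
  lower <- c(log(1e-10), log(sill0 * 1e-6), log(min(h[h > 0]) / 10), log(0.05))
  upper <- c(log(sill0 * 4 + 1e-8), log(sill0 * 4), log(max(h) * 10), log(5))
  np <- if (est_v) 4L else 3L
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0[seq_len(np)], obj, method = "L-BFGS-B",
            lower = lower[seq_len(np)], upper = upper[seq_len(np)]),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("WLS variogram fit failed in every start",
                          call. = FALSE)
  p <- best$par
  at_b <- any(abs(p - lower[seq_len(np)]) < 1e-6) ||
    any(abs(p - upper[seq_len(np)]) < 1e-6)
  variogram_model(exp(p[1]), exp(p[2]), exp(p[3]),
                  v = if (est_v) exp(p[4]) else v,
                  method = "wls", objective = best$value, at_bounds = at_b)
}

# Negative profile log-likelihood: correlation R = (1 - psi) rho + psi I with
# psi the nugget fraction; sigma^2 and the constant mean are profiled out.
matern_nll <- function(psi, loga, logv, dmat, z) {
  n <- length(z)
  R <- (1 - psi) * matern_correlation(dmat, exp(loga), exp(logv))
  diag(R) <- 1
  cR <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(cR)) return(1e10)
  one <- rep(1, n)
  Ri1 <- backsolve(cR, forwardsolve(t(cR), one))
  Riz <- backsolve(cR, forwardsolve(t(cR), z))
  mu <- sum(Ri1 * z) / sum(Ri1 * one)
  q <- sum((z - mu) * (Riz - mu * Ri1))
  if (q <= 0) return(1e10)
  s2 <- q / n
  0.5 * (n * log(s2) + 2 * sum(log(diag(cR))) + n * (1 + log(2 * pi)))
}

fit_variogram_ml <- function(site_xy, values, v = 0.5, n_starts = 5,
                             seed = 1) {
  site_xy <- as.matrix(site_xy)
  if (is.null(site_xy) || is.null(values))
    stop("ML fitting needs `site_xy` and `values`", call. = FALSE)
  n <- length(values)
  if (n < 20L) stop("ML fitting needs n >= 20 sites", call. = FALSE)
  dmat <- as.matrix(dist(site_xy))
  est_v <- is.na(v)
  dmax <- max(dmat)
  obj <- function(p) {
    psi <- 1 / (1 + exp(-p[1]))   # logit-parameterised nugget fraction
    matern_nll(psi, p[2], if (est_v) p[3] else log(v), dmat, values)
  }
  starts <- with_seed(seed, {
    s <- list(c(qlogis_safe(0.1), log(dmax / 6), log(0.5)))
    for (i in seq_len(max(0L, n_starts - 1L))) {
      s[[i + 1L]] <- c(qlogis_safe(runif(1, 0.02, 0.6)),
                       log(dmax * runif(1, 0.02, 0.5)),
                       log(runif(1, 0.1, 2)))
    }
    s
  })
  np <- if (est_v) 3L else 2L
  lower <- c(qlogis_safe(1e-6), log(dmax / 1e4), log(0.05))
  upper <- c(qlogis_safe(1 - 1e-6), log(dmax * 10), log(5))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      optim(p0[seq_len(np)], obj, method = "L-BFGS-B",
            lower = lower[seq_len(np)], upper = upper[seq_len(np)],
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("ML variogram fit failed to converge from any start", call. = FALSE)
  p <- best$par
  psi <- 1 / (1 + exp(-p[1]))
  a <- exp(p[2]); vv <- if (est_v) exp(p[3]) else v
  # recover the profiled total variance at the optimum
  R <- (1 - psi) * matern_correlation(dmat, a, vv)
  diag(R) <- 1
  cR <- chol(R)
  one <- rep(1, length(values))
  Ri1 <- backsolve(cR, forwardsolve(t(cR), one))
  mu <- sum(Ri1 * values) / sum(Ri1 * one)
  Riz <- backsolve(cR, forwardsolve(t(cR), values))
  s2 <- sum((values - mu) * (Riz - mu * Ri1)) / length(values)
  at_b <- any(abs(p - lower[seq_len(np)]) < 1e-6) ||
    any(abs(p - upper[seq_len(np)]) < 1e-6)
  variogram_model(psi * s2, (1 - psi) * s2, a, v = vv, method = "ml",
                  objective = best$value, at_bounds = at_b)
}

qlogis_safe <- function(p) log(p / (1 - p))

#' Effective range of a variogram model
#'
#' Smallest distance at which the structured semivariance reaches 95% of the
#' partial sill, i.e. the root of \eqn{\gamma(h) - c_0 = 0.95\,c_1}.  For the
#' exponential model (\eqn{v = 0.5}) this is \eqn{\approx 2.9957\,a}.
#'
#' @param model a [variogram_model()] with `c1 > 0`.
#' @return effective range in metres.
#' @export
effective_range <- function(model) {
  stopifnot(inherits(model, "variogram_model"))
  if (model$c1 <= 0)
    stop("effective range undefined when the partial sill c1 is 0",
         call. = FALSE)
  f <- function(h) (1 - matern_correlation(h, model$a, model$v)) - 0.95
  hi <- model$a
  while (f(hi) < 0 && hi < model$a * 1e6) hi <- hi * 2
  uniroot(f, lower = model$a * 1e-6, upper = hi, tol = model$a * 1e-9)$root
}
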