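#' Assemble and prune predictor blocks
#'
#' Builds the three explanatory blocks used in the variance partitioning:
#' soil (numeric, standardized to mean 0 / sd 1), land management
#' (dummy-coded with a configurable reference level) and space (PCNM
#' scores).  Collinear soil columns are pruned in two passes: (1) for any
#' pair with |r| above the threshold, the member with the larger mean
#' absolute correlation to the remaining variables is dropped (this removes
#' e.g. total nitrogen when it tracks organic carbon at r = 0.92);
#' (2) exactly linearly dependent columns (e.g. silt in the compositional
#' clay + silt + sand = 100 triple) are detected by rank deficiency and
#' dropped by the same mean-|r| rule among the dependent set.
#'
#' @param site_table site table with soil columns and `management`.
#' @param pcnm a `spatial_eigenbasis` from [build_pcnm()] (or a numeric
#'   matrix of spatial scores), or NULL for no spatial block.
#' @param soil_vars soil columns to use (default: all numeric except
#'   coordinates).
#' @param cor_threshold pairwise |r| above which one of a pair is dropped
#'   (default 0.9).
#' @param reference_level reference land-management level for dummy coding
#'   (default "Forest", i.e. the low end of the cropping-intensity
#'   gradient).
#' @return object of class `predictor_blocks`: list with `soil`,
#'   `management`, `space` matrices and a `pruned` log.
#' @export
prepare_blocks <- function(site_table, pcnm = NULL, soil_vars = NULL,
                           cor_threshold = 0.9,
                           reference_level = "Forest") {
  if (is.null(soil_vars)) {
    soil_vars <- setdiff(
      names(site_table)[vapply(site_table, is.numeric, logical(1))],
      c("x", "y"))
  }
  X <- as.matrix(site_table[, soil_vars, drop = FALSE])
  if (any(!complete.cases(X)))
    stop("incomplete cases in soil variables; complete-case first",
         call. = FALSE)
  const <- apply(X, 2, var) == 0
  pruned <- character(0)
  if (any(const)) {
    pruned <- c(pruned, sprintf("%s (constant)", colnames(X)[const]))
    X <- X[, !const, drop = FALSE]
  }
  # pass 1: pairwise correlation pruning
  repeat {
    R <- abs(cor(X))
    diag(R) <- 0
    if (ncol(X) < 2L || max(R) <= cor_threshold) break
    pair <- arrayInd(which.max(R), dim(R))
    mean_r <- rowMeans(abs(cor(X)) - diag(ncol(X)))
    drop_j <- pair[1, which.max(mean_r[pair[1, ]])]
    pruned <- c(pruned, sprintf("%s (|r| = %.3f with %s)",
                                colnames(X)[drop_j], max(R),
                                colnames(X)[setdiff(pair[1, ], drop_j)]))
    X <- X[, -drop_j, drop = FALSE]
  }
  # pass 2: exact linear dependence (compositional closure etc.)
  repeat {
    Xs <- scale(X)
    qrX <- qr(Xs)
    if (qrX$rank == ncol(Xs)) break
    dep <- qrX$pivot[seq(qrX$rank + 1L, ncol(Xs))]
    # among columns involved in the dependency, drop the one with the
    # largest mean absolute correlation to the others
    mean_r <- colMeans(abs(cor(X)))
    drop_j <- dep[which.max(mean_r[dep])]
    pruned <- c(pruned, sprintf("%s (linearly dependent)",
                                colnames(X)[drop_j]))
    X <- X[, -drop_j, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("soil block empty after pruning", call. = FALSE)
  soil <- scale(X)
  mgmt <- NULL
  if ("management" %in% names(site_table)) {
    f <- droplevels(factor(site_table$management))
    if (!reference_level %in% levels(f))
      reference_level <- levels(f)[1]
    f <- stats::relevel(f, ref = reference_level)
    mm <- model.matrix(~f)[, -1, drop = FALSE]
    colnames(mm) <- sub("^f", "management", colnames(mm))
    mgmt <- mm
  }
  space <- NULL
  if (!is.null(pcnm)) {
    space <- if (inherits(pcnm, "spatial_eigenbasis")) pcnm$vectors
    else as.matrix(pcnm)
  }
  structure(list(soil = soil, management = mgmt, space = space,
                 pruned = pruned, reference_level = reference_level),
            class = "predictor_blocks")
}

#' @export
print.predictor_blocks <- function(x, ...) {
  cat(sprintf("Predictor blocks: soil %d, management %s, space %s\n",
              ncol(x$soil),
              if (is.null(x$management)) "-" else ncol(x$management),
              if (is.null(x$space)) "-" else ncol(x$space)))
  if (length(x$pruned)) cat("  pruned:", paste(x$pruned, collapse = "; "),
                            "\n")
  invisible(x)
}

# ---- regression internals shared by selection and partitioning ----------

# R^2 of (possibly multivariate) response Y on predictor matrix X (with
# intercept).  Y is centred; R^2 = tr(fitted'fitted) / tr(Yc'Yc).
r2_of <- function(Y, X) {
  Y <- as.matrix(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (is.null(X) || ncol(as.matrix(X)) == 0L) return(0)
  qx <- qr(cbind(1, X))
  fit <- qr.fitted(qx, Y)
  fitc <- scale(fit, center = TRUE, scale = FALSE)
  sum(fitc^2) / sum(Yc^2)
}

rank_of <- function(X) {
  if (is.null(X) || ncol(as.matrix(X)) == 0L) return(0L)
  qr(scale(as.matrix(X), scale = FALSE))$rank
}

adj_r2_of <- function(Y, X) {
  n <- nrow(as.matrix(Y))
  adjust_r2(r2_of(Y, X), n, rank_of(X))
}

#' Forward selection with adjusted-R2, AIC and permutation criteria
#'
#' At each step the candidate giving the largest adjusted-R2 gain is
#' examined: it enters only if (a) its permutation p-value is at or below
#' `alpha` and (b) the regression AIC, \eqn{n \log(RSS/n) + 2k}, decreases.
#' The permutation null is selection-aware: within every permutation the
#' statistic is the best adjusted-R2 gain over all remaining candidates
#' (family-wise null), so on pure noise the per-step rejection rate is
#' calibrated at `alpha`.  Permutations are residualized on the current
#' model (Freedman-Lane).  Passing residuals of a previous model as the
#' response implements residual-based selection of spatial descriptors.
#'
#' @param response numeric response vector (typically a log-transformed
#'   relative abundance) or multivariate response matrix.
#' @param block candidate predictor matrix.
#' @param alpha permutation significance threshold (default 0.001).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return object of class `selection_result`: data frame of selected
#'   variables with adjusted R2, AIC and p after inclusion; `stopping`
#'   attribute records why selection ended.
#' @export
forward_select <- function(response, block, alpha = 0.001, n_perm = 999,
                           seed = 1) {
  y <- as.numeric(response)
  block <- as.matrix(block)
  if (ncol(block) == 0L) stop("empty candidate block", call. = FALSE)
  n <- length(y)
  stopifnot(nrow(block) == n)
  if (is.null(colnames(block)))
    colnames(block) <- paste0("V", seq_len(ncol(block)))
  selected <- integer(0)
  rows <- list()
  stopping <- "no candidate passed the criteria"
  aic_of <- function(X) {
    k <- rank_of(X) + 1L # + intercept
    XX <- cbind(rep(1, n), X)
    rss <- sum((y - qr.fitted(qr(XX), y))^2)
    n * log(rss / n) + 2 * k
  }
  perm_seed <- derive_seed(seed, "forward_select")
  step <- 0L
  repeat {
    step <- step + 1L
    cand <- setdiff(seq_len(ncol(block)), selected)
    if (!length(cand)) { stopping <- "all candidates selected"; break }
    Xcur <- if (length(selected)) block[, selected, drop = FALSE] else NULL
    kr <- rank_of(Xcur)
    # orthonormal basis of the current model (incl. intercept), and unit
    # residual directions of the candidates against it; all statistics below
    # reduce to projections on these, which lets the permutation loop run as
    # one matrix product per step.
    Q0 <- qr.Q(qr(cbind(rep(1, n), Xcur)))[, seq_len(kr + 1L), drop = FALSE]
    U <- block[, cand, drop = FALSE] - Q0 %*% crossprod(Q0, block[, cand,
                                                                  drop = FALSE])
    unorm <- sqrt(colSums(U^2))
    live <- unorm > 1e-8 * sqrt(n)
    U[, live] <- sweep(U[, live, drop = FALSE], 2, unorm[live], "/")
    U[, !live] <- 0
    my <- mean(y)
    stats_of <- function(Ym) {
      # Ym: n x B matrix of responses (columns); returns best adjusted gain
      ss_tot <- colSums((Ym - my)^2)
      ss_cur <- colSums(crossprod(Q0, Ym)^2) - n * my^2
      r2_cur <- ss_cur / ss_tot
      gain <- crossprod(U, Ym)^2 # cand x B
      r2_best <- r2_cur + apply(gain, 2, max) / ss_tot
      vapply(seq_along(ss_tot), function(b) {
        adjust_r2(r2_best[b], n, kr + 1L) - adjust_r2(r2_cur[b], n, kr)
      }, numeric(1))
    }
    obs_gain_all <- crossprod(U, y)^2
    ss_tot_obs <- sum((y - my)^2)
    r2_cur_obs <- (sum(crossprod(Q0, y)^2) - n * my^2) / ss_tot_obs
    adj_gains <- vapply(seq_along(cand), function(jj) {
      adjust_r2(r2_cur_obs + obs_gain_all[jj] / ss_tot_obs, n, kr + 1L) -
        adjust_r2(r2_cur_obs, n, kr)
    }, numeric(1))
    best_i <- which.max(adj_gains)
    best <- cand[best_i]
    best_gain <- adj_gains[best_i]
    if (!is.finite(best_gain) || best_gain <= 0) break
    # Freedman-Lane: permute residuals of the current model, add back fit
    fit0 <- as.numeric(Q0 %*% crossprod(Q0, y))
    res0 <- y - fit0
    null <- with_seed(derive_seed(perm_seed, paste0("step", step)), {
      perms <- matrix(0L, n, n_perm)
      for (b in seq_len(n_perm)) perms[, b] <- sample.int(n)
      stats_of(fit0 + matrix(res0[perms], n, n_perm))
    })
    p <- perm_pvalue(best_gain, null)
    aic_old <- aic_of(Xcur)
    aic_new <- aic_of(cbind(Xcur, block[, best]))
    if (p > alpha) { stopping <- sprintf(
      "best candidate '%s' not significant (p = %.4g)", colnames(block)[best],
      p); break }
    if (aic_new >= aic_old) { stopping <- sprintf(
      "best candidate '%s' did not reduce AIC", colnames(block)[best]); break }
    selected <- c(selected, best)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = colnames(block)[best],
      adj_r2 = adjust_r2(r2_cur_obs + obs_gain_all[best_i] / ss_tot_obs, n,
                         kr + 1L),
      aic = aic_new, p = p, stringsAsFactors = FALSE)
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), adj_r2 = numeric(0),
               aic = numeric(0), p = numeric(0))
  structure(res, class = c("selection_result", "data.frame"),
            stopping = stopping, alpha = alpha, n_perm = n_perm,
            selected = colnames(block)[selected])
}

# folded three-block fraction table (see package vignette): soil-only and
# management-only from the soil+management pair, space-only as the increment
# of the full model over soil+management, one shared soil-with-management
# fraction, residual as the complement of the full model.
fold_fractions <- function(Y, S, M, P) {
  aS <- if (is.null(S)) 0 else adj_r2_of(Y, S)
  aM <- if (is.null(M)) 0 else adj_r2_of(Y, M)
  aSM <- adj_r2_of(Y, cbind(S, M))
  aSMP <- adj_r2_of(Y, cbind(S, M, P))
  c(soil = aSM - aM, management = aSM - aS, shared = aS + aM - aSM,
    space = aSMP - aSM, residual = 1 - aSMP)
}

# permutation test of the marginal effect of block X given covariates Z on
# response Y (reduced-model residual permutation); F-like statistic on R^2.
perm_block_test <- function(Y, X, Z, n_perm, seed) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (is.null(X) || ncol(as.matrix(X)) == 0L) return(NA_real_)
  kz <- rank_of(Z)
  Qz <- qr.Q(qr(cbind(rep(1, n), Z)))[, seq_len(kz + 1L), drop = FALSE]
  kf <- rank_of(cbind(Z, X))
  Qf <- qr.Q(qr(cbind(rep(1, n), Z, X)))[, seq_len(kf + 1L), drop = FALSE]
  mY <- colMeans(Y)
  stat <- function(Yy) {
    # Yy centred column means equal mY under Freedman-Lane permutation
    ss_tot <- sum(sweep(Yy, 2, mY)^2)
    ss_red <- sum(crossprod(Qz, Yy)^2) - n * sum(mY^2)
    ss_full <- sum(crossprod(Qf, Yy)^2) - n * sum(mY^2)
    (ss_full - ss_red) / (ss_tot - ss_full + 1e-12)
  }
  obs <- stat(Y)
  fit0 <- Qz %*% crossprod(Qz, Y)
  res0 <- Y - fit0
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    stat(fit0 + res0[sample.int(n), , drop = FALSE])
  }, numeric(1)))
  perm_pvalue(obs, null)
}

#' Partition the variance of a taxon abundance among predictor blocks
#'
#' Partial-regression decomposition of the adjusted R2 of a (log-transformed)
#' taxon abundance into soil-only, management-only, space-only and shared
#' soil-with-management fractions plus residual.  Blocks are used as given
#' (apply [forward_select()] per block beforehand); marginal fractions are
#' tested by residualized permutation.  Adjusted fractions may be slightly
#' negative and are reported unclipped.
#'
#' @param response numeric vector (log relative abundance).
#' @param blocks a [prepare_blocks()] result, possibly with selected-column
#'   subsets.
#' @param n_perm permutations for the marginal tests (default 999; 0 skips
#'   testing).
#' @param seed integer seed.
#' @return object of class `partition_result`.
#' @export
partition_abundance <- function(response, blocks, n_perm = 999, seed = 1) {
  stopifnot(inherits(blocks, "predictor_blocks"))
  Y <- as.numeric(response)
  S <- blocks$soil; M <- blocks$management; P <- blocks$space
  empty <- is.null(S) && is.null(M) && is.null(P)
  fr <- if (empty) c(soil = 0, management = 0, shared = 0, space = 0,
                     residual = 1)
  else fold_fractions(Y, S, M, P)
  pv <- c(soil = NA_real_, management = NA_real_, space = NA_real_)
  if (!empty && n_perm > 0) {
    pv["soil"] <- perm_block_test(Y, S, cbind(M, P), n_perm,
                                  derive_seed(seed, "soil"))
    pv["management"] <- perm_block_test(Y, M, cbind(S, P), n_perm,
                                        derive_seed(seed, "management"))
    pv["space"] <- perm_block_test(Y, P, cbind(S, M), n_perm,
                                   derive_seed(seed, "space"))
  }
  unadj <- c(full = r2_of(Y, cbind(S, M, P)))
  structure(list(fractions = fr, p_values = pv, unadjusted_full = unadj,
                 empty = empty, kind = "abundance"),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Variance partition (%s):\n", x$kind))
  f <- x$fractions
  for (nm in names(f)) {
    p <- if (nm %in% names(x$p_values) && is.finite(x$p_values[nm]))
      sprintf("  (p = %.4g)", x$p_values[nm]) else ""
    cat(sprintf("  %-11s %6.3f%s\n", nm, f[nm], p))
  }
  invisible(x)
}

# PCoA with Lingoes correction when negative eigenvalues are material.
pcoa_coords <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
  e <- eigen(G, symmetric = TRUE)
  tol <- 1e-8 * max(abs(e$values))
  if (min(e$values) < -tol) {
    # Lingoes: add constant c = -min eigenvalue to squared distances
    cst <- -min(e$values)
    D2 <- D^2 + 2 * cst
    diag(D2) <- 0
    A <- -0.5 * D2
    G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A)
    e <- eigen(G, symmetric = TRUE)
    if (min(e$values) < -10 * tol - 1e-6 * max(abs(e$values)))
      stop("distance matrix not embeddable even after Lingoes correction",
           call. = FALSE)
  }
  keep <- e$values > tol
  sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(e$values[keep]), "*")
}

#' Partition community dissimilarity among predictor blocks (db-RDA)
#'
#' Distance-based redundancy analysis: the dissimilarity matrix is embedded
#' by principal-coordinates analysis (with additive Lingoes correction when
#' negative eigenvalues appear, as can happen for weighted UniFrac), and the
#' coordinate matrix is analysed by redundancy analysis on each block
#' combination.  Fractions are adjusted R2 (folded as in
#' [partition_abundance()]); marginal block effects are tested by
#' permutation of reduced-model residuals.
#'
#' @param d square symmetric dissimilarity matrix with zero diagonal.
#' @param blocks a [prepare_blocks()] result.
#' @param n_perm permutations (default 999; 0 skips testing).
#' @param seed integer seed.
#' @return object of class `partition_result` (kind "community"); the PCoA
#'   coordinate matrix is attached as attribute `coordinates`.
#' @export
partition_community <- function(d, blocks, n_perm = 999, seed = 1) {
  stopifnot(inherits(blocks, "predictor_blocks"))
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-10)
    stop("dissimilarity matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12))
    stop("dissimilarity matrix diagonal must be zero", call. = FALSE)
  Y <- pcoa_coords(d)
  S <- blocks$soil; M <- blocks$management; P <- blocks$space
  fr <- fold_fractions(Y, S, M, P)
  pv <- c(soil = NA_real_, management = NA_real_, space = NA_real_)
  if (n_perm > 0) {
    pv["soil"] <- perm_block_test(Y, S, cbind(M, P), n_perm,
                                  derive_seed(seed, "soil"))
    pv["management"] <- perm_block_test(Y, M, cbind(S, P), n_perm,
                                        derive_seed(seed, "management"))
    pv["space"] <- perm_block_test(Y, P, cbind(S, M), n_perm,
                                   derive_seed(seed, "space"))
  }
  structure(list(fractions = fr, p_values = pv,
                 unadjusted_full = c(full = r2_of(Y, cbind(S, M, P))),
                 empty = FALSE, kind = "community"),
            class = "partition_result", coordinates = Y)
}

#' Standardized partial regression coefficients
#'
#' Fits the response on standardized predictors and reports each
#' coefficient on the standardized scale (so in simple regression the
#' coefficient equals Pearson's r), together with the marginal adjusted-R2
#' contribution of each variable computed by leave-one-covariate-out
#' difference against the full model.
#'
#' @param response numeric response vector.
#' @param X predictor matrix (standardized internally).
#' @return data frame with `variable`, `coefficient`, `marginal_adj_r2`;
#'   rank-deficient fits flag aliased coefficients with NA.
#' @export
standardized_coefficients <- function(response, X) {
  X <- as.matrix(X)
  y <- as.numeric(response)
  ys <- (y - mean(y)) / sd(y)
  Xs <- scale(X)
  fit <- lm(ys ~ Xs)
  cf <- stats::coef(fit)[-1]
  full <- adj_r2_of(ys, Xs)
  marg <- vapply(seq_len(ncol(Xs)), function(j) {
    full - adj_r2_of(ys, Xs[, -j, drop = FALSE])
  }, numeric(1))
  data.frame(variable = colnames(X), coefficient = unname(cf),
             marginal_adj_r2 = marg, stringsAsFactors = FALSE)
}
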