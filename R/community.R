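#' Extract the numeric matrix of a community table
#'
#' @param table a `community_table` (columns `taxon`, `lineage`, then sites).
#' @param proportions if TRUE, columns rescaled to sum to 1.
#' @return numeric matrix, taxa in rows (rownames = taxon), sites in columns.
#' @export
community_matrix <- function(table, proportions = FALSE) {
  stopifnot(all(c("taxon", "lineage") %in% names(table)))
  m <- as.matrix(table[, setdiff(names(table), c("taxon", "lineage")),
                       drop = FALSE])
  rownames(m) <- table$taxon
  if (proportions) m <- sweep(m, 2, colSums(m), "/")
  m
}

#' Rarefy a count table to a common sequencing depth
#'
#' Each site is subsampled without replacement to exactly `depth` reads;
#' sites whose total falls below the depth are dropped with a warning.
#'
#' @param table a `community_table` of counts.
#' @param depth target depth (default 10800).
#' @param seed integer seed; draws are deterministic given the seed.
#' @return rarefied `community_table`.
#' @export
rarefy_counts <- function(table, depth = 10800, seed = 1) {
  if (!is.numeric(depth) || depth <= 0)
    stop("`depth` must be a positive count", call. = FALSE)
  m <- community_matrix(table)
  if (any(m < 0) || any(m != round(m)))
    stop("rarefaction needs nonnegative integer counts", call. = FALSE)
  totals <- colSums(m)
  drop <- totals < depth
  if (any(drop)) {
    warning(sprintf("dropping %d site(s) below depth %d: %s", sum(drop),
                    depth, paste(colnames(m)[drop], collapse = ", ")),
            call. = FALSE)
    m <- m[, !drop, drop = FALSE]
  }
  out <- with_seed(seed, {
    apply(m, 2, function(col) {
      if (sum(col) == depth) return(as.integer(col))
      picked <- sample.int(sum(col), depth)
      tabulate(findInterval(picked - 1, cumsum(col)) + 1L,
               nbins = length(col))
    })
  })
  res <- table[, c("taxon", "lineage")]
  res <- cbind(res, as.data.frame(out))
  names(res)[-(1:2)] <- colnames(m)
  structure(res, class = c("community_table", "data.frame"))
}

#' Aggregate a community table at a taxonomic rank
#'
#' Lineage strings are split on ";"; counts are summed within the groups at
#' the requested rank.  Taxa whose lineage is too shallow for the rank are
#' pooled as "unclassified".  The special rank
#' `"phylum_with_proteobacteria_classes"` reports phyla but splits
#' Proteobacteria into its classes, the usual convention for soil surveys.
#'
#' @param table a `community_table`.
#' @param rank one of "domain", "phylum", "class", "order", "family",
#'   "genus", a numeric rank index, or
#'   "phylum_with_proteobacteria_classes".
#' @return aggregated `community_table` (lineage = the group label).
#' @export
aggregate_taxonomy <- function(table, rank = "phylum") {
  if (nrow(table) == 0L) stop("empty community table", call. = FALSE)
  ranks <- c(domain = 1, phylum = 2, class = 3, order = 4, family = 5,
             genus = 6)
  parts <- strsplit(table$lineage, ";", fixed = TRUE)
  pick <- function(p, i) if (length(p) >= i && nzchar(trimws(p[i])))
    trimws(p[i]) else "unclassified"
  if (identical(rank, "phylum_with_proteobacteria_classes")) {
    group <- vapply(parts, function(p) {
      ph <- pick(p, 2)
      if (identical(ph, "Proteobacteria")) pick(p, 3) else ph
    }, character(1))
  } else {
    i <- if (is.numeric(rank)) as.integer(rank) else ranks[[match.arg(
      rank, names(ranks))]]
    group <- vapply(parts, pick, character(1), i = i)
  }
  m <- community_matrix(table)
  agg <- rowsum(m, group)
  res <- data.frame(taxon = rownames(agg), lineage = rownames(agg),
                    agg, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(res) <- NULL
  names(res)[-(1:2)] <- colnames(m)
  structure(res, class = c("community_table", "data.frame"))
}

#' Weighted UniFrac distances between sites
#'
#' Normalized weighted UniFrac: for samples A and B,
#' \deqn{d(A,B) = \frac{\sum_e b_e\,|p_A(e) - p_B(e)|}
#'                     {\sum_e b_e\,(p_A(e) + p_B(e))}}
#' summing over tree branches, with \eqn{b_e} the branch length and
#' \eqn{p_S(e)} the proportion of sample S descending from the branch.
#' Result lies in \[0, 1\].  Set `normalized = FALSE` for the raw branch sum.
#'
#' @param table a `community_table` (counts or proportions; proportions are
#'   taken per site).
#' @param tree an [ape] `phylo` tree whose tips cover all table taxa, with
#'   branch lengths.
#' @param normalized divide by the abundance-weighted total branch length
#'   (default TRUE).
#' @return a `dist_matrix`: square symmetric matrix with site ids.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; weighted UniFrac needs them",
         call. = FALSE)
  P <- community_matrix(table, proportions = TRUE)
  missing <- setdiff(rownames(P), tree$tip.label)
  if (length(missing))
    stop(sprintf("table taxa missing from tree: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  # node_prop[v, s]: proportion of sample s under node v
  node_prop <- matrix(0, nnode, ncol(P))
  tipP <- matrix(0, ntip, ncol(P))
  idx <- match(tree$tip.label, rownames(P))
  tipP[!is.na(idx), ] <- P[idx[!is.na(idx)], , drop = FALSE]
  node_prop[seq_len(ntip), ] <- tipP
  for (k in seq_len(nrow(tr$edge))) {
    node_prop[tr$edge[k, 1], ] <- node_prop[tr$edge[k, 1], ] +
      node_prop[tr$edge[k, 2], ]
  }
  B <- node_prop[tr$edge[, 2], , drop = FALSE] # per-branch proportions
  b <- tr$edge.length
  ns <- ncol(P)
  D <- matrix(0, ns, ns, dimnames = list(colnames(P), colnames(P)))
  for (i in seq_len(ns - 1L)) {
    for (j in seq((i + 1L), ns)) {
      num <- sum(b * abs(B[, i] - B[, j]))
      D[i, j] <- D[j, i] <- if (normalized) {
        den <- sum(b * (B[, i] + B[, j]))
        if (den > 0) num / den else 0
      } else num
    }
  }
  structure(D, class = c("dist_matrix", "matrix"))
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS via [vegan::monoMDS()], initialized from classical
#' scaling (principal coordinates) and re-run from random configurations;
#' the configuration with the lowest stress over all restarts is returned.
#'
#' @param d square dissimilarity matrix (or `dist`).
#' @param k number of axes (default 2).
#' @param restarts number of additional random starts (default 20).
#' @param seed integer seed.
#' @param ties monotone-regression tie treatment, "weak" (default, primary
#'   approach) or "strong".
#' @return object of class `ordination_result` with `points` (n x k scores),
#'   `stress`, `method`.
#' @export
nmds <- function(d, k = 2, restarts = 20, seed = 1, ties = c("weak",
                                                             "strong")) {
  ties <- match.arg(ties)
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  if (n < k + 2) stop("need n >= k + 2 sites", call. = FALSE)
  init <- cmdscale(dd, k = k)
  if (ncol(init) < k)
    init <- cbind(init, matrix(0, n, k - ncol(init)))
  runs <- with_seed(seed, {
    fits <- list(vegan::monoMDS(dd, y = init, k = k, model = "global",
                                weakties = ties == "weak"))
    for (r in seq_len(restarts)) {
      y0 <- matrix(rnorm(n * k), n, k)
      fits[[r + 1L]] <- vegan::monoMDS(dd, y = y0, k = k, model = "global",
                                       weakties = ties == "weak")
    }
    fits
  })
  stresses <- vapply(runs, `[[`, numeric(1), "stress")
  best <- runs[[which.min(stresses)]]
  pts <- best$points
  rownames(pts) <- labels(dd)
  colnames(pts) <- paste0("NMDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, method = "nmds",
                 k = k, restart_stress = stresses),
            class = "ordination_result")
}

#' Principal component analysis of soil variables
#'
#' PCA on standardized variables; incomplete rows are dropped (logged) and
#' zero-variance variables removed with a warning.
#'
#' @param site_table a site table.
#' @param variables character vector of numeric columns (default: all soil
#'   columns).
#' @return `ordination_result` with `points` (scores), `loadings`,
#'   `explained` (proportion of variance per axis).
#' @export
pca_soil <- function(site_table, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(site_table)[vapply(site_table, is.numeric,
                                                  logical(1))],
                         c("x", "y"))
  }
  if (length(variables) < 2L) stop("need >= 2 variables", call. = FALSE)
  X <- site_table[, variables, drop = FALSE]
  cc <- complete.cases(X)
  if (!all(cc)) message(sprintf("pca_soil: dropping %d incomplete row(s)",
                                sum(!cc)))
  X <- X[cc, , drop = FALSE]
  v0 <- vapply(X, function(col) var(col) == 0, logical(1))
  if (any(v0)) {
    warning(sprintf("dropping zero-variance variable(s): %s",
                    paste(variables[v0], collapse = ", ")), call. = FALSE)
    X <- X[, !v0, drop = FALSE]
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  pts <- p$x
  if (!is.null(site_table$site_id)) rownames(pts) <- site_table$site_id[cc]
  structure(list(points = pts, loadings = p$rotation, explained = expl,
                 stress = NA_real_, method = "pca"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("%s ordination: %d sites x %d axes\n", toupper(x$method),
              nrow(x$points), ncol(x$points)))
  if (identical(x$method, "nmds"))
    cat(sprintf("  stress: %.4f (best of %d starts)\n", x$stress,
                length(x$restart_stress)))
  if (identical(x$method, "pca"))
    cat("  explained variance:",
        paste0(sprintf("%.1f%%", 100 * head(x$explained, 5)),
               collapse = ", "), "\n")
  invisible(x)
}

#' Permutation-based vector fitting onto an ordination
#'
#' Each variable is regressed on the ordination scores; the direction
#' cosines are the regression coefficients scaled to unit norm, \eqn{R^2} is
#' the squared multiple correlation, and the p-value comes from permuting the
#' variable across sites with the add-one rule
#' \eqn{p = (1 + \#\{R^2_{perm} \ge R^2\}) / (1 + n_{perm})}.  A vector is
#' retained when \eqn{R^2} meets the threshold and \eqn{p \le \alpha}
#' (with 999 permutations the smallest attainable p is exactly 0.001, the
#' value conventionally printed as "P < 0.001").
#'
#' @param ordination an `ordination_result`.
#' @param variables data frame of numeric variables, rows aligned to the
#'   ordination sites.
#' @param n_perm number of permutations, >= 99 (default 999).
#' @param seed integer seed.
#' @param r2_threshold retention threshold on R^2 (default 0.20).
#' @param alpha retention threshold on p (default 0.001).
#' @return data frame of class `fitted_vectors`: one row per variable with
#'   axis direction cosines, `r2`, `p`, `retained`.
#' @export
fit_vectors <- function(ordination, variables, n_perm = 999, seed = 1,
                        r2_threshold = 0.20, alpha = 0.001) {
  stopifnot(inherits(ordination, "ordination_result"), n_perm >= 99)
  scores <- ordination$points
  n <- nrow(scores)
  stopifnot(nrow(variables) == n)
  X <- cbind(1, scores)
  Q <- qr.Q(qr(X)) # orthonormal basis, reused for all variables and perms
  perms <- with_seed(seed, {
    P <- matrix(0L, n, n_perm)
    for (b in seq_len(n_perm)) P[, b] <- sample.int(n)
    P
  })
  rows <- lapply(names(variables), function(v) {
    y <- variables[[v]]
    if (!is.numeric(y)) return(NULL)
    if (var(y) == 0) {
      warning(sprintf("skipping constant variable '%s'", v), call. = FALSE)
      return(NULL)
    }
    ssy <- sum((y - mean(y))^2)
    r2_of_mat <- function(Ym) {
      (colSums(crossprod(Q, Ym)^2) - n * mean(y)^2) / ssy
    }
    r2 <- r2_of_mat(matrix(y, ncol = 1))
    coefs <- solve(crossprod(X), crossprod(X, y))[-1, 1]
    dir <- coefs / sqrt(sum(coefs^2))
    null <- r2_of_mat(matrix(y[perms], n, n_perm))
    p <- perm_pvalue(r2, null)
    out <- data.frame(variable = v, t(dir), r2 = r2, p = p,
                      retained = r2 >= r2_threshold && p <= alpha,
                      stringsAsFactors = FALSE)
    names(out)[2:(1 + length(dir))] <- colnames(scores)
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(variable = character(0), r2 = numeric(0),
                      p = numeric(0), retained = logical(0))
  }
  rownames(res) <- NULL
  structure(res, class = c("fitted_vectors", "data.frame"),
            n_perm = n_perm, r2_threshold = r2_threshold, alpha = alpha)
}
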