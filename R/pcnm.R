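#' Principal coordinates of neighbour matrices (PCNM)
#'
#' Builds spatial eigenvectors from site coordinates: the inter-site
#' distance matrix is truncated (distances beyond the threshold replaced by
#' four times the threshold), double-centred as in principal-coordinates
#' analysis, and eigendecomposed.  Eigenvectors whose eigenvalue exceeds
#' `tolerance` times the largest eigenvalue are retained, scaled to unit
#' norm, centred, and sign-fixed so the first nonzero loading is positive.
#' The resulting PCNM1..PCNMk describe spatial patterns from broad to fine
#' scale and serve as explanatory variables for spatial structure.
#'
#' @param site_xy two-column coordinate matrix (>= 3 non-collinear sites).
#' @param truncation threshold in metres, or "auto" (default): the longest
#'   edge of the minimum spanning tree of the sites, the classic PCNM rule.
#' @param tolerance relative positivity cutoff (default 1e-8).
#' @return object of class `spatial_eigenbasis`: list with `vectors` (n x k
#'   matrix, columns PCNM1..), `values` (eigenvalues, descending),
#'   `truncation`, `tolerance`.
#' @export
build_pcnm <- function(site_xy, truncation = "auto", tolerance = 1e-8) {
  xy <- design_xy(site_xy)
  n <- nrow(xy)
  if (n < 3L) stop("need >= 3 sites", call. = FALSE)
  D <- as.matrix(dist(xy))
  if (max(D) == 0) stop("all sites coincident: degenerate geometry",
                        call. = FALSE)
  if (identical(truncation, "auto")) {
    st <- vegan::spantree(dist(xy))
    truncation <- max(st$dist)
  }
  stop_if_not_scalar_pos(truncation, "truncation")
  Dt <- D
  Dt[Dt > truncation] <- 4 * truncation
  A <- -0.5 * Dt^2
  G <- A - outer(rowMeans(A), colMeans(A), "+") + mean(A) # Gower centring
  e <- eigen(G, symmetric = TRUE)
  keep <- e$values > tolerance * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-12)[1]
    if (length(nz) && V[nz, j] < 0) V[, j] <- -V[, j]
  }
  colnames(V) <- paste0("PCNM", seq_len(ncol(V)))
  structure(list(vectors = V, values = e$values[keep],
                 all_values = e$values, truncation = truncation,
                 tolerance = tolerance),
            class = "spatial_eigenbasis")
}

#' @export
print.spatial_eigenbasis <- function(x, ...) {
  cat(sprintf("PCNM basis: %d eigenvectors (truncation %.4g m)\n",
              ncol(x$vectors), x$truncation))
  invisible(x)
}
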