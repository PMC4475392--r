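# Independent oracles and small fixtures, kept free of the package's own
# implementation paths.

# Brute-force method-of-moments variogram: enumerate every pair, bin by
# distance, average squared differences.
bf_variogram <- function(xy, z, breaks) {
  n <- nrow(xy)
  gh <- numeric(length(breaks) - 1L)
  np <- integer(length(breaks) - 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- sqrt(sum((xy[i, ] - xy[j, ])^2))
      if (d <= 0 || d > max(breaks)) next
      b <- findInterval(d, breaks, left.open = TRUE, rightmost.closed = TRUE)
      if (b >= 1 && b <= length(gh)) {
        gh[b] <- gh[b] + (z[i] - z[j])^2
        np[b] <- np[b] + 1L
      }
    }
  }
  list(gamma = ifelse(np > 0, gh / (2 * np), NA_real_), n_pairs = np)
}

# Brute-force weighted UniFrac: explicit recursion to find the tip set under
# every branch, then the weighted branch sum.
bf_unifrac <- function(P, tree) {
  ntip <- length(tree$tip.label)
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  ns <- ncol(P)
  D <- matrix(0, ns, ns, dimnames = list(colnames(P), colnames(P)))
  branch_prop <- function(node, s) {
    tips <- tree$tip.label[tips_under(node)]
    sum(P[rownames(P) %in% tips, s])
  }
  for (a in seq_len(ns - 1L)) {
    for (b in seq(a + 1L, ns)) {
      num <- 0; den <- 0
      for (e in seq_len(nrow(tree$edge))) {
        pa <- branch_prop(tree$edge[e, 2], a)
        pb <- branch_prop(tree$edge[e, 2], b)
        num <- num + tree$edge.length[e] * abs(pa - pb)
        den <- den + tree$edge.length[e] * (pa + pb)
      }
      D[a, b] <- D[b, a] <- if (den > 0) num / den else 0
    }
  }
  D
}

# Small community table fixture built in code.
make_community_table <- function(counts, taxa = NULL, lineages = NULL) {
  counts <- as.matrix(counts)
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(counts)))
  if (is.null(lineages)) lineages <- paste0("Bacteria;P", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  structure(
    data.frame(taxon = taxa, lineage = lineages, counts,
               stringsAsFactors = FALSE, check.names = FALSE),
    class = c("community_table", "data.frame"))
}

# Uniformly scattered sites on a square, reproducible.
random_sites <- function(n, side = 2000, seed = 1) {
  set.seed(seed)
  cbind(x = runif(n, 0, side), y = runif(n, 0, side))
}

# Reference Matern parameters used across geostatistics tests.
ref_model <- function() variogram_model(0.1, 0.9, 200, v = 0.5)
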