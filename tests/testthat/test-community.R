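test_that("rarefaction subsamples to exact depth, deterministically", {
  set.seed(2)
  counts <- matrix(rpois(5 * 4, 40), 5, 4)
  counts[, 1] <- c(10, 5, 3, 2, 0) # total 20
  tab <- make_community_table(counts)
  r <- rarefy_counts(tab, depth = 20, seed = 1)
  m <- community_matrix(r)
  expect_true(all(colSums(m) == 20))
  # a site already at depth is returned unchanged
  expect_equal(m[, 1], counts[, 1], ignore_attr = TRUE)
  expect_identical(r, rarefy_counts(tab, depth = 20, seed = 1))
  # sites under depth are dropped with a warning
  expect_warning(r2 <- rarefy_counts(tab, depth = 50, seed = 1), "s1")
  expect_false("s1" %in% names(r2))
  expect_error(rarefy_counts(tab, depth = 0), "positive")
})

test_that("rarefied counts have the hypergeometric mean", {
  tab <- make_community_table(matrix(c(30, 10, 60), 3, 1))
  draws <- sapply(1:1000, function(s)
    community_matrix(rarefy_counts(tab, depth = 20, seed = s))[, 1])
  expect_equal(unname(rowMeans(draws)), 20 * c(0.3, 0.1, 0.6),
               tolerance = 0.05)
})

test_that("taxonomy aggregation conserves totals and groups correctly", {
  tab <- make_community_table(
    matrix(c(5, 7, 11, 2,  3, 1, 9, 4), 4, 2),
    taxa = c("o1", "o2", "o3", "o4"),
    lineages = c("Bacteria;Acidobacteria;A1",
                 "Bacteria;Acidobacteria;A2",
                 "Bacteria;Proteobacteria;Alphaproteobacteria",
                 "junk"))
  agg <- aggregate_taxonomy(tab, "phylum")
  m <- community_matrix(agg)
  expect_equal(sum(m), sum(community_matrix(tab)))
  expect_equal(m["Acidobacteria", ], c(s1 = 12, s2 = 4))
  expect_true("unclassified" %in% rownames(m))
  # Proteobacteria split at class level under the special rank
  agg2 <- aggregate_taxonomy(tab, "phylum_with_proteobacteria_classes")
  expect_true("Alphaproteobacteria" %in% agg2$taxon)
  expect_false("Proteobacteria" %in% agg2$taxon)
  expect_error(aggregate_taxonomy(tab[0, ], "phylum"), "empty")
})

test_that("aggregation closes the loop with generator proportions", {
  d <- generate_sampling_design(215, 100, 0, seed = 1)
  st <- attach_soil_and_management(
    d, cluster_layout = list(labels = "L", counts = 100), seed = 1)
  spec <- community_spec(list(
    community_taxon("a1", "Bacteria;PhA;c1", baseline = log(0.6)),
    community_taxon("a2", "Bacteria;PhA;c2", baseline = log(0.2)),
    community_taxon("b1", "Bacteria;PhB;c1", baseline = log(0.2))),
    library_size = 10000)
  comm <- simulate_community(st, spec, seed = 2)
  agg <- aggregate_taxonomy(comm, "phylum")
  p <- rowMeans(community_matrix(agg, proportions = TRUE))
  expect_equal(unname(p["PhA"]), 0.8, tolerance = 0.02)
  expect_equal(unname(p["PhB"]), 0.2, tolerance = 0.02)
})

test_that("weighted UniFrac matches hand and brute-force evaluation", {
  # two-leaf star tree, disjoint samples: distance exactly 1
  star <- ape::read.tree(text = "(A:1,B:1);")
  tab <- make_community_table(matrix(c(10, 0, 0, 10), 2, 2),
                              taxa = c("A", "B"))
  D <- weighted_unifrac(tab, star)
  expect_equal(D[1, 2], 1)
  expect_equal(diag(D), c(s1 = 0, s2 = 0))
  # identical abundance vectors: distance 0
  tab2 <- make_community_table(matrix(c(3, 7, 6, 14), 2, 2),
                               taxa = c("A", "B"))
  expect_equal(weighted_unifrac(tab2, star)[1, 2], 0)
  # random 8-leaf trees against the brute-force branch enumeration oracle
  for (r in 1:5) {
    tr <- simulate_taxa_tree(paste0("x", 1:8), seed = 200 + r)
    set.seed(300 + r)
    counts <- matrix(rpois(8 * 4, 30), 8, 4)
    tab3 <- make_community_table(counts, taxa = paste0("x", 1:8))
    D3 <- weighted_unifrac(tab3, tr)
    P <- community_matrix(tab3, proportions = TRUE)
    expect_equal(unclass(D3), bf_unifrac(P, tr), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(D3 >= 0 & D3 <= 1))
    expect_equal(unclass(D3), t(unclass(D3)), ignore_attr = TRUE)
  }
})

test_that("UniFrac validates its inputs", {
  star <- ape::read.tree(text = "(A:1,B:1);")
  tab <- make_community_table(matrix(1:4, 2, 2), taxa = c("A", "Zmissing"))
  expect_error(weighted_unifrac(tab, star), "Zmissing")
  nolen <- ape::read.tree(text = "(A,B);")
  expect_error(weighted_unifrac(tab, nolen), "branch lengths")
})

test_that("NMDS embeds an exact configuration with near-zero stress", {
  set.seed(5)
  pts <- matrix(rnorm(30 * 2), 30, 2)
  D <- as.matrix(dist(pts))
  dimnames(D) <- list(paste0("s", 1:30), paste0("s", 1:30))
  ord <- nmds(D, k = 2, restarts = 10, seed = 1)
  expect_lt(ord$stress, 0.01)
  expect_gte(ord$stress, 0)
  expect_lte(ord$stress, 1)
  expect_equal(rownames(ord$points), paste0("s", 1:30))
})

test_that("NMDS is stable across restarts and monotone in k", {
  set.seed(6)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  D <- as.matrix(dist(Y))
  s1 <- nmds(D, k = 2, restarts = 10, seed = 1)$stress
  s2 <- nmds(D, k = 2, restarts = 10, seed = 999)$stress
  expect_lt(abs(s1 - s2), 1e-3)
  s3 <- nmds(D, k = 3, restarts = 10, seed = 1)$stress
  expect_lte(s3, s1 + 1e-8)
})

test_that("soil PCA has orthogonal scores and ordered eigenvalues", {
  d <- generate_sampling_design(215, 60, 0, seed = 2)
  st <- attach_soil_and_management(
    d, cluster_layout = list(labels = "L", counts = 60), seed = 3)
  ord <- pca_soil(st)
  cv <- crossprod(scale(ord$points, scale = FALSE))
  off <- abs(cv[upper.tri(cv)]) / max(diag(cv))
  expect_true(all(off < 1e-8))
  expect_true(all(diff(ord$explained) <= 1e-12))
  # two standardized variables at correlation r: PC1 explains (1 + r)/2
  set.seed(7)
  a <- rnorm(200); b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(200)
  df <- data.frame(site_id = 1:200, v1 = a, v2 = b)
  o2 <- pca_soil(df, c("v1", "v2"))
  expect_equal(o2$explained[1], (1 + abs(cor(a, b))) / 2, tolerance = 1e-10)
  # zero-variance variables dropped with a warning
  df$flat <- 1
  expect_warning(pca_soil(df, c("v1", "v2", "flat")), "flat")
})

test_that("vector fitting recovers self-fit and applies thresholds", {
  set.seed(8)
  pts <- matrix(rnorm(60 * 2), 60, 2,
                dimnames = list(NULL, c("NMDS1", "NMDS2")))
  ord <- structure(list(points = pts, method = "nmds"),
                   class = "ordination_result")
  vars <- data.frame(ax1 = pts[, 1])
  vf <- fit_vectors(ord, vars, n_perm = 199, seed = 1)
  expect_equal(vf$r2, 1, tolerance = 1e-10)
  expect_equal(abs(vf$NMDS1), 1, tolerance = 1e-8)
  expect_equal(vf$NMDS2, 0, tolerance = 1e-8)
  expect_equal(vf$p, 1 / 200)
  # unit-norm directions always
  expect_equal(vf$NMDS1^2 + vf$NMDS2^2, 1, tolerance = 1e-10)
  # retention needs both R2 >= 0.20 and p <= alpha
  set.seed(9)
  weak <- pts[, 1] * sqrt(0.12) + rnorm(60) * sqrt(0.88)
  vf2 <- fit_vectors(ord, data.frame(weak = weak), n_perm = 999, seed = 2)
  expect_lt(vf2$r2, 0.20)
  expect_false(vf2$retained)
  strong <- pts[, 1] + rnorm(60, 0, 0.3)
  vf3 <- fit_vectors(ord, data.frame(strong = strong), n_perm = 999,
                     seed = 3)
  expect_true(vf3$retained)
  expect_warning(fit_vectors(ord, data.frame(k = rep(1, 60)), n_perm = 99),
                 "constant")
})

test_that("vector-fit R2 agrees with the vegan envfit oracle", {
  set.seed(10)
  pts <- matrix(rnorm(40 * 2), 40, 2,
                dimnames = list(NULL, c("NMDS1", "NMDS2")))
  ord <- structure(list(points = pts, method = "nmds"),
                   class = "ordination_result")
  v <- pts[, 1] * 0.7 + rnorm(40)
  vf <- fit_vectors(ord, data.frame(v = v), n_perm = 99, seed = 1)
  ef <- vegan::envfit(pts, data.frame(v = v), permutations = 99)
  expect_equal(vf$r2, unname(ef$vectors$r), tolerance = 1e-10)
})
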