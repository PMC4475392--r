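design_278 <- generate_sampling_design(215, 248, 30, seed = 1)

test_that("soil fields achieve their target cross-correlations", {
  st <- attach_soil_and_management(design_278, seed = 42)
  expect_lt(abs(cor(st$organic_carbon, st$total_nitrogen) - 0.92), 0.05)
  expect_lt(abs(cor(st$clay, st$sand) - (-0.3)), 0.05)
  # uncorrelated pairs stay near zero
  expect_lt(abs(cor(st$pH, st$caco3)), 0.15)
  expect_lt(abs(cor(st$pH, st$clay)), 0.15)
  # texture closure is exact
  expect_equal(st$clay + st$silt + st$sand, rep(100, nrow(st)),
               tolerance = 1e-10)
})

test_that("cluster label counts match the request exactly", {
  st <- attach_soil_and_management(design_278, seed = 7)
  lay <- default_cluster_layout(278)
  expect_equal(as.integer(table(st$management)[lay$labels]), lay$counts)
  # published counts preserved except the padded largest cluster
  expect_equal(lay$counts[1:5], c(44, 7, 22, 57, 33))
  # custom counts honoured exactly too
  st2 <- attach_soil_and_management(
    design_278, cluster_layout = list(labels = c("A", "B"),
                                      counts = c(100, 178)), seed = 3)
  expect_equal(as.integer(table(st2$management)), c(100, 178))
})

test_that("cluster patches are spatially contiguous-ish and deterministic", {
  st1 <- attach_soil_and_management(design_278, seed = 5)
  st2 <- attach_soil_and_management(design_278, seed = 5)
  expect_identical(st1, st2)
  # mean within-cluster distance well below the landscape scale
  xy <- cbind(st1$x, st1$y)
  for (lev in levels(st1$management)) {
    idx <- st1$management == lev
    if (sum(idx) < 5) next
    within <- mean(dist(xy[idx, ]))
    expect_lt(within, mean(dist(xy)))
  }
})

test_that("all-zero cross-correlations give near-independent fields", {
  vg <- variogram_model(0.2, 0.8, 250, 0.5)
  specs <- list(a = field_spec("a", vg), b = field_spec("b", vg),
                c = field_spec("c", vg))
  st <- attach_soil_and_management(
    design_278, field_specs = specs,
    cluster_layout = list(labels = c("L1", "L2"), counts = c(139, 139)),
    seed = 8)
  cc <- cor(st[, c("a", "b", "c")])
  expect_true(all(abs(cc[upper.tri(cc)]) < 0.15))
})

test_that("non-positive-definite correlation requests are rejected", {
  vg <- variogram_model(0.2, 0.8, 250, 0.5)
  specs <- list(a = field_spec("a", vg, cross_correlations = c(b = 0.9,
                                                              c = 0.9)),
                b = field_spec("b", vg, cross_correlations = c(c = -0.9)),
                c = field_spec("c", vg))
  expect_error(attach_soil_and_management(
    design_278, field_specs = specs,
    cluster_layout = list(labels = "L", counts = 278), seed = 1),
    "not positive definite")
})

test_that("community counts close to the library size and are reproducible", {
  st <- attach_soil_and_management(design_278, seed = 2)
  spec <- default_community_spec(library_size = 5000)
  comm <- simulate_community(st, spec, seed = 4)
  m <- community_matrix(comm)
  expect_true(all(colSums(m) == 5000))
  expect_equal(dim(m), c(19L, 278L))
  expect_identical(comm, simulate_community(st, spec, seed = 4))
})

test_that("unknown soil columns in a community spec raise a schema error", {
  st <- attach_soil_and_management(design_278, seed = 2)
  spec <- community_spec(list(
    community_taxon("t1", "B;P1", env_coef = c(not_a_column = 1)),
    community_taxon("t2", "B;P2")), library_size = 100)
  expect_error(simulate_community(st, spec, seed = 1), "not_a_column")
})

test_that("a null taxon shows no land-management signal", {
  # taxon with no effects: one-way permutation test on cluster means should
  # be non-significant in at least 90% of replicates
  st <- attach_soil_and_management(design_278, seed = 6)
  spec <- community_spec(list(
    community_taxon("null", "B;P1", baseline = 0),
    community_taxon("bulk", "B;P2", baseline = 2)), library_size = 2000)
  groups <- st$management
  f_stat <- function(y, g) {
    gm <- tapply(y, g, mean)
    sum(tabulate(g) * (gm - mean(y))^2) / stats::var(y)
  }
  nonsig <- 0
  for (r in 1:50) {
    comm <- simulate_community(st, spec, seed = 100 + r)
    p <- community_matrix(comm, proportions = TRUE)["null", ]
    y <- log_transform_abundance(p)
    obs <- f_stat(y, groups)
    null <- replicate(199, f_stat(y, sample(groups)))
    if ((1 + sum(null >= obs)) / 200 > 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 45)
})

test_that("an environmental response propagates to the counts", {
  # pH coefficient +2, everything else flat: log relative abundance should
  # track pH strongly (forward-model check)
  st <- attach_soil_and_management(design_278, seed = 9)
  spec <- community_spec(list(
    community_taxon("resp", "B;P1", baseline = 0, env_coef = c(pH = 2)),
    community_taxon("bulk", "B;P2", baseline = 2)), library_size = 10800)
  comm <- simulate_community(st, spec, seed = 10)
  p <- community_matrix(comm, proportions = TRUE)["resp", ]
  y <- log_transform_abundance(p)
  expect_gt(cor(y, st$pH), 0.5)
})

test_that("the synthetic taxa tree is a valid ultrametric phylogeny", {
  tr <- simulate_taxa_tree(paste0("t", 1:8), seed = 3)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), paste0("t", 1:8))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_taxa_tree(paste0("t", 1:8),
                                                      seed = 3)))
})
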