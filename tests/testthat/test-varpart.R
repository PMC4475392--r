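make_landscape <- function(seed = 1) {
  d <- generate_sampling_design(215, 248, 30, seed = 1)
  st <- attach_soil_and_management(d, seed = seed)
  list(design = d, st = st, xy = cbind(d$x, d$y))
}

test_that("block preparation standardizes and prunes collinearity", {
  L <- make_landscape(5)
  b <- build_pcnm(L$xy)
  blocks <- prepare_blocks(L$st, pcnm = b)
  expect_lt(max(abs(colMeans(blocks$soil))), 1e-8)
  expect_equal(unname(apply(blocks$soil, 2, sd)), rep(1, ncol(blocks$soil)),
               tolerance = 1e-8)
  # nitrogen dropped for its r = 0.92 with organic carbon; exactly one of
  # the compositional texture triple dropped
  expect_false("total_nitrogen" %in% colnames(blocks$soil))
  expect_true("organic_carbon" %in% colnames(blocks$soil))
  tex <- c("clay", "silt", "sand") %in% colnames(blocks$soil)
  expect_equal(sum(tex), 2)
  # management dummy-coded with the reference level dropped
  expect_equal(ncol(blocks$management), 5)
  expect_false(any(grepl("Forest", colnames(blocks$management))))
})

test_that("the pairwise pruning rule matches an exhaustive scan", {
  set.seed(11)
  n <- 120
  x1 <- rnorm(n); x2 <- 0.97 * x1 + sqrt(1 - 0.97^2) * rnorm(n)
  x3 <- rnorm(n); x4 <- rnorm(n)
  df <- data.frame(site_id = 1:n, x = runif(n), y = runif(n),
                   v1 = x1, v2 = x2, v3 = x3, v4 = x4)
  blocks <- prepare_blocks(df, soil_vars = c("v1", "v2", "v3", "v4"),
                           cor_threshold = 0.9)
  # oracle: among the offending pair, the member with the larger mean
  # absolute correlation to everything else must go
  C <- abs(cor(df[, c("v1", "v2", "v3", "v4")])); diag(C) <- 0
  pair <- c("v1", "v2")
  loser <- pair[which.max(rowMeans(C)[pair])]
  expect_false(loser %in% colnames(blocks$soil))
  expect_equal(ncol(blocks$soil), 3)
})

test_that("forward selection finds planted signal and honours its gates", {
  n <- 278
  hits <- 0
  for (r in 1:20) {
    set.seed(1000 + r)
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    y <- 3 * X[, 1] + rnorm(n, 0, 0.3)
    sel <- forward_select(y, X, alpha = 0.001, n_perm = 999, seed = r)
    if (nrow(sel) >= 1 && sel$variable[1] == "x1" &&
        sel$p[1] == 1 / 1000) hits <- hits + 1
  }
  expect_gte(hits, 19) # >= 95% of 20 replicates
})

test_that("selection results are monotone and reproducible", {
  set.seed(12)
  n <- 150
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("x", 1:8)))
  y <- 2 * X[, 1] + 1 * X[, 2] + rnorm(n)
  s1 <- forward_select(y, X, alpha = 0.01, n_perm = 199, seed = 3)
  s2 <- forward_select(y, X, alpha = 0.01, n_perm = 199, seed = 3)
  expect_identical(s1, s2)
  expect_true(all(diff(s1$adj_r2) >= 0) || nrow(s1) < 2)
  expect_true(all(s1$p <= 0.01))
})

test_that("a duplicated copy of a selected variable is never re-selected", {
  set.seed(13)
  n <- 100
  x <- rnorm(n)
  X <- cbind(x1 = x, dup = x, x2 = rnorm(n))
  y <- 3 * x + rnorm(n, 0, 0.5)
  sel <- forward_select(y, X, alpha = 0.05, n_perm = 199, seed = 1)
  expect_false("dup" %in% sel$variable && "x1" %in% sel$variable)
})

test_that("abundance partition fractions sum to one and attribute variance", {
  L <- make_landscape(6)
  b <- build_pcnm(L$xy)
  blocks <- prepare_blocks(L$st, pcnm = b$vectors[, 1:20])
  y <- blocks$soil[, "pH"] + rnorm(278, 0, 0.5)
  pr <- partition_abundance(y, blocks, n_perm = 99, seed = 2)
  expect_equal(sum(pr$fractions), 1, tolerance = 1e-10)
  expect_gt(pr$fractions["soil"], pr$fractions["management"])
  expect_gt(pr$fractions["soil"], pr$fractions["space"])
  expect_lte(pr$p_values["soil"], 0.05)
  # a response equal to one management dummy is fully management-explained
  y2 <- blocks$management[, 1]
  pr2 <- partition_abundance(y2, blocks, n_perm = 0)
  expect_gt(pr2$fractions["management"], 0.95)
  expect_lt(abs(pr2$fractions["soil"]), 0.05)
})

test_that("orthogonal blocks yield near-zero foreign fractions", {
  # mutually orthogonal constructed blocks: soil-only response leaks < 0.02
  set.seed(14)
  n <- 200
  M <- qr.Q(qr(matrix(rnorm(n * 9), n, 9)))
  blocks <- structure(list(
    soil = M[, 1:3, drop = FALSE] * sqrt(n),
    management = M[, 4:6, drop = FALSE] * sqrt(n),
    space = M[, 7:9, drop = FALSE] * sqrt(n),
    pruned = character(0)), class = "predictor_blocks")
  colnames(blocks$soil) <- paste0("s", 1:3)
  colnames(blocks$management) <- paste0("m", 1:3)
  colnames(blocks$space) <- paste0("p", 1:3)
  y <- blocks$soil %*% c(1, -1, 0.5) + rnorm(n, 0, 0.4)
  pr <- partition_abundance(as.numeric(y), blocks, n_perm = 0)
  expect_lt(abs(pr$fractions["management"]), 0.02)
  expect_lt(abs(pr$fractions["space"]), 0.02)
  expect_gt(pr$fractions["soil"], 0.8)
})

test_that("two-block fractions agree with the vegan varpart oracle", {
  L <- make_landscape(7)
  blocks <- prepare_blocks(L$st)
  y <- blocks$soil[, "pH"] * 0.8 + rnorm(278)
  pr <- partition_abundance(y, blocks, n_perm = 0)
  vp <- vegan::varpart(y, blocks$soil, blocks$management)
  # vegan indfract rows: [a] = unique X1, [b] = unique X2, [c] = shared
  ind <- vp$part$indfract$Adj.R.square
  expect_equal(unname(pr$fractions["soil"]), ind[1], tolerance = 1e-8)
  expect_equal(unname(pr$fractions["management"]), ind[2], tolerance = 1e-8)
  expect_equal(unname(pr$fractions["shared"]), ind[3], tolerance = 1e-8)
})

test_that("db-RDA on Euclidean distances equals direct RDA", {
  set.seed(15)
  n <- 60
  Y <- matrix(rnorm(n * 4), n, 4)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("e", 1:3)))
  D <- as.matrix(dist(Y))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  blocks <- structure(list(soil = scale(X), management = NULL, space = NULL,
                           pruned = character(0)),
                      class = "predictor_blocks")
  pr <- partition_community(D, blocks, n_perm = 0)
  oracle <- vegan::RsquareAdj(vegan::rda(Y, X))
  expect_equal(unname(pr$unadjusted_full["full"]), oracle$r.squared,
               tolerance = 1e-8)
  expect_equal(unname(1 - pr$fractions["residual"]), oracle$adj.r.squared,
               tolerance = 1e-8)
})

test_that("db-RDA self-explanation and permutation behaviour", {
  set.seed(16)
  n <- 50
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  blocks <- structure(list(soil = scale(X), management = NULL, space = NULL,
                           pruned = character(0)),
                      class = "predictor_blocks")
  pr <- partition_community(D, blocks, n_perm = 199, seed = 1)
  expect_gt(1 - pr$fractions["residual"], 0.99)
  expect_equal(unname(pr$p_values["soil"]), 1 / 200)
  # asymmetric input rejected
  Dbad <- D; Dbad[1, 2] <- Dbad[1, 2] + 1
  expect_error(partition_community(Dbad, blocks), "symmetric")
})

test_that("null predictors give approximately uniform permutation p-values", {
  set.seed(17)
  n <- 40
  ps <- vapply(1:200, function(r) {
    Y <- matrix(rnorm(n * 2), n, 2)
    X <- matrix(rnorm(n * 2), n, 2)
    soilscape:::perm_block_test(Y, X, NULL, n_perm = 99, seed = r)
  }, numeric(1))
  # p-values are discrete multiples of 1/100; suppress the tie warning
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.05)
})

test_that("standardized coefficients obey their closed forms", {
  set.seed(18)
  x <- rnorm(120); y <- 0.6 * x + rnorm(120)
  sc <- standardized_coefficients(y, cbind(x = x))
  expect_equal(sc$coefficient, cor(x, y), tolerance = 1e-10)
  # rescaling a raw predictor leaves the standardized coefficient unchanged
  sc2 <- standardized_coefficients(y, cbind(x = 1000 * x))
  expect_equal(sc2$coefficient, sc$coefficient, tolerance = 1e-10)
  # self-regression
  sc3 <- standardized_coefficients(y, cbind(y = y))
  expect_equal(sc3$coefficient, 1, tolerance = 1e-10)
  # marginal contribution: dropping the only informative variable loses
  # the model's entire adjusted R2
  X <- cbind(x = x, noise = rnorm(120))
  sc4 <- standardized_coefficients(y, X)
  expect_gt(sc4$marginal_adj_r2[1], 0.2)
  expect_lt(abs(sc4$marginal_adj_r2[2]), 0.05)
})

test_that("permutation machinery is seed-stable across entry points", {
  set.seed(19)
  Y <- matrix(rnorm(60), 60, 1)
  X <- matrix(rnorm(60 * 2), 60, 2)
  p1 <- soilscape:::perm_block_test(Y, X, NULL, n_perm = 99, seed = 42)
  p2 <- soilscape:::perm_block_test(Y, X, NULL, n_perm = 99, seed = 42)
  expect_identical(p1, p2)
})
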