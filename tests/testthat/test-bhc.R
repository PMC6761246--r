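test_that("quantile discretization bins by tertiles with ties to the lower bin", {
  d <- discretize(cbind(c(1, 2, 3, 4, 5, 6)))
  expect_equal(unname(d$values[, 1]), c(0, 0, 1, 1, 2, 2))
  # values equal to a tertile edge go to the lower bin: for (1,2,3,4) the
  # edges are exactly 2 and 3
  d2 <- discretize(cbind(c(1, 2, 3, 4)))
  expect_equal(unname(d2$values[, 1]), c(0, 0, 1, 2))
  expect_warning(dc <- discretize(cbind(rep(7, 5))), "constant")
  expect_true(all(dc$values == 0))
  # monotone transforms leave the coding unchanged
  x <- rnorm(30)
  expect_identical(discretize(matrix(x, ncol = 1))$values,
                   discretize(matrix(exp(x), ncol = 1))$values)
  expect_error(discretize(cbind(x), n_bins = 1), "n_bins")
})

test_that("Dirichlet-multinomial marginal likelihood has its closed forms", {
  # one item, one column, beta = 1, 3 categories: uniform predictive 1/3
  expect_equal(dirichlet_multinomial_logml(cbind(c(1, 0, 0)), 1), log(1 / 3))
  # two items in the same category: 1/3 * (1+1)/(3+1)
  expect_equal(dirichlet_multinomial_logml(cbind(c(2, 0, 0)), 1), log(1 / 6))
  # independent columns factorize
  c1 <- cbind(c(2, 1, 0)); c2 <- cbind(c(0, 1, 2))
  expect_equal(dirichlet_multinomial_logml(cbind(c1, c2), 0.7),
               dirichlet_multinomial_logml(c1, 0.7) +
                 dirichlet_multinomial_logml(c2, 0.7))
  expect_error(dirichlet_multinomial_logml(cbind(c(1, -1, 0)), 1), "non-negative")
  expect_error(dirichlet_multinomial_logml(cbind(c(1, 0, 0)), 0), "positive")
})

test_that("the n = 2 merge prior has closed form 1/(1+alpha)", {
  for (a in c(0.05, 0.5, 1, 3, 40)) {
    tree <- bhc_build(matrix(c(0L, 2L), 2, 1), alpha = a, n_bins = 3)
    expect_equal(exp(tree$log_pi[3]), 1 / (1 + a), tolerance = 1e-12)
    # root p(D|T) = pi p(D|H1) + (1-pi) p(D1) p(D2)
    manual <- exp(tree$log_pi[3] + tree$log_ml_h1[3]) +
      (1 - exp(tree$log_pi[3])) * exp(tree$log_ml_tree[1] + tree$log_ml_tree[2])
    expect_equal(tree$log_ml_root, log(manual), tolerance = 1e-12)
  }
})

test_that("recursion equals the exhaustive partition oracle on small data", {
  # exhaustive grid: every 3-item single-column dataset over 3 categories
  grid <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  for (i in seq_len(nrow(grid))) {
    v <- matrix(as.integer(grid[i, ]), 3, 1)
    tree <- bhc_build(v, alpha = 0.7, beta = 1.3, n_bins = 3)
    o <- oracle_root_logml(tree, v, 1.3, 3)
    expect_equal(tree$log_ml_root, o, tolerance = 1e-8)
  }
  # random instances up to 4 items x 3 columns
  set.seed(42)
  for (rep in 1:100) {
    ni <- sample(2:4, 1); nc <- sample(1:3, 1)
    a <- exp(runif(1, -2, 2)); b <- exp(runif(1, -1, 1))
    v <- matrix(sample(0:2, ni * nc, replace = TRUE), ni, nc)
    tree <- bhc_build(v, alpha = a, beta = b, n_bins = 3)
    o <- oracle_root_logml(tree, v, b, 3)
    expect_equal(tree$log_ml_root, o, tolerance = 1e-8)
  }
})

test_that("identical items merge before discordant ones and r stays in [0,1]", {
  v <- rbind(x1 = c(0L, 0L, 0L), x2 = c(0L, 0L, 0L), y = c(2L, 2L, 2L))
  tree <- bhc_build(v, n_bins = 3)
  expect_equal(tree$merges[1, ], c(1, 2))  # the identical pair merges first
  expect_true(all(tree$r >= 0 & tree$r <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(tree$r[1:3] == 1))       # leaf convention
})

test_that("trees are deterministic for identical input and hyperparameters", {
  set.seed(6)
  v <- matrix(sample(0:2, 60, replace = TRUE), 12, 5)
  t1 <- bhc_build(v, alpha = 0.8, beta = 1.2, n_bins = 3)
  t2 <- bhc_build(v, alpha = 0.8, beta = 1.2, n_bins = 3)
  expect_identical(t1$merges, t2$merges)
  expect_identical(t1$log_ml_root, t2$log_ml_root)
})

test_that("cut_tree produces the documented partitions", {
  sim <- simulate_feature_blocks(n_clusters = 2, features_per_cluster = 5,
                                 n_columns = 20, seed = 31)
  disc <- t(discretize(t(sim$matrix))$values)
  tree <- bhc_build(disc)
  part <- cut_tree(tree)
  expect_length(unique(part), 2)
  expect_equal(length(part), 10)
  # partition matches planted truth exactly (up to labels): a bijection
  # between recovered clusters and planted blocks
  ct <- table(part, sim$truth) > 0
  expect_true(all(rowSums(ct) == 1) && all(colSums(ct) == 1))
  # cut at 0 keeps everything in one cluster; cut above 1 fully shatters
  expect_length(unique(cut_tree(tree, cut = 0)), 1)
  expect_length(unique(cut_tree(tree, cut = 1 + 1e-9)), 10)
})

test_that("concentration selection maximizes evidence with ties to small alpha", {
  v <- matrix(sample(0:2, 30, replace = TRUE), 6, 5)
  one <- optimize_concentration(v, grid = 0.3, n_bins = 3)
  expect_equal(one$alpha, 0.3)
  dup <- optimize_concentration(v, grid = c(2, 0.5, 2), n_bins = 3)
  best <- min(as.numeric(names(dup$log_ml)[dup$log_ml == max(dup$log_ml)]))
  expect_equal(dup$alpha, best)
  # a strongly clustered toy prefers small over huge concentration
  sim <- simulate_feature_blocks(n_clusters = 2, features_per_cluster = 6,
                                 n_columns = 15, noise_sd = 0.1, seed = 8)
  disc <- t(discretize(t(sim$matrix))$values)
  res <- optimize_concentration(disc, grid = c(0.01, 1, 100), n_bins = 3)
  expect_lt(res$alpha, 100)
  expect_equal(res$tree$log_ml_root, max(res$log_ml))
})

test_that("Newick export carries r_k support values and parses", {
  skip_if_not_installed("ape")
  sim <- simulate_feature_blocks(n_clusters = 2, features_per_cluster = 4,
                                 n_columns = 10, seed = 2)
  tree <- bhc_build(t(discretize(t(sim$matrix))$values))
  nwk <- bhc_newick(tree)
  ph <- ape::read.tree(text = nwk)
  expect_equal(length(ph$tip.label), 8)
  expect_equal(sort(ph$tip.label), sort(gsub("[][();,: ]", "_", tree$items)))
  supports <- as.numeric(ph$node.label)
  expect_true(all(supports >= 0 & supports <= 1))
})

test_that("bicluster swaps trees under transposition and handles 2 individuals", {
  sim <- simulate_feature_blocks(n_clusters = 2, features_per_cluster = 4,
                                 n_columns = 12, seed = 77)
  bc <- bicluster(sim$matrix)
  bct <- bicluster(t(sim$matrix))
  expect_identical(bc$feature_tree$merges, bct$individual_tree$merges)
  expect_identical(bc$individual_tree$merges, bct$feature_tree$merges)
  two <- matrix(rnorm(20), nrow = 10,
                dimnames = list(paste0("f", 1:10), c("i1", "i2")))
  bc2 <- bicluster(two)
  expect_equal(bc2$individual_tree$n_items, 2)
  expect_equal(nrow(bc2$individual_tree$merges), 1)
})

test_that("planted feature blocks are recovered and a planted CE block co-clusters", {
  sim <- simulate_feature_blocks(seed = 123)
  bc <- bicluster(sim$matrix)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(bc$feature_clusters, sim$truth)
  expect_gte(ari, 0.9)
})
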