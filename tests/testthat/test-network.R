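make_event <- function(lead, traits) {
  structure(list(lead = lead, traits = traits, method = "multitrait"),
            class = "coloc_event")
}

test_that("build_zmatrix applies the sample-size-dependent significance
           gates", {
  lookup <- list(
    big = make_stats("v1", beta = 0.049, se = 0.01, n = 100000),
    small = make_stats("v1", beta = 0.049, se = 0.01, n = 50000))
  lookup$big[, `:=`(z = 4.9, p = 1e-6)]     # significant only at 1e-5
  lookup$small[, `:=`(z = 4.9, p = 1e-6)]
  ev <- list(make_event("v1", c("t2d", "big", "small")))
  zm <- build_zmatrix(ev, lookup, index_trait = "t2d")
  # p = 1e-6 fails the 5e-8 gate for N > 60,000 but passes 1e-5 below it
  expect_equal(zm$values["v1", "big"], 0)
  expect_equal(zm$values["v1", "small"], 4.9)

  # a variant whose traits all fail their gates keeps an all-zero row
  lookup2 <- list(big = lookup$big)
  zm2 <- build_zmatrix(list(make_event("v1", c("t2d", "big"))), lookup2,
                       index_trait = "t2d")
  expect_true(all(zm2$values == 0))

  # unresolvable lead errors naming variant and trait
  expect_error(
    build_zmatrix(list(make_event("v9", c("t2d", "big"))), lookup,
                  index_trait = "t2d"),
    "v9.*big")
})

test_that("snp_correlation matches the textbook Pearson formula", {
  zm <- structure(list(variants = c("a", "b", "c"),
                       traits = c("x", "y", "w"),
                       values = rbind(c(1, -1, 0), c(-1, 1, 0),
                                      c(2, -2, 0))),
                  class = "zmatrix")
  cc <- snp_correlation(zm)
  expect_equal(cc["a", "b"], -1)
  expect_equal(cc["a", "c"], 1)

  set.seed(81)
  vals <- matrix(rnorm(60), 10, 6)
  zm2 <- structure(list(variants = sprintf("v%d", 1:10),
                        traits = sprintf("t%d", 1:6), values = vals),
                   class = "zmatrix")
  cc2 <- snp_correlation(zm2)
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(cc2[i, j], brute_pearson(vals[i, ], vals[j, ]),
                   tolerance = 1e-10)
    }
  }

  # zero-variance rows get correlation 0, logged
  vals3 <- rbind(vals, 0)
  zm3 <- structure(list(variants = sprintf("v%d", 1:11),
                        traits = sprintf("t%d", 1:6), values = vals3),
                   class = "zmatrix")
  expect_message(cc3 <- snp_correlation(zm3), "zero-variance")
  expect_true(all(cc3["v11", colnames(cc3) != "v11"] == 0))
})

test_that("min_degree_threshold equals the exhaustive cutoff scan", {
  # worked 3-node case: edges 0.9, 0.5, 0.2 -> cutoff 0.5
  cc <- diag(3)
  cc[1, 2] <- cc[2, 1] <- 0.9
  cc[2, 3] <- cc[3, 2] <- 0.5
  cc[1, 3] <- cc[3, 1] <- 0.2
  expect_equal(as.numeric(min_degree_threshold(cc)), 0.5)
  # complete graph with equal weights: cutoff is that weight
  cc2 <- matrix(0.7, 4, 4); diag(cc2) <- 1
  expect_equal(as.numeric(min_degree_threshold(cc2)), 0.7)
  # random matrices vs brute force, exact agreement
  set.seed(82)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 8), n, 8)
    cc3 <- cor(t(x))
    expect_identical(as.numeric(min_degree_threshold(cc3)),
                     brute_min_degree_threshold(cc3))
  }
})

test_that("modularity_q matches hand computation and independent
           oracles", {
  adj <- two_triangle_adj()
  expect_equal(modularity_q(adj, rep(1, 6)), 0)   # one community
  expect_equal(modularity_q(adj, c(1, 1, 1, 2, 2, 2)),
               2 * (3 / 7 - (7 / 14)^2), tolerance = 1e-12)
  expect_equal(modularity_q(adj, c(1, 1, 1, 2, 2, 2)), 0.3571,
               tolerance = 1e-3)
  set.seed(83)
  for (i in 1:30) {
    n <- sample(5:12, 1)
    adj2 <- matrix(runif(n * n) * (runif(n * n) < 0.4), n, n)
    adj2 <- (adj2 + t(adj2)) / 2
    diag(adj2) <- 0
    mem <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(adj2, mem), brute_modularity(adj2, mem),
                 tolerance = 1e-10)
    # cross-check against igraph on the same weighted graph
    g <- igraph::graph_from_adjacency_matrix(adj2, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_q(adj2, mem),
                 igraph::modularity(g, mem, weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
    # permutation invariance of labels
    relabel <- c(3, 1, 2)[mem]
    expect_equal(modularity_q(adj2, relabel), modularity_q(adj2, mem),
                 tolerance = 1e-12)
  }
})

test_that("spinglass_cluster recovers planted structure and drops small
           clusters from retention", {
  # two 5-cliques joined by one edge
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 0.9
  adj[6:10, 6:10] <- 0.9
  adj[5, 6] <- adj[6, 5] <- 0.9
  diag(adj) <- 1
  sol <- spinglass_cluster(adj, 0.5,
                           cluster_config(n_restarts = 5, seed = 2))
  expect_equal(sol$k, 2)
  expect_equal(length(unique(sol$membership[1:5])), 1)
  expect_equal(length(unique(sol$membership[6:10])), 1)
  expect_true(sol$membership[1] != sol$membership[10])

  # winning modularity beats random partitions on the same graph
  pruned <- adj; pruned[pruned < 0.5] <- 0; diag(pruned) <- 0
  set.seed(84)
  rand_q <- replicate(100, modularity_q(pruned,
                                        sample(1:2, 10, replace = TRUE)))
  expect_gte(sol$modularity, max(rand_q))

  # a planted 3-variant cluster is kept in membership but not retained
  set.seed(85)
  plan <- list(a = c(x = 1, y = 1, w = 0, u = 0),
               b = c(x = 0, y = 0, w = 1, u = -1))
  sim <- simulate_zmatrix(plan, n_per_cluster = c(5, 3), noise_sd = 0.3)
  cc <- snp_correlation(sim$zmatrix)
  sol2 <- suppressMessages(
    spinglass_cluster(cc, 0.5, cluster_config(n_restarts = 5, seed = 3,
                                              min_cluster_size = 4)))
  small <- unique(sol2$membership[sim$membership == "b"])
  expect_length(small, 1)
  expect_false(small %in% sol2$retained)
  expect_true(unique(sol2$membership[sim$membership == "a"]) %in%
                sol2$retained)
})

test_that("summarize_clusters reports per-cluster trait means", {
  vals <- rbind(c(5, 0, 0), c(5, 0, 0), c(5, 0, 0), c(5, 0, 0),
                c(0, 3, 0))
  zm <- structure(list(variants = sprintf("v%d", 1:5),
                       traits = c("A", "B", "C"), values = vals),
                  class = "zmatrix")
  sol <- structure(list(membership = setNames(c(1, 1, 1, 1, 2),
                                              zm$variants),
                        retained = 1L), class = "cluster_solution")
  sig <- summarize_clusters(zm, sol)
  expect_equal(sig[trait == "A", mean_z], 5)
  expect_equal(sig[trait == "B", mean_z], 0)
  expect_equal(nrow(sig), 3)   # only the retained cluster

  sol$retained <- integer(0)
  empty <- summarize_clusters(zm, sol)
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("cluster", "trait", "mean_z"))
})

test_that("adjusted Rand index agrees with the mclust reference
           implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  set.seed(86)
  for (i in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
  }
})
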