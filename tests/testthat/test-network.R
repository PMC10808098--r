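test_that("inverse-variance locus weights preserve ratios and cap monomorphic loci", {
  # locus variances 1/3 and 1 -> inverse-variance weights in ratio 3:1
  mat <- cbind(c(10L, 10L, 11L, 11L), c(10L, 10L, 10L, 12L))
  w <- locus_weights_inverse_variance(ht(mat))
  expect_equal(unname(w$weights[1] / w$weights[2]), 3)

  mono <- cbind(c(10L, 11L), c(12L, 12L))
  w2 <- locus_weights_inverse_variance(ht(mono), cap = 10)
  expect_equal(unname(w2$weights[2]), 10)

  eq <- cbind(c(10L, 11L), c(12L, 13L))
  w3 <- locus_weights_inverse_variance(ht(eq))
  expect_equal(unname(w3$weights[1]), unname(w3$weights[2]))
  expect_true(all(w3$weights >= 1))
})

test_that("pairwise_steps sums absolute per-locus differences", {
  h1 <- c(L1 = 13L, L2 = 10L, L3 = 20L)
  expect_equal(pairwise_steps(h1, h1)$total, 0)
  h2 <- c(L1 = 15L, L2 = 10L, L3 = 20L)
  expect_equal(pairwise_steps(h1, h2)$total, 2)
  h3 <- c(L1 = 14L, L2 = 10L, L3 = 17L)
  expect_equal(pairwise_steps(h1, h3)$total, 4)
  expect_equal(unname(pairwise_steps(h1, h3)$per_locus), c(1, 0, 3))
  expect_error(pairwise_steps(h1, c(LX = 1L, L2 = 2L, L3 = 3L)), "panel")
  expect_error(pairwise_steps(h1, c(L1 = NA, L2 = 2L, L3 = 3L)), "complete")
})

test_that("degenerate and closed-form median-joining cases", {
  # identical haplotypes collapse to a single node without edges
  same <- ht(matrix(12L, 5, 3))
  net <- median_joining(same)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(igraph::ecount(net$graph), 0L)
  expect_equal(net$nodes$multiplicity, 5L)

  # A=(10,10), B=(11,10), C=(10,11): star through A, no median vector
  tri <- ht(rbind(c(10L, 10L), c(11L, 10L), c(10L, 11L)))
  net2 <- median_joining(tri, weights = equal_locus_weights(c("L1", "L2")))
  expect_equal(sum(net2$nodes$is_median_vector), 0L)
  expect_equal(igraph::ecount(net2$graph), 2L)
  deg <- igraph::degree(net2$graph)
  a <- which(net2$haplotypes[, 1] == 10 & net2$haplotypes[, 2] == 10)
  expect_equal(unname(deg[a]), 2)

  # square lattice: adjacent path lengths equal direct step counts
  sq <- ht(rbind(c(10L, 10L), c(12L, 10L), c(10L, 12L), c(12L, 12L)))
  net3 <- median_joining(sq, weights = equal_locus_weights(c("L1", "L2")))
  g <- net3$graph
  obs <- which(!net3$nodes$is_median_vector)
  sp <- igraph::distances(g, weights = igraph::E(g)$steps)
  for (i in obs) for (j in obs) {
    direct <- sum(abs(net3$haplotypes[i, ] - net3$haplotypes[j, ]))
    if (direct == 2) expect_equal(sp[i, j], 2)
  }

  # one varying locus: the chain of observed alleles
  chain <- ht(matrix(c(10L, 11L, 13L), 3, 1))
  net4 <- median_joining(chain, weights = equal_locus_weights("L1"))
  expect_equal(igraph::ecount(net4$graph), 2L)
  expect_equal(sort(igraph::E(net4$graph)$steps), c(1, 2))

  expect_error(median_joining(ht(matrix(12L, 1, 2)), epsilon = -1), "epsilon")
})

test_that("median-joining output is invariant under record order", {
  set.seed(13)
  tab <- random_table(8, 3)
  net_a <- median_joining(tab, weights = equal_locus_weights(panel_loci(tab)))
  shuf <- subset_table(tab, rows = sample(8))
  net_b <- median_joining(shuf, weights = equal_locus_weights(panel_loci(tab)))
  expect_identical(net_a$haplotypes, net_b$haplotypes)
  expect_equal(igraph::ecount(net_a$graph), igraph::ecount(net_b$graph))
  expect_identical(igraph::as_edgelist(net_a$graph),
                   igraph::as_edgelist(net_b$graph))
})

test_that("the observed-haplotype subnetwork is connected and respects the MSN oracle", {
  set.seed(37)
  for (inst in 1:12) {
    k <- sample(3:6, 1)
    H <- unique(matrix(sample(10:13, k * 3, replace = TRUE), k, 3))
    tab <- ht(H)
    net <- median_joining(tab, weights = equal_locus_weights(panel_loci(tab)))
    g <- net$graph
    expect_true(igraph::is_connected(g))
    # the emitted graph is exactly the epsilon-MSN of its final node set,
    # checked against an independent Floyd-Warshall minimax oracle
    oracle <- oracle_msn(net$haplotypes)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    expect_identical(unname(adj), oracle$adjacency)
    sp <- igraph::distances(g, weights = igraph::E(g)$steps)
    key_net <- apply(net$haplotypes, 1, paste, collapse = "-")
    key_obs <- apply(H, 1, paste, collapse = "-")
    map <- match(key_obs, key_net)
    for (i in seq_len(nrow(H) - 1)) for (j in seq(i + 1, nrow(H))) {
      direct <- sum(abs(H[i, ] - H[j, ]))
      # network paths are valid mutational paths, never shorter than the
      # direct single-step distance ...
      expect_gte(sp[map[i], map[j]], direct - 1e-9)
      # ... and linked pairs sit at exactly their direct distance
      if (oracle$adjacency[map[i], map[j]]) {
        expect_equal(sp[map[i], map[j]], direct)
      }
    }
  }
})

test_that("group separation is a shortest-path quantity over step lengths", {
  tab <- ht(rbind(c(10L, 10L), c(10L, 10L), c(10L, 13L)),
            populations = c("A", "B", "C"))
  net <- median_joining(tab, weights = equal_locus_weights(c("L1", "L2")))
  expect_equal(group_separation(net, "A", "B"), 0)
  expect_equal(group_separation(net, "A", "C"), 3)
  expect_equal(group_separation(net, c("A", "B"), "C"), 3)
  expect_error(group_separation(net, "Z", "A"), "groupA")
})

test_that("GraphML export round-trips node and edge attributes", {
  set.seed(3)
  tab <- random_table(6, 3, populations = "A")
  net <- median_joining(tab)
  f <- tempfile(fileext = ".graphml")
  write_network(net, f)
  back <- read_network_graphml(f)
  expect_equal(igraph::vcount(back), nrow(net$nodes))
  expect_equal(igraph::ecount(back), igraph::ecount(net$graph))
  expect_setequal(igraph::vertex_attr_names(back),
                  c("name", "multiplicity", "is_median_vector",
                    "haplotype", "populations", "id"))
  expect_equal(sort(igraph::E(back)$steps), sort(igraph::E(net$graph)$steps))
  f2 <- tempfile(fileext = ".dot")
  write_network(net, f2, format = "dot")
  expect_gt(file.size(f2), 0)
})
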