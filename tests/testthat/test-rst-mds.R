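test_that("Rst hits its boundary cases", {
  # fixed difference at one locus, no within-group variance -> 1
  a <- ht(matrix(10L, 3, 1), populations = "A")
  a$repeats[1, 1] <- 10L
  b <- ht(matrix(14L, 3, 1), populations = "B", samples = paste0("B", 1:3))
  # give each group a sliver of variance at a second locus? No: spec case
  # is exactly one varying locus with zero within-group variance.
  expect_equal(rst_pair(a, b), 1)

  # identical composition -> at most 0 (slightly negative by sampling)
  x <- ht(matrix(c(10L, 11L, 12L), 3, 1), populations = "A")
  y <- ht(matrix(c(10L, 11L, 12L), 3, 1), populations = "B",
          samples = paste0("B", 1:3))
  expect_lte(rst_pair(x, y), 0)

  # no variance anywhere -> undefined
  expect_error(rst_pair(ht(matrix(10L, 3, 2)),
                        ht(matrix(10L, 3, 2), samples = paste0("B", 1:3))),
               "zero total variance")
  expect_error(rst_pair(ht(matrix(10:11, 2, 1)), ht(matrix(12L, 1, 1))),
               "insufficient")
})

test_that("Rst is invariant to per-locus shifts and record order", {
  set.seed(21)
  a <- random_table(8, 5, populations = "A")
  b <- random_table(6, 5, populations = "B")
  base <- rst_pair(a, b)
  a2 <- a; a2$repeats[, 2] <- a2$repeats[, 2] + 9L
  b2 <- b; b2$repeats[, 2] <- b2$repeats[, 2] + 9L
  expect_equal(rst_pair(a2, b2), base, tolerance = 1e-12)
  expect_equal(rst_pair(subset_table(a, rows = sample(8)), b), base,
               tolerance = 1e-12)
})

test_that("permutation test is seeded, add-one corrected, and exact on toys", {
  a <- ht(matrix(10L, 10, 1) + diag(0L, 10, 1), populations = "A")
  a$repeats[, 1] <- c(10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 10L, 11L)
  b <- ht(matrix(20L, 10, 1), populations = "B", samples = paste0("B", 1:10))
  b$repeats[, 1] <- c(20L, 20L, 20L, 20L, 20L, 20L, 20L, 20L, 20L, 21L)
  r1 <- permutation_test(a, b, n_permutations = 2000, seed = 99)
  r2 <- permutation_test(a, b, n_permutations = 2000, seed = 99)
  expect_identical(r1, r2)
  # separation so strong that no sampled relabeling reaches the observed Rst
  expect_equal(r1$p_value, 1 / 2001)
  expect_gt(r1$rst, 0.9)

  # identical 3+3 composition: exhaustively, at least half the splits do
  # as well as the observed one
  x <- ht(matrix(c(10L, 11L, 12L), 3, 1), populations = "A")
  y <- ht(matrix(c(10L, 11L, 12L), 3, 1), populations = "B",
          samples = paste0("B", 1:3))
  ex <- permutation_test(x, y, method = "exhaustive")
  expect_equal(ex$n_permutations, choose(6, 3))
  expect_gte(ex$p_value, 0.5)
})

test_that("exhaustive enumeration matches the independent rst_pair oracle", {
  set.seed(31)
  for (i in 1:4) {
    a <- random_table(4, 3, populations = "A")
    b <- random_table(4, 3, populations = "B")
    ex <- permutation_test(a, b, method = "exhaustive")
    expect_equal(ex$p_value, oracle_exhaustive_p(a, b), tolerance = 1e-12)
  }
})

test_that("Bonferroni threshold and comparison counts follow alpha/m", {
  bt <- bonferroni_threshold(0.05, 136)
  expect_equal(bt$display, 4e-04)
  expect_equal(bt$threshold, 0.05 / 136)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(n_pairwise_comparisons(17), 136L)
  expect_equal(n_pairwise_comparisons(1), 0L)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("mean Rst is nondecreasing in split time", {
  rates <- stats::setNames(rep(0.002, 10), paste0("L", 1:10))
  mean_rst <- sapply(c(0, 300, 1500), function(st) {
    vals <- sapply(1:200, function(r) {
      cfgA <- sim_config(10, rates = rates, tmrca = 40, genealogy = "star",
                         population_label = "A")
      cfgB <- sim_config(10, rates = rates, tmrca = 40, genealogy = "star",
                         population_label = "B")
      tab <- simulate_split(cfgA, cfgB, split_time = st,
                            seed = 7000 + st + r)
      tryCatch(rst_pair(subset_table(tab, population = "A"),
                        subset_table(tab, population = "B")),
               error = function(e) NA_real_)
    })
    mean(vals, na.rm = TRUE)
  })
  expect_true(all(diff(mean_rst) > 0))
  expect_lt(abs(mean_rst[1]), 0.05)
  expect_gt(mean_rst[3], 0.5)
})

test_that("rst_matrix assembles symmetric values, p-values and flags", {
  set.seed(77)
  rates <- stats::setNames(rep(0.003, 8), paste0("L", 1:8))
  tabs <- lapply(c("A", "B", "C"), function(p) {
    simulate_star(sim_config(8, rates = rates, tmrca = 150,
                             population_label = p,
                             founder = stats::setNames(
                               rep(switch(p, A = 20L, B = 24L, C = 20L), 8),
                               names(rates))))
  })
  tab <- do.call(bind_tables, tabs)
  m <- rst_matrix(tab, n_permutations = 199, seed = 5)
  expect_equal(diag(m$values), rep(0, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(m$values))
  expect_true(all(m$p_values[upper.tri(m$p_values)] > 0))
  expect_equal(m$threshold$m, 3)
  f <- tempfile(fileext = ".tsv")
  write_distance_matrix(m, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.tsv$", ".pvalues.tsv", f)))
})

test_that("classical MDS recovers collinear and Euclidean configurations", {
  # three collinear points with gaps 3 and 4
  d <- matrix(c(0, 3, 7, 3, 0, 4, 7, 4, 0), 3, 3)
  emb <- suppressWarnings(classical_mds(d, k = 1))
  got <- as.matrix(stats::dist(emb$coordinates))
  expect_equal(got, d, ignore_attr = TRUE, tolerance = 1e-8)
  expect_lt(emb$stress, 1e-8)

  # an exact Euclidean configuration embeds with stress 0, R^2 = 1
  set.seed(9)
  pts <- matrix(rnorm(12), 6, 2)
  emb2 <- classical_mds(as.matrix(stats::dist(pts)), k = 2)
  expect_lt(emb2$stress, 1e-8)
  expect_equal(emb2$r_squared, 1, tolerance = 1e-8)
  expect_equal(colMeans(emb2$coordinates), c(0, 0), tolerance = 1e-10)

  # all-zero distances: everything coincides
  z <- classical_mds(matrix(0, 4, 4), k = 2)
  expect_equal(z$stress, 0)
  expect_true(all(z$coordinates == 0))
})

test_that("MDS floors negative entries and warns when axes run out", {
  d <- matrix(c(0, -0.01, 0.5, -0.01, 0, 0.5, 0.5, 0.5, 0), 3, 3)
  emb <- suppressWarnings(classical_mds(d, k = 2))
  expect_true(all(is.finite(emb$coordinates)))
  dd <- matrix(c(0, 3, 7, 3, 0, 4, 7, 4, 0), 3, 3)
  expect_warning(classical_mds(dd, k = 2), "positive eigenvalue")
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})
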