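# Fixture builders and independent oracles shared across test files.

# Normalized table from a plain matrix; loci auto-named L1..Lk.
ht <- function(mat, populations = "Pop", samples = NULL, loci = NULL) {
  mat <- as.matrix(mat)
  if (is.null(loci)) loci <- paste0("L", seq_len(ncol(mat)))
  colnames(mat) <- loci
  if (is.null(samples)) samples <- sprintf("S%03d", seq_len(nrow(mat)))
  haplotype_table(samples, populations, mat, normalized = TRUE)
}

# A 17-locus un-normalized table with given DYS389I/II and filler elsewhere.
raw_yfiler_table <- function(n = 3, dys389i = 13, dys389ii = 29) {
  loci <- yfiler_panel()
  mat <- matrix(14L, n, length(loci), dimnames = list(NULL, loci))
  mat[, "DYS389I"] <- dys389i
  mat[, "DYS389II"] <- dys389ii
  haplotype_table(sprintf("R%02d", seq_len(n)), "PopX", mat)
}

# Random small normalized table for oracle suites (repeats 10..14, with a
# chance of missing calls when allow_na).
random_table <- function(n, L, populations = "Pop", allow_na = FALSE) {
  mat <- matrix(sample(10:14, n * L, replace = TRUE), n, L)
  if (allow_na && n > 2) {
    mat[sample(length(mat), 1L)] <- NA
  }
  ht(mat, populations = populations,
     samples = sprintf("%s_%03d", populations[1], seq_len(n)))
}

# --- independent oracles ------------------------------------------------------

# Gene diversity at one locus by explicit pair counting: the fraction of
# unordered pairs of individuals that differ, which equals Nei's unbiased
# n(1 - sum p^2)/(n-1).
oracle_gd_locus <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  pairs <- utils::combn(n, 2)
  mean(x[pairs[1, ]] != x[pairs[2, ]])
}

# Unbiased variance via mean squared pairwise difference / 2.
oracle_var_pairs <- function(x) {
  n <- length(x)
  pairs <- utils::combn(n, 2)
  sum((x[pairs[1, ]] - x[pairs[2, ]])^2) / (n * (n - 1) / 2) / 2
}

# Exhaustive permutation p-value by enumerating all size-preserving group
# assignments through the public rst_pair (a different code path from the
# vectorized permutation internals).
oracle_exhaustive_p <- function(popA, popB) {
  tab <- bind_tables(popA, popB)
  nA <- n_samples(popA); N <- n_samples(tab)
  obs <- rst_pair(popA, popB)
  idx <- utils::combn(N, nA)
  vals <- apply(idx, 2, function(a) {
    rst_pair(subset_table(tab, rows = a),
             subset_table(tab, rows = setdiff(seq_len(N), a)))
  })
  mean(vals >= obs - 1e-12)
}

# Brute-force epsilon-relaxed minimum spanning network on a haplotype
# matrix: minimax path distances by Floyd–Warshall on the complete graph
# (independent of the package's MST-based construction).
oracle_msn <- function(H, w = rep(1, ncol(H)), epsilon = 0) {
  n <- nrow(H)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    D[i, j] <- sum(abs(H[i, ] - H[j, ]) * w)
  }
  M <- D
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    M[i, j] <- min(M[i, j], max(M[i, k], M[k, j]))
  }
  adj <- D <= M + epsilon + 1e-9
  diag(adj) <- FALSE
  list(dist = D, minimax = M, adjacency = adj)
}

# Exact E|net displacement| of a +/-1 random walk with Poisson(lambda)
# steps, by truncated enumeration.
expected_abs_walk <- function(lambda, kmax = 60) {
  k <- 0:kmax
  pk <- stats::dpois(k, lambda)
  eabs <- vapply(k, function(kk) {
    j <- 0:kk
    sum(stats::dbinom(j, kk, 0.5) * abs(2 * j - kk))
  }, numeric(1))
  sum(pk * eabs)
}

write_tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
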