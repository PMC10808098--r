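# Per-locus AMOVA variance components on repeat scores for k groups.
# X: complete numeric matrix (individuals x loci); g: integer group index.
# Returns list(sig_a, sig_w): per-locus among- and within-group components
# (Michalakis & Excoffier convention; sig_a may be negative by sampling).
.rst_components <- function(X, g) {
  N <- nrow(X)
  sizes <- tabulate(g)
  k <- length(sizes)
  T2 <- colSums(X^2)
  G <- colSums(X)
  ss_group <- matrix(0, k, ncol(X))
  for (j in seq_len(k)) {
    ss_group[j, ] <- colSums(X[g == j, , drop = FALSE])
  }
  within_fit <- colSums(ss_group^2 / sizes)
  ssd_within <- T2 - within_fit
  ssd_among <- within_fit - G^2 / N
  msd_within <- ssd_within / (N - k)
  msd_among <- ssd_among / (k - 1)
  n_c <- (N - sum(sizes^2) / N) / (k - 1)
  sig_w <- msd_within
  sig_a <- (msd_among - msd_within) / n_c
  list(sig_a = sig_a, sig_w = sig_w)
}

# Rst from components summed across loci before forming the ratio.
.rst_from_components <- function(comp) {
  num <- sum(comp$sig_a)
  den <- sum(comp$sig_a + comp$sig_w)
  if (den == 0) return(NA_real_)
  num / den
}

#' Pairwise Rst between two population samples
#'
#' Slatkin-type analog of Fst for microsatellites: variance in repeat
#' scores is partitioned within versus among the two groups by a one-level
#' AMOVA per locus; components are summed across loci before forming
#' \eqn{R_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}. Slightly negative
#' values can arise by sampling when the groups are effectively one
#' population.
#'
#' @param popA,popB Normalized [haplotype_table()]s (or slices), each with
#'   at least 2 complete haplotypes.
#' @return Numeric Rst.
#' @export
rst_pair <- function(popA, popB) {
  XA <- .complete_repeats(popA)
  XB <- .complete_repeats(popB)
  if (!identical(colnames(XA), colnames(XB))) stop("panel mismatch")
  if (nrow(XA) < 2L || nrow(XB) < 2L) {
    stop("insufficient sample: Rst needs >= 2 complete haplotypes per group")
  }
  X <- rbind(XA, XB)
  if (all(apply(X, 2L, function(x) length(unique(x))) == 1L)) {
    stop("undefined distance: zero total variance across all loci")
  }
  g <- rep(1:2, c(nrow(XA), nrow(XB)))
  r <- .rst_from_components(.rst_components(X, g))
  if (is.na(r)) stop("undefined distance: zero total variance")
  r
}

.complete_repeats <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  if (!table$normalized) stop("requires a normalized table")
  X <- table$repeats[stats::complete.cases(table$repeats), , drop = FALSE]
  storage.mode(X) <- "double"
  X
}

#' Permutation test for pairwise Rst
#'
#' Individuals are reassigned to the two groups preserving group sizes; the
#' p-value uses the add-one correction \eqn{p = (1 + b) / (1 + B)} where
#' \eqn{b} counts permuted Rst values at least as large as the observed one,
#' so p is never exactly 0. With \code{method = "exhaustive"} all
#' \eqn{\binom{n_A+n_B}{n_A}} assignments are enumerated instead and the
#' p-value is the exact fraction (the identity assignment counts).
#'
#' @param popA,popB Normalized [haplotype_table()]s.
#' @param n_permutations Number of random reassignments (default 10000).
#' @param seed Integer seed; the test is reproducible given the seed.
#' @param method \code{"sampling"} (default) or \code{"exhaustive"}.
#' @return List with \code{rst}, \code{p_value}, \code{n_permutations}
#'   (or number of enumerated assignments), and \code{method}.
#' @export
permutation_test <- function(popA, popB, n_permutations = 10000L,
                             seed = NULL,
                             method = c("sampling", "exhaustive")) {
  method <- match.arg(method)
  XA <- .complete_repeats(popA)
  XB <- .complete_repeats(popB)
  if (!identical(colnames(XA), colnames(XB))) stop("panel mismatch")
  nA <- nrow(XA); nB <- nrow(XB)
  if (nA < 2L || nB < 2L) {
    stop("insufficient sample: Rst needs >= 2 complete haplotypes per group")
  }
  X <- rbind(XA, XB)
  N <- nA + nB
  # fixed per-locus quantities shared by every reassignment
  T2 <- colSums(X^2)
  G <- colSums(X)
  gg <- G^2 / N
  n_c <- N - (nA^2 + nB^2) / N
  rst_for <- function(idxA) {
    SA <- colSums(X[idxA, , drop = FALSE])
    SB <- G - SA
    fit <- SA^2 / nA + SB^2 / nB
    msd_w <- (T2 - fit) / (N - 2)
    sig_a <- ((fit - gg) - msd_w) / n_c
    den <- sum(sig_a + msd_w)
    if (den == 0) return(NA_real_)
    sum(sig_a) / den
  }
  obs <- rst_for(seq_len(nA))
  if (is.na(obs)) stop("undefined distance: zero total variance")
  if (method == "exhaustive") {
    assignments <- utils::combn(N, nA)
    perm <- apply(assignments, 2L, rst_for)
    p <- mean(perm >= obs - 1e-12, na.rm = TRUE)
    return(list(rst = obs, p_value = p,
                n_permutations = ncol(assignments), method = method))
  }
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  b <- 0L
  for (i in seq_len(n_permutations)) {
    r <- rst_for(sample.int(N, nA))
    if (!is.na(r) && r >= obs - 1e-12) b <- b + 1L
  }
  list(rst = obs, p_value = (1 + b) / (1 + n_permutations),
       n_permutations = n_permutations, method = method)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param m Number of comparisons (for k populations, \eqn{m = k(k-1)/2}).
#' @return List with \code{threshold} (exact \eqn{\alpha/m}), \code{display}
#'   (rounded to 4 decimal places, the form quoted in methods sections),
#'   \code{alpha}, and \code{m}.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (m < 1) stop("m must be a positive number of comparisons")
  t <- alpha / m
  list(threshold = t, display = round(t, 4), alpha = alpha, m = m)
}

#' Number of pairwise comparisons among k populations
#'
#' @param k Number of populations.
#' @return Integer \eqn{k(k-1)/2}.
#' @export
n_pairwise_comparisons <- function(k) {
  if (k < 1) stop("k must be >= 1")
  as.integer(k * (k - 1) / 2)
}

#' Full pairwise Rst matrix with permutation p-values
#'
#' Computes Rst and its permutation p-value for every population pair in a
#' multi-population table, and flags pairs significant after Bonferroni
#' correction of the family-wise level.
#'
#' @param table A normalized [haplotype_table()] with >= 2 populations.
#' @param n_permutations Permutations per pair (default 10000).
#' @param seed Integer seed; pair tests use seeds derived deterministically
#'   from it.
#' @param alpha Family-wise significance level (default 0.05).
#' @return An object of class \code{rst_matrix}: list with \code{labels},
#'   \code{values}, \code{p_values}, \code{significant} (logical matrix,
#'   Bonferroni-corrected), \code{n_permutations}, \code{threshold}.
#' @export
rst_matrix <- function(table, n_permutations = 10000L, seed = NULL,
                       alpha = 0.05) {
  stopifnot(inherits(table, "haplotype_table"))
  pops <- sort(unique(table$populations))
  k <- length(pops)
  if (k < 2L) stop("need at least two populations for a distance matrix")
  vals <- pv <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  diag(vals) <- 0
  diag(pv) <- 1
  m <- n_pairwise_comparisons(k)
  thr <- bonferroni_threshold(alpha, m)
  pair_id <- 0L
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    pair_id <- pair_id + 1L
    res <- permutation_test(
      subset_table(table, population = pops[i]),
      subset_table(table, population = pops[j]),
      n_permutations = n_permutations,
      seed = if (is.null(seed)) NULL else (seed + pair_id) %% .Machine$integer.max)
    vals[i, j] <- vals[j, i] <- res$rst
    pv[i, j] <- pv[j, i] <- res$p_value
  }
  sig <- pv < thr$threshold
  diag(sig) <- FALSE
  structure(list(labels = pops, values = vals, p_values = pv,
                 significant = sig, n_permutations = n_permutations,
                 threshold = thr),
            class = "rst_matrix")
}

#' @export
print.rst_matrix <- function(x, ...) {
  cat(sprintf("rst_matrix: %d populations, %d permutations/pair, Bonferroni threshold %.4g\n",
              length(x$labels), x$n_permutations, x$threshold$threshold))
  print(round(x$values, 4))
  invisible(x)
}

#' Write a distance matrix (and p-values) as square TSVs
#'
#' @param dist An \code{rst_matrix}.
#' @param path Output path for Rst values; p-values go to
#'   \code{<path>} with a \code{.pvalues.tsv} suffix replacing the extension.
#' @return Invisibly, \code{path}.
#' @export
write_distance_matrix <- function(dist, path) {
  stopifnot(inherits(dist, "rst_matrix"))
  df <- data.frame(Population = dist$labels, dist$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utf8_write_tsv(df, path)
  pvp <- sub("\\.[^.]*$", "", path)
  pdf <- data.frame(Population = dist$labels, dist$p_values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utf8_write_tsv(pdf, paste0(pvp, ".pvalues.tsv"))
  invisible(path)
}
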